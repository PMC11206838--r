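# table builder: one outcome, subjects x conditions, cell means given by
# mu(group, condition), subject random intercept sd tau, residual sd sigma
make_stats_table <- function(n_per_group = 15, conds = 1:3,
                             mu = function(g, c) 0, tau = 0.05,
                             sigma = 0.05, outcome = "bin_LG_L1") {
  rows <- list()
  for (g in c("CP", "TD")) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s%02d", g, i)
      ui <- rnorm(1, 0, tau)
      for (cc in conds) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, group = g, level = 1L, outcome = outcome,
          condition = cc, value = mu(g, cc) + ui + rnorm(1, 0, sigma)
        )
      }
    }
  }
  do.call(rbind, rows)
}

test_that("compute_weights is the inverse cell variance", {
  tab <- data.frame(
    subject_id = c("a", "b", "a", "b"), group = "TD",
    outcome = "x", condition = c(1, 1, 2, 2),
    value = c(1, 3, 2, 2.5)
  )
  w <- compute_weights(tab)
  expect_equal(w$weight[1:2], c(0.5, 0.5))  # var(1,3) = 2
  expect_equal(w$weight[3:4], rep(1 / var(c(2, 2.5)), 2))

  # row-order invariance
  perm <- sample(nrow(tab))
  w2 <- compute_weights(tab[perm, ])
  expect_equal(w2$weight, w$weight[perm])

  # constant cell floored with warning
  tab$value[3:4] <- 1
  expect_warning(wf <- compute_weights(tab), "floored")
  expect_equal(wf$weight[3], 1e8)

  expect_error(compute_weights(tab[1:3, ]), "fewer than 2")
  expect_error(compute_weights(tab[, -5]), "lacks column")
})

test_that("holm_correct implements the step-down rule", {
  h <- holm_correct(c(0.01, 0.04, 0.03), 0.05)
  expect_equal(h$reject, c(TRUE, FALSE, FALSE))
  expect_equal(h$alpha_level, c(0.05 / 3, 0.05, 0.05 / 2))

  expect_false(any(holm_correct(rep(1, 5))$reject))
  expect_true(holm_correct(0.04)$reject)
  expect_error(holm_correct(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("holm_correct matches the brute-force oracle exactly", {
  set.seed(21)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)  # skew some toward small values
    got <- holm_correct(p, 0.05)$reject
    oracle <- p.adjust(p, method = "holm") <= 0.05
    expect_identical(got, unname(oracle))
  }
})

test_that("fit_group_model recovers null and obvious effects", {
  set.seed(31)
  # identical groups by construction: copy TD values into CP
  tab <- make_stats_table(mu = function(g, c) 0.2 + 0.05 * c)
  td <- tab[tab$group == "TD", ]
  cp <- td
  cp$group <- "CP"
  cp$subject_id <- sub("TD", "CP", cp$subject_id)
  mirror <- rbind(cp, td)
  res <- fit_group_model(compute_weights(mirror), "bin_LG_L1", "group")
  gterm <- res$estimates[grepl("^group", res$estimates$term), ]
  expect_lt(abs(gterm$estimate), 1e-6)
  expect_gt(res$p, 0.9)

  # a large group shift is detected
  set.seed(32)
  tab <- make_stats_table(mu = function(g, c)
    0.2 + 0.05 * c + 0.3 * (g == "CP"))
  res <- fit_group_model(compute_weights(tab), "bin_LG_L1", "group")
  expect_lt(res$p, 1e-6)
})

test_that("constant weights reproduce the unweighted fit", {
  # on balanced homoscedastic data the true weights are a constant, and a
  # constant weight is absorbed into the residual variance: the fit must
  # match the unweighted one to numerical tolerance
  set.seed(33)
  tab <- make_stats_table(mu = function(g, c) 0.2 + 0.1 * c,
                          tau = 0.03, sigma = 0.04)
  w <- tab
  w$weight <- rep(7, nrow(w))
  res_w <- fit_group_model(w, "bin_LG_L1", "interaction")
  u <- tab
  u$weight <- rep(1, nrow(u))
  res_u <- fit_group_model(u, "bin_LG_L1", "interaction")
  expect_equal(res_w$p, res_u$p, tolerance = 1e-6)
  expect_equal(res_w$estimates$estimate, res_u$estimates$estimate,
               tolerance = 1e-6)
})

test_that("posthoc contrasts equal cell-mean differences on balanced data", {
  # noiseless: exact interaction, exact contrasts
  set.seed(34)
  mu <- function(g, c) 0.1 * c + ifelse(g == "CP", c(0, 0, 0.3)[c], 0)
  tab <- make_stats_table(mu = mu, tau = 0, sigma = 1e-3)
  w <- compute_weights(tab)
  res <- fit_group_model(w, "bin_LG_L1", "interaction")
  expect_lt(res$p, 0.001)
  ph <- posthoc_interaction(w, res)
  cellmean <- function(g, c) mean(tab$value[tab$group == g &
                                              tab$condition == c])
  for (cc in 1:3) {
    row <- ph[ph$contrast == sprintf("TD-CP @ condition %d", cc), ]
    expect_equal(row$estimate, cellmean("TD", cc) - cellmean("CP", cc),
                 tolerance = 1e-6)
  }
  # only the condition-3 group contrast is real
  expect_true(ph$reject[ph$contrast == "TD-CP @ condition 3"])
  expect_false(ph$reject[ph$contrast == "TD-CP @ condition 1"])
  # the 2->3 change differs between groups; 1->2 does not
  expect_true(ph$reject[grepl("change 2->3", ph$contrast)])
  expect_false(ph$reject[grepl("change 1->2", ph$contrast)])

  # calling post-hocs without a significant interaction is a usage error
  set.seed(35)
  null_tab <- make_stats_table(mu = function(g, c) 0.1 * c)
  null_res <- fit_group_model(compute_weights(null_tab), "bin_LG_L1",
                              "interaction")
  if (null_res$p > 0.05) {
    expect_error(posthoc_interaction(null_tab, null_res), "not significant")
  }
  expect_error(posthoc_interaction(tab, "nope"), "interaction-effect")
})

test_that("targeted simulation flags the differing bin most of the time", {
  set.seed(36)
  hits <- 0
  runs <- 20
  for (i in seq_len(runs)) {
    mu <- function(g, c) 0.1 * c + ifelse(g == "CP", c(0, 0, 0.15)[c], 0)
    tab <- make_stats_table(mu = mu, tau = 0.03, sigma = 0.04)
    w <- suppressWarnings(compute_weights(tab))
    res <- fit_group_model(w, "bin_LG_L1", "interaction")
    if (!is.na(res$p) && res$p <= 0.05) {
      ph <- posthoc_interaction(w, res)
      if (ph$reject[ph$contrast == "TD-CP @ condition 3"]) hits <- hits + 1
    }
  }
  expect_gt(hits, runs / 2)
})
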