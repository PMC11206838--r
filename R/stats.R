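# Group statistics.
#
# Outcomes (bin averages, co-contraction indices, gains, cost
# improvements) are compared between groups with linear mixed models:
# fixed effects group and condition (time bin 1-3 or perturbation level
# 1-4, coded numerically as they are ordinal), random intercept per
# participant (participants are nested within group, so a plain
# per-subject intercept with globally unique ids is equivalent).
# Observations are weighted by the inverse of the outcome variance within
# each group x condition cell. Effects are tested by likelihood-ratio
# tests on maximum-likelihood fits; families of tests are corrected with
# the Bonferroni-Holm step-down procedure.

#' Inverse-variance observation weights
#'
#' Adds a `weight` column: `1 / var(value)` within each
#' outcome x group x condition cell. Variances below `floor` are floored
#' (with a warning) so degenerate cells cannot produce infinite weights.
#'
#' @param table A cohort table: data.frame with columns `subject_id`,
#'   `group`, `outcome`, `condition`, `value` (plus anything else).
#' @param floor Variance floor (default 1e-8).
#' @return The table with a `weight` column appended.
#' @export
compute_weights <- function(table, floor = 1e-8) {
  needed <- c("subject_id", "group", "outcome", "condition", "value")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  key <- interaction(table$outcome, table$group, table$condition, drop = TRUE)
  counts <- tapply(table$value, key, length)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop("cell(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  vars <- tapply(table$value, key, var)
  if (any(vars < floor)) {
    warning("variance floored in ", sum(vars < floor), " cell(s)")
    vars <- pmax(vars, floor)
  }
  table$weight <- as.numeric(1 / vars[as.character(key)])
  table
}

#' Weighted mixed-model group comparison for one outcome
#'
#' Fits `value ~ group * condition + (1 | subject_id)` (or the additive
#' model when testing the group main effect) by maximum likelihood with
#' inverse-variance weights, and tests the configured effect by a
#' likelihood-ratio test against the nested model without it.
#'
#' @param table Cohort table with weights (see [compute_weights()]).
#' @param outcome Outcome name to analyse.
#' @param effect `"interaction"` (group x condition, used for time-bin
#'   outcomes) or `"group"` (group main effect, used for CCI, gains, cost
#'   improvement).
#' @return A `group_model_result`: `outcome`, `effect`, `p` (LRT p-value),
#'   `chisq`, `df`, fixed-effect `estimates` (with Wald 95% CIs),
#'   `singular` flag, and the fitted `model`.
#' @export
fit_group_model <- function(table, outcome,
                            effect = c("interaction", "group")) {
  effect <- match.arg(effect)
  if (!"weight" %in% names(table)) table <- compute_weights(table)
  d <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop("outcome not present in table: ", outcome)
  d$condition <- as.numeric(d$condition)
  d$group <- factor(d$group)
  full_f <- value ~ group * condition + (1 | subject_id)
  red_f <- value ~ group + condition + (1 | subject_id)
  if (effect == "group") {
    full_f <- value ~ group + condition + (1 | subject_id)
    red_f <- value ~ condition + (1 | subject_id)
  }
  quiet_fit <- function(f) {
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, weights = d$weight, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
  }
  full <- quiet_fit(full_f)
  red <- quiet_fit(red_f)
  lrt <- suppressMessages(anova(red, full))
  p <- lrt[2, "Pr(>Chisq)"]
  fe <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(vcov(full))))
  est <- data.frame(
    term = names(fe), estimate = as.numeric(fe), se = se,
    ci_lo = as.numeric(fe) - 1.96 * se, ci_hi = as.numeric(fe) + 1.96 * se
  )
  structure(
    list(outcome = outcome, effect = effect, p = p,
         chisq = lrt[2, "Chisq"], df = lrt[2, "Df"], estimates = est,
         singular = lme4::isSingular(full), model = full, data = d),
    class = "group_model_result"
  )
}

#' @export
print.group_model_result <- function(x, ...) {
  cat(sprintf("<group_model_result> %s: %s effect, LRT chisq = %.3f (df %d), p = %.4g%s\n",
              x$outcome, x$effect, x$chisq, x$df, x$p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Bonferroni-Holm step-down correction
#'
#' Orders the p-values ascending and compares the k-th smallest to
#' `alpha / (m - k + 1)`, stopping at the first failure; all earlier
#' hypotheses are rejected. Returns, per hypothesis in input order, the
#' decision and the step-wise alpha level it was compared against.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data.frame with columns `p`, `alpha_level`, `reject`.
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  ord <- order(pvals)
  thresh_sorted <- alpha / (m - seq_len(m) + 1)
  reject_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (pvals[ord[k]] <= thresh_sorted[k]) {
      reject_sorted[k] <- TRUE
    } else {
      break
    }
  }
  out <- data.frame(p = pvals, alpha_level = NA_real_, reject = FALSE)
  out$alpha_level[ord] <- thresh_sorted
  out$reject[ord] <- reject_sorted
  out
}

#' Post-hoc contrasts after a significant group x condition interaction
#'
#' Two contrast families, mirroring the usual decomposition of an
#' interaction: (1) the group difference within each condition, and
#' (2) the group difference in the condition-to-condition change
#' (e.g., does activity drop from bin 2 to bin 3 differently across
#' groups). Each contrast is a weighted linear model on the relevant
#' subset; the whole post-hoc family is Holm-corrected together.
#'
#' @param table Cohort table with weights.
#' @param model A significant `group_model_result` with
#'   `effect == "interaction"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data.frame of contrasts: `contrast`, `estimate`, `p`,
#'   `alpha_level`, `reject`.
#' @export
posthoc_interaction <- function(table, model, alpha = 0.05) {
  if (!inherits(model, "group_model_result") ||
      model$effect != "interaction") {
    stop("posthoc_interaction needs an interaction-effect model result")
  }
  if (is.na(model$p) || model$p > alpha) {
    stop("interaction effect is not significant; post-hocs not warranted")
  }
  d <- model$data
  groups <- sort(unique(as.character(d$group)))
  if (length(groups) != 2) stop("post-hocs require exactly two groups")
  conds <- sort(unique(d$condition))
  rows <- list()
  # group difference within each condition
  for (cc in conds) {
    dc <- d[d$condition == cc, ]
    fit <- stats::lm(value ~ group, data = dc, weights = dc$weight)
    sm <- summary(fit)$coefficients
    rows[[paste0("group@cond", cc)]] <- data.frame(
      contrast = sprintf("%s-%s @ condition %s", groups[2], groups[1], cc),
      estimate = sm[2, 1], p = sm[2, 4]
    )
  }
  # group difference of adjacent condition changes (per-subject deltas)
  for (i in seq_len(length(conds) - 1)) {
    c1 <- conds[i]; c2 <- conds[i + 1]
    d1 <- d[d$condition == c1, c("subject_id", "group", "value")]
    d2 <- d[d$condition == c2, c("subject_id", "group", "value")]
    mg <- merge(d1, d2, by = c("subject_id", "group"),
                suffixes = c("_1", "_2"))
    mg$delta <- mg$value_2 - mg$value_1
    fit <- stats::lm(delta ~ group, data = mg)
    sm <- summary(fit)$coefficients
    rows[[paste0("change", c1, c2)]] <- data.frame(
      contrast = sprintf("%s-%s change %s->%s", groups[2], groups[1], c1, c2),
      estimate = sm[2, 1], p = sm[2, 4]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  hc <- holm_correct(out$p, alpha)
  out$alpha_level <- hc$alpha_level
  out$reject <- hc$reject
  out
}
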