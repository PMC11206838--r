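# Pipeline orchestration: configuration, simulate / analyze / stats /
# report entry points. Every stage is a pure function of (config, seed);
# outputs embed the seed so runs can be traced.

#' Default pipeline configuration
#'
#' Nested list with one block per stage. Values mirror the canonical
#' analysis: 10-450 Hz band-pass and 40 Hz low-pass EMG conditioning,
#' 100 Hz analysis grid over [-0.6, 1.5] s, Z1-Z3 time bins with the
#' 100 ms kinematic shift, 100 ms feedback delay, [0, 10] gain bounds,
#' 1e-4 prime-gain penalty, 0.5 degree stiction threshold.
#'
#' @param seed Global seed (default 1).
#' @return Configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    log_level = "info",
    synthetic = list(
      n_per_group = 20, n_trials = 8, levels = 1:4,
      gain_sigma = 0.25, step_prob = 0.05,
      noise = list(envelope_sd = 0.02, baseline = 0.05,
                   kin_jitter_sd = 0.02),
      groups = list(CP = "CP_like", TD = "TD_like")
    ),
    preprocess = list(
      band = c(10, 450), lowpass = 40,
      sg_order = 5, sg_window = 11,
      analysis_rate = 100, window = c(-0.6, 1.5),
      resmooth_com = FALSE
    ),
    bins = list(emg_edges = c(0, 0.150, 0.250, 0.400),
                kin_edges = c(0, 0.050, 0.150, 0.300)),
    cci = list(windows = list(short = c(0, 0.4), long = c(-0.5, 1.5))),
    model = list(
      tau = 0.100, bounds = 10, penalty_weight = 1e-4,
      stiction_threshold = 0.5, fit_window = c(-0.5, 1.5),
      gof_window = c(0, 1.5), n_starts = 8, seed = seed
    ),
    stats = list(alpha = 0.05),
    paths = list(data_dir = "data", out_dir = "results")
  )
}

#' Load a pipeline configuration file
#'
#' JSON file whose blocks override [default_config()].
#'
#' @param path Path to the JSON configuration.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), user)
}

config_model <- function(config, variant = "extended") {
  mc <- config$model
  model_config(
    tau = mc$tau, bounds = mc$bounds, penalty_weight = mc$penalty_weight,
    stiction_threshold = mc$stiction_threshold,
    fit_window = mc$fit_window, gof_window = mc$gof_window,
    variant = variant, n_starts = mc$n_starts, seed = mc$seed
  )
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Simulate a synthetic dataset to disk
#'
#' Wraps [generate_cohort()]: writes trial files, a manifest, and a
#' ground-truth gain sidecar into `config$paths$data_dir`.
#'
#' @param config Pipeline configuration.
#' @param force Overwrite an existing non-empty output directory.
#' @return The [generate_cohort()] result (invisibly).
#' @export
cmd_simulate <- function(config = default_config(), force = FALSE) {
  dir <- config$paths$data_dir
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    stop("output directory ", dir, " exists and is not empty; use force")
  }
  syn <- config$synthetic
  nm <- syn$noise
  res <- generate_cohort(
    n_per_group = syn$n_per_group, seed = config$seed,
    groups = syn$groups,
    noise = noise_model(nm$envelope_sd, nm$baseline, nm$kin_jitter_sd),
    gain_sigma = syn$gain_sigma, levels = syn$levels,
    n_trials = syn$n_trials, step_prob = syn$step_prob,
    dir = dir, config = config_model(config)
  )
  pipe_log(config, "simulated %d trials into %s (seed %d)",
           length(res$trials), dir, config$seed)
  invisible(res)
}

#' Analyze a set of trials
#'
#' Core analysis on in-memory trials: preprocess, subject-maximum scaling,
#' per-level averaging over non-stepping trials, then (as requested) time
#' bins, co-contraction indices, and simple + extended model fits with
#' cost improvement. Used by [cmd_analyze()] and directly by simulations.
#'
#' @param trials List of [trial_recording()] objects.
#' @param config Pipeline configuration.
#' @param components Character subset of `c("bins", "cci", "fits")`.
#' @return List: `table` (long cohort table: subject_id, group, level,
#'   outcome, condition, value), `fits` (per subject/level/muscle fit
#'   objects when fitted), `scales` (per subject/muscle scale factors),
#'   `log` (stepped-trial and missing-level bookkeeping).
#' @export
analyze_trials <- function(trials, config = default_config(),
                           components = c("bins", "cci", "fits")) {
  if (!length(trials)) stop("no trials to analyze")
  pp <- config$preprocess
  processed <- lapply(trials, preprocess_trial, config = pp)
  subjects <- unique(vapply(processed, `[[`, "", "subject_id"))
  rows <- list()
  fits <- list()
  scales <- list()
  log <- list(stepped = 0L, missing = character(0))
  mc_ext <- config_model(config, "extended")
  mc_sim <- config_model(config, "simple")

  for (sid in subjects) {
    mine <- processed[vapply(processed, function(p)
      p$subject_id == sid, logical(1))]
    # subject-maximum scaling pools every trial of the subject
    for (m in MUSCLES) {
      sc <- scale_emg(lapply(mine, function(p) p$emg_env[[m]]))
      for (i in seq_along(mine)) mine[[i]]$emg_env[[m]] <- sc$envelopes[[i]]
      scales[[sid]][[m]] <- sc$scale
    }
    grp <- mine[[1]]$group
    levels_here <- sort(unique(vapply(mine, `[[`, 0L, "level")))
    for (lv in levels_here) {
      at_level <- mine[vapply(mine, function(p) p$level == lv, logical(1))]
      keep <- at_level[!vapply(at_level, `[[`, FALSE, "stepped")]
      log$stepped <- log$stepped + (length(at_level) - length(keep))
      if (!length(keep)) {
        log$missing <- c(log$missing, sprintf("%s/L%d", sid, lv))
        next
      }
      avg <- average_trials(keep)
      com <- com_kinematics(avg, config$model$stiction_threshold)
      add_row <- function(outcome, condition, value) {
        rows[[length(rows) + 1]] <<- data.frame(
          subject_id = sid, group = grp, level = lv,
          outcome = outcome, condition = condition, value = value
        )
      }
      if ("bins" %in% components) {
        tb <- timebin_summary(avg, com, config$bins$emg_edges,
                              config$bins$kin_edges)
        for (i in seq_len(nrow(tb))) {
          add_row(sprintf("bin_%s_L%d", tb$channel[i], lv),
                  as.integer(sub("Z", "", tb$bin[i])), tb$value[i])
        }
      }
      if ("cci" %in% components) {
        cc <- cci_battery(avg, config$cci$windows)
        for (i in seq_len(nrow(cc))) {
          add_row(sprintf("cci_%s_%s", cc$pair[i], cc$window[i]),
                  lv, cc$value[i])
        }
      }
      if ("fits" %in% components) {
        for (m in MUSCLES) {
          role <- muscle_role(m)
          ext <- fit_gains(avg$emg_env[[m]], com, mc_ext, role)
          sim <- fit_gains(avg$emg_env[[m]], com, mc_sim, role)
          fits[[sprintf("%s_L%d_%s", sid, lv, m)]] <-
            list(extended = ext, simple = sim)
          for (g in names(ext$gains)) {
            add_row(sprintf("gain_%s_%s", m, g), lv, ext$gains[[g]])
          }
          add_row(sprintf("r2_%s", m), lv, ext$r2)
          add_row(sprintf("vaf_%s", m), lv, ext$vaf)
          add_row(sprintf("rmse_%s", m), lv, ext$rmse)
          add_row(sprintf("costimp_%s", m), lv,
                  cost_improvement(sim$cost, ext$cost))
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fits = fits, scales = scales, log = log,
       seed = config$seed)
}

#' Analyze a dataset from a manifest
#'
#' Reads every manifest entry, runs [analyze_trials()], and writes the
#' cohort table to `config$paths$out_dir/cohort_table.tsv`.
#'
#' @param config Pipeline configuration.
#' @param manifest_path Path to the manifest JSON (default: the one in
#'   `config$paths$data_dir`).
#' @param components Passed to [analyze_trials()].
#' @return The [analyze_trials()] result (invisibly), with `table_path`.
#' @export
cmd_analyze <- function(config = default_config(),
                        manifest_path = file.path(config$paths$data_dir,
                                                  "manifest.json"),
                        components = c("bins", "cci", "fits")) {
  manifest <- load_manifest(manifest_path)
  if (!length(manifest$entries)) stop("manifest has no entries")
  trials <- lapply(manifest$entries, function(e) read_trial(e$path, e))
  res <- analyze_trials(trials, config, components)
  pipe_log(config, "analyzed %d trials (%d stepped excluded%s)",
           length(trials), res$log$stepped,
           if (length(res$log$missing)) {
             paste0("; missing: ", paste(res$log$missing, collapse = ", "))
           } else "")
  dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  res$table_path <- file.path(config$paths$out_dir, "cohort_table.tsv")
  write.table(res$table, res$table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(res)
}

# outcome-name prefix -> tested effect; families for Holm correction are
# one per outcome type (all muscles/levels in one family).
OUTCOME_FAMILIES <- list(
  bins = list(prefix = "^bin_", effect = "interaction"),
  cci = list(prefix = "^cci_", effect = "group"),
  gains = list(prefix = "^gain_", effect = "group"),
  costimp = list(prefix = "^costimp_", effect = "group")
)

#' Group statistics over a cohort table
#'
#' Runs the weighted mixed model per outcome, grouped into Holm families
#' by outcome type (time bins are tested for the group x bin interaction;
#' CCI, gains and cost improvements for the group main effect).
#'
#' @param table Cohort table (data.frame or path to a TSV written by
#'   [cmd_analyze()]).
#' @param config Pipeline configuration.
#' @param families Which families to run (default all present).
#' @return Data.frame: `family`, `outcome`, `effect`, `p`, `alpha_level`,
#'   `reject_raw`, `reject_holm`, `singular`.
#' @export
cmd_stats <- function(table, config = default_config(),
                      families = names(OUTCOME_FAMILIES)) {
  if (is.character(table)) {
    table <- read.table(table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  }
  needed <- c("subject_id", "group", "outcome", "condition", "value")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  table <- suppressWarnings(compute_weights(table))
  alpha <- config$stats$alpha
  out <- list()
  for (fam in families) {
    fd <- OUTCOME_FAMILIES[[fam]]
    if (is.null(fd)) stop("unknown outcome family: ", fam)
    outs <- sort(unique(grep(fd$prefix, table$outcome, value = TRUE)))
    if (!length(outs)) next
    res <- lapply(outs, function(o) fit_group_model(table, o, fd$effect))
    p <- vapply(res, `[[`, 0, "p")
    hc <- holm_correct(p, alpha)
    out[[fam]] <- data.frame(
      family = fam, outcome = outs, effect = fd$effect, p = p,
      alpha_level = hc$alpha_level,
      reject_raw = p <= alpha, reject_holm = hc$reject,
      singular = vapply(res, `[[`, FALSE, "singular")
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary plots of a synthetic-cohort analysis
#'
#' Writes a multi-page PDF: time-binned reactive EMG by group, CCI by
#' level and pair, and fitted gains by group, mirroring the standard
#' figures for this kind of analysis.
#'
#' @param analysis Result of [analyze_trials()]/[cmd_analyze()].
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
cmd_report <- function(analysis, path = "results/report.pdf") {
  tab <- analysis$table
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::pdf(path, width = 9, height = 6)
  on.exit(grDevices::dev.off())
  plot_family <- function(prefix, main, xlab) {
    d <- tab[grepl(prefix, tab$outcome), ]
    if (!nrow(d)) return(invisible())
    graphics::boxplot(
      value ~ group + outcome, data = d, las = 2, cex.axis = 0.6,
      main = main, xlab = xlab, ylab = "value",
      col = c("orange", "steelblue")
    )
  }
  plot_family("^bin_(LG|MG|SOL|TA)_", "Reactive EMG by time bin", "")
  plot_family("^cci_", "Co-contraction index", "")
  plot_family("^gain_.*_(k_v|k_vp)$", "Velocity and prime velocity gains", "")
  plot_family("^costimp_", "Cost improvement, extended vs simple (%)", "")
  invisible(path)
}
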