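# Small stable checksum for embedding a configuration fingerprint in outputs.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(s)) h <- (xor(h, v) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full robustness evaluation
#'
#' End-to-end orchestration: the factor-analysis screen on the full table,
#' then for each configured classifier a replacement-noise severity sweep,
#' a Gaussian-noise severity sweep (both on a shared fixed split), and a
#' Monte Carlo split study. The per-classifier robustness evidence is
#' reported raw -- the count of the classifier's input features found in the
#' screen's F* set, and accuracy variances relative to the fleet median --
#' rather than as a binary verdict, since no universal numeric robustness
#' cutoff exists.
#'
#' @param table An [omics_table()].
#' @param classifiers List of [classifier_spec()]s (features may be `NULL`
#'   for all-feature classifiers).
#' @param levels Noise levels for both sweeps (default `seq(0, 1, 0.1)`).
#' @param reps Corruptions per level (default 100).
#' @param n_splits Splits for the split study (default 100).
#' @param ratio Training fraction (default 0.7).
#' @param track_loocv Track LOOCV accuracy inside the sweeps
#'   (default `FALSE`; the split study always records it).
#' @param screen_args Named list of overrides for [run_factor_analysis()].
#' @param seed Master seed, recorded in every output.
#'
#' @return A `robustness_report` bundle: list with `screen`, `results` (per
#'   classifier: `replacement`, `gaussian`, `splits`, `verdict`), `summary`
#'   (one row per classifier: accuracy with no noise, accuracy and variance
#'   at full replacement, at full Gaussian noise, and across splits), `seed`,
#'   and `config_hash`.
#' @export
run_full_evaluation <- function(table, classifiers, levels = seq(0, 1, 0.1),
                                reps = 100L, n_splits = 100L, ratio = 0.7,
                                track_loocv = FALSE, screen_args = list(),
                                seed = 1L) {
  stopifnot(inherits(table, "omics_table"), length(classifiers) >= 1L)
  config <- list(levels = levels, reps = reps, n_splits = n_splits,
                 ratio = ratio, track_loocv = track_loocv,
                 screen_args = screen_args, seed = seed,
                 classifiers = lapply(classifiers, unclass))
  screen <- do.call(run_factor_analysis,
                    c(list(table = table, seed = derive_seed(seed, 1L)),
                      screen_args))
  split <- make_split(table, ratio = ratio, seed = derive_seed(seed, 2L))
  results <- list()
  rows <- list()
  for (ci in seq_along(classifiers)) {
    spec <- classifiers[[ci]]
    rep_sweep <- severity_sweep(table, spec, "replacement", levels = levels,
                                reps = reps, split = split,
                                seed = derive_seed(seed, 3L, ci),
                                track_loocv = track_loocv)
    gau_sweep <- severity_sweep(table, spec, "gaussian", levels = levels,
                                reps = reps, split = split,
                                seed = derive_seed(seed, 4L, ci),
                                track_loocv = track_loocv)
    splits <- mc_split_study(table, spec, n_splits = n_splits, ratio = ratio,
                             seed = derive_seed(seed, 5L, ci))
    inputs <- spec$features %||% table$feature_names
    verdict <- list(
      n_inputs = length(inputs),
      n_from_screen = sum(inputs %in% screen$F_star),
      var_p1 = utils::tail(rep_sweep$summary$var_test_acc, 1L),
      var_s1 = utils::tail(gau_sweep$summary$var_test_acc, 1L),
      var_mc_split = splits$var_test_acc
    )
    last <- nrow(rep_sweep$summary)
    rows[[ci]] <- data.frame(
      classifier = spec$algorithm,
      acc_no_noise = rep_sweep$summary$mean_test_acc[1L],
      acc_p1 = rep_sweep$summary$mean_test_acc[last],
      var_p1 = rep_sweep$summary$var_test_acc[last],
      acc_s1 = gau_sweep$summary$mean_test_acc[last],
      var_s1 = gau_sweep$summary$var_test_acc[last],
      acc_mc_split = splits$mean_test_acc,
      var_mc_split = splits$var_test_acc,
      n_from_screen = verdict$n_from_screen
    )
    results[[spec$algorithm]] <- list(replacement = rep_sweep,
                                      gaussian = gau_sweep,
                                      splits = splits, verdict = verdict)
  }
  summary <- do.call(rbind, rows)
  fleet_median <- stats::median(summary$var_p1)
  for (nm in names(results)) {
    results[[nm]]$verdict$var_p1_vs_fleet <-
      results[[nm]]$verdict$var_p1 / fleet_median
  }
  structure(list(screen = screen, results = results, summary = summary,
                 split = split, seed = seed, config_hash = config_hash(config)),
            class = "robustness_report")
}

#' Write a robustness report to disk
#'
#' Emits `summary.csv` (the one-row-per-classifier accuracy/variance table),
#' `screen.json` (per-feature FDRs, cluster memberships, silhouettes, scaled
#' variances and the F'/F''/F* lists), and per-classifier sweep CSVs plus a
#' consolidated `report.json`. Every file embeds the master seed and the
#' configuration hash, so two runs with equal hash produce equal numerics.
#'
#' @param bundle A [run_full_evaluation()] result.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#'
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, out_dir, formats = c("csv", "json")) {
  stopifnot(inherits(bundle, "robustness_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- list(seed = bundle$seed, config_hash = bundle$config_hash)
  if ("csv" %in% formats) {
    p <- file.path(out_dir, "summary.csv")
    utils::write.csv(bundle$summary, p, row.names = FALSE)
    paths <- c(paths, p)
    for (nm in names(bundle$results)) {
      for (cond in c("replacement", "gaussian")) {
        p <- file.path(out_dir, sprintf("sweep_%s_%s.csv", nm, cond))
        utils::write.csv(summarize_result(bundle$results[[nm]][[cond]]), p,
                         row.names = FALSE)
        paths <- c(paths, p)
      }
    }
  }
  if ("json" %in% formats) {
    scr <- bundle$screen
    screen_json <- c(meta, list(
      fdr = scr$fdr,
      n_components = scr$n_components,
      clusters = if (!is.null(scr$clusters)) {
        list(k = scr$clusters$k, labels = as.list(scr$clusters$labels),
             silhouettes = scr$clusters$silhouettes)
      },
      weights = as.list(scr$weights),
      scaled_variances = as.list(scr$scaled_variances),
      F_prime = scr$F_prime, F_doubleprime = scr$F_doubleprime,
      F_star = scr$F_star
    ))
    p <- file.path(out_dir, "screen.json")
    jsonlite::write_json(screen_json, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    report_json <- c(meta, list(
      summary = bundle$summary,
      verdicts = lapply(bundle$results, `[[`, "verdict"),
      sweeps = lapply(bundle$results, function(r) {
        list(replacement = r$replacement$summary, gaussian = r$gaussian$summary)
      })
    ))
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_json, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot a severity sweep
#'
#' Mean test accuracy (with a +/- one-standard-deviation band) against the
#' noise level, in the style of the accuracy-decay curves the Monte Carlo
#' protocol produces.
#'
#' @param x A `sweep_result`.
#' @param ... Passed to [plot()].
#' @export
plot.sweep_result <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$level, s$mean_test_acc, type = "b", pch = 16,
                 ylim = c(0.4, 1), xlab = sprintf("noise level (%s)", x$kind),
                 ylab = "mean test accuracy", ...)
  sdv <- sqrt(s$var_test_acc)
  graphics::arrows(s$level, s$mean_test_acc - sdv, s$level,
                   s$mean_test_acc + sdv, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
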