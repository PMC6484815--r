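#' Analyse a synthetic cohort end to end
#'
#' For every subject of a [simulate_cohort()] cohort: simulate the sampled
#' fluorescence curve from the subject's kinetic ground truth, fit the
#' perfusion parameters ([fit_perfusion()]) and classify the perfusion status
#' ([perfusion_status()]). Subjects whose curve shows no detectable perfusion
#' are kept with `NA` estimates and flagged.
#'
#' Per-subject recording duration adapts to the subject's kinetics
#' (onset + rise + a margin), capped by `max_duration`.
#'
#' @param cohort A `perfusion_cohort` from [simulate_cohort()].
#' @param frame_rate Sampling rate of the simulated curves (fps).
#' @param control A [perfusion_control()].
#' @param cutoffs A [perfusion_cutoffs()].
#' @param seed Integer seed for the curve noise.
#' @param margin Seconds of plateau recorded past the end of the rise.
#' @param max_duration Recording cap (s).
#' @return A data.frame (class `perfusion_cohort_fit`): per subject the true
#'   generative parameters (`true_*`), the estimates (`est_*`), `censored`,
#'   `no_perfusion`, the per-factor categories, the slow flags and the
#'   `risk_zone`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_no_complication = 8, n_complication = 2),
#'                        seed = 1)
#' res <- analyze_cohort(coh, frame_rate = 5, seed = 1)
#' table(res$risk_zone, res$outcome)
#' @export
analyze_cohort <- function(cohort, frame_rate = 5,
                           control = perfusion_control(),
                           cutoffs = perfusion_cutoffs(), seed = 1L,
                           margin = 60, max_duration = 360) {
  stopifnot(inherits(cohort, "perfusion_cohort") || is.data.frame(cohort))
  n <- nrow(cohort)
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      truth <- cohort_truth(cohort, i)
      duration <- min(max(120, truth$onset_t0 + truth$rise_duration + margin),
                      max_duration)
      if (duration <= truth$onset_t0 + truth$rise_duration) {
        duration <- truth$onset_t0 + truth$rise_duration + margin
      }
      pc <- simulate_curve(truth, frame_rate = frame_rate, duration = duration)
      fit <- tryCatch(
        withCallingHandlers(
          fit_perfusion(pc, control),
          icg_peak_censored = function(w) invokeRestart("muffleWarning")
        ),
        icg_no_perfusion = function(e) NULL
      )
      base <- data.frame(
        subject = cohort$subject[i], outcome = cohort$outcome[i],
        true_slope = cohort$slope[i], true_t_max = cohort$t_max[i],
        true_tr = cohort$tr[i],
        true_t_half_max = cohort$t_max[i] * cohort$tr[i]
      )
      if (is.null(fit)) {
        cbind(base, data.frame(
          est_slope = NA_real_, est_t_max = NA_real_,
          est_t_half_max = NA_real_, est_tr = NA_real_,
          est_f_min = NA_real_, est_delta_f = NA_real_,
          censored = NA, no_perfusion = TRUE,
          cat_slope = NA_character_, cat_t_half_max = NA_character_,
          cat_tr = NA_character_, slow_tr = NA, slow_t_half_max = NA,
          slow_slope = NA, risk_zone = NA_character_
        ))
      } else {
        st <- perfusion_status(fit, cutoffs)
        p <- fit$params
        cbind(base, data.frame(
          est_slope = p$slope, est_t_max = p$t_max,
          est_t_half_max = p$t_half_max, est_tr = p$tr,
          est_f_min = p$f_min, est_delta_f = p$delta_f,
          censored = p$censored, no_perfusion = FALSE,
          cat_slope = st$category[["slope"]],
          cat_t_half_max = st$category[["t_half_max"]],
          cat_tr = st$category[["tr"]],
          slow_tr = st$slow[["tr"]],
          slow_t_half_max = st$slow[["t_half_max"]],
          slow_slope = st$slow[["slope"]],
          risk_zone = as.character(st$risk_zone)
        ))
      }
    })
    out <- do.call(rbind, rows)
    class(out) <- c("perfusion_cohort_fit", "data.frame")
    out
  })
}

#' Cohort-level diagnostic evaluation
#'
#' Evaluates the perfusion factors of an analysed cohort as predictors of the
#' outcome: per-factor ROC analysis (time factors with risk direction
#' "greater", slope with "less"), diagnostic values of the slow / not-slow
#' split at the configured cut-offs, and complication rates per risk zone.
#' Subjects without detectable perfusion are excluded (with a count kept).
#'
#' @param results A `perfusion_cohort_fit` from [analyze_cohort()].
#' @param cutoffs A [perfusion_cutoffs()].
#' @return An object of class `perfusion_evaluation`: list with `roc` (per
#'   factor), `diagnostics` (per factor), `zones` (data.frame from
#'   [zone_rates()]), `incidence`, `n`, `n_excluded`.
#' @export
evaluate_cohort <- function(results, cutoffs = perfusion_cutoffs()) {
  stopifnot(is.data.frame(results))
  keep <- !results$no_perfusion & !is.na(results$est_tr)
  n_excluded <- sum(!keep)
  r <- results[keep, , drop = FALSE]
  if (length(unique(r$outcome)) < 2L) {
    stop("both outcome classes must be present for evaluation (empty class)",
         call. = FALSE)
  }
  roc <- list(
    slope = roc_analysis(r$est_slope, r$outcome, direction = "less"),
    t_half_max = roc_analysis(r$est_t_half_max, r$outcome,
                              direction = "greater"),
    tr = roc_analysis(r$est_tr, r$outcome, direction = "greater")
  )
  diagnostics <- list(
    slope = diagnostic_values(contingency_2x2(predicted = r$slow_slope,
                                              outcome = r$outcome)),
    t_half_max = diagnostic_values(contingency_2x2(predicted = r$slow_t_half_max,
                                                   outcome = r$outcome)),
    tr = diagnostic_values(contingency_2x2(predicted = r$slow_tr,
                                           outcome = r$outcome))
  )
  zones <- zone_rates(factor(r$risk_zone, levels = zone_levels), r$outcome)
  structure(
    list(roc = roc, diagnostics = diagnostics, zones = zones,
         incidence = mean(r$outcome), n = nrow(r), n_excluded = n_excluded),
    class = "perfusion_evaluation"
  )
}

#' @export
print.perfusion_evaluation <- function(x, ...) {
  cat(sprintf("Cohort evaluation: n = %d (%d excluded), incidence %.1f%%\n",
              x$n, x$n_excluded, 100 * x$incidence))
  for (f in names(x$roc)) {
    cat(sprintf("  %-10s AUC %.3f, Youden cut-off %.3g\n", f, x$roc[[f]]$auc,
                x$roc[[f]]$chosen_cutoff))
  }
  cat("  risk zones:\n")
  z <- x$zones
  for (i in seq_len(nrow(z))) {
    cat(sprintf("    %-12s %d/%d%s\n", z$zone[i], z$events[i], z$total[i],
                if (is.na(z$pct[i])) "" else sprintf(" (%.1f%%)", z$pct[i])))
  }
  invisible(x)
}
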