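#' Perfusion classification cut-offs
#'
#' Per-factor cut-offs splitting perfusion into fast / moderate / slow, with
#' the published defaults: slope fast > 1.0 AU/s, slow < 0.7 AU/s; T_1/2MAX
#' fast < 10 s, slow > 18 s; TR fast < 0.4, slow > 0.6. All inequalities are
#' strict: a value equal to a bound is moderate.
#'
#' @param slope_fast_gt,slope_slow_lt Slope bounds (AU/s); fast bound must
#'   exceed the slow bound so a moderate band exists.
#' @param thalf_fast_lt,thalf_slow_gt T_1/2MAX bounds (s); fast bound below
#'   the slow bound.
#' @param tr_fast_lt,tr_slow_gt TR bounds (dimensionless).
#' @return An object of class `perfusion_cutoffs`.
#' @export
perfusion_cutoffs <- function(slope_fast_gt = 1.0, slope_slow_lt = 0.7,
                              thalf_fast_lt = 10, thalf_slow_gt = 18,
                              tr_fast_lt = 0.4, tr_slow_gt = 0.6) {
  if (slope_fast_gt <= slope_slow_lt) {
    stop("slope bounds must leave a moderate band: fast bound > slow bound",
         call. = FALSE)
  }
  if (thalf_fast_lt >= thalf_slow_gt || tr_fast_lt >= tr_slow_gt) {
    stop("time-factor bounds must leave a moderate band: fast bound < slow bound",
         call. = FALSE)
  }
  structure(
    list(slope_fast_gt = slope_fast_gt, slope_slow_lt = slope_slow_lt,
         thalf_fast_lt = thalf_fast_lt, thalf_slow_gt = thalf_slow_gt,
         tr_fast_lt = tr_fast_lt, tr_slow_gt = tr_slow_gt),
    class = "perfusion_cutoffs"
  )
}

#' @export
print.perfusion_cutoffs <- function(x, ...) {
  cat("Perfusion cut-offs (boundary values are moderate)\n")
  cat(sprintf("  slope:      fast > %g AU/s, slow < %g AU/s\n",
              x$slope_fast_gt, x$slope_slow_lt))
  cat(sprintf("  T_1/2MAX:   fast < %g s,    slow > %g s\n",
              x$thalf_fast_lt, x$thalf_slow_gt))
  cat(sprintf("  TR:         fast < %g,      slow > %g\n",
              x$tr_fast_lt, x$tr_slow_gt))
  invisible(x)
}

zone_levels <- c("safe", "intermediate", "dangerous", "critical")
category_levels <- c("fast", "moderate", "slow")

#' Classify a perfusion factor as fast / moderate / slow
#'
#' Strict-inequality three-way split: for the slope, larger is faster; for the
#' time factors (`t_half_max`, `tr`), smaller is faster. Values falling on or
#' between the bounds are moderate. Vectorised over `value`.
#'
#' @param value Numeric factor value(s); must be finite.
#' @param factor_name One of `"slope"`, `"t_half_max"`, `"tr"`.
#' @param cutoffs A [perfusion_cutoffs()].
#' @return A factor with levels `fast`, `moderate`, `slow`.
#' @examples
#' classify_factor(c(0.39, 0.5, 0.65), "tr")
#' @export
classify_factor <- function(value, factor_name,
                            cutoffs = perfusion_cutoffs()) {
  if (length(factor_name) != 1L ||
      !factor_name %in% c("slope", "t_half_max", "tr")) {
    stop("configuration error: unknown factor name ",
         deparse(substitute(factor_name)), call. = FALSE)
  }
  value <- as.numeric(value)
  if (any(!is.finite(value))) {
    stop("factor values must be finite", call. = FALSE)
  }
  out <- rep("moderate", length(value))
  if (factor_name == "slope") {
    out[value > cutoffs$slope_fast_gt] <- "fast"
    out[value < cutoffs$slope_slow_lt] <- "slow"
  } else if (factor_name == "t_half_max") {
    out[value < cutoffs$thalf_fast_lt] <- "fast"
    out[value > cutoffs$thalf_slow_gt] <- "slow"
  } else {
    out[value < cutoffs$tr_fast_lt] <- "fast"
    out[value > cutoffs$tr_slow_gt] <- "slow"
  }
  factor(out, levels = category_levels)
}

#' Two-factor risk-zone assignment
#'
#' Step-by-step flow chart for anastomotic-complication risk: step 1 screens
#' on the T_1/2MAX category (a sensitive detector of slow reperfusion), step 2
#' refines on the TR category (a specific one). The four zones, ordered by
#' severity, are:
#' * `safe` — both factors fast;
#' * `intermediate` — neither factor slow, but not both fast;
#' * `dangerous` — exactly one factor slow;
#' * `critical` — both factors slow.
#'
#' Assigning the mixed quadrants (one slow, one not) to `dangerous` is a
#' documented package choice; the mapping is exposed through `zone_map` so
#' alternative conventions are reproducible.
#'
#' A fit whose `t_max` was censored at the analysis-window end is forced to at
#' least `dangerous` (censoring means perfusion was still incomplete when
#' observation stopped, which is treated conservatively as slow).
#'
#' @param params A [perfusion_params()] or [fit_perfusion()] result, or `NULL`
#'   when `t_half_max` and `tr` are given directly.
#' @param cutoffs A [perfusion_cutoffs()].
#' @param t_half_max,tr Factor values, used when `params` is `NULL`.
#' @param censored Logical; overrides the `censored` flag of `params`.
#' @param zone_map A 3x3 character matrix (rows: T_1/2MAX category, columns:
#'   TR category, both ordered fast/moderate/slow) of zone names.
#' @return A factor with ordered levels `safe`, `intermediate`, `dangerous`,
#'   `critical`.
#' @examples
#' risk_zone(t_half_max = 8, tr = 0.3)    # safe
#' risk_zone(t_half_max = 40, tr = 0.7)   # critical
#' @export
risk_zone <- function(params = NULL, cutoffs = perfusion_cutoffs(),
                      t_half_max = NULL, tr = NULL, censored = NULL,
                      zone_map = default_zone_map()) {
  if (!is.null(params)) {
    if (inherits(params, "perfusion_fit")) params <- params$params
    t_half_max <- params$t_half_max
    tr <- params$tr
    if (is.null(censored)) censored <- params$censored
  }
  if (is.null(censored)) censored <- FALSE
  thalf_cat <- classify_factor(t_half_max, "t_half_max", cutoffs)
  tr_cat <- classify_factor(tr, "tr", cutoffs)
  zone <- zone_map[cbind(as.integer(thalf_cat), as.integer(tr_cat))]
  zone <- factor(zone, levels = zone_levels, ordered = TRUE)
  if (isTRUE(censored)) {
    zone[zone < "dangerous"] <- "dangerous"
  }
  zone
}

#' @rdname risk_zone
#' @export
default_zone_map <- function() {
  matrix(c(
    #         TR fast        TR moderate     TR slow
    "safe",         "intermediate", "dangerous",   # T1/2 fast
    "intermediate", "intermediate", "dangerous",   # T1/2 moderate
    "dangerous",    "dangerous",    "critical"     # T1/2 slow
  ), nrow = 3, byrow = TRUE,
  dimnames = list(category_levels, category_levels))
}

#' Full perfusion status of a fitted curve
#'
#' Combines the per-factor fast/moderate/slow categories, the binary slow
#' flags (the slow / not-slow split used for diagnostic evaluation), and the
#' two-factor risk zone. Surgical implications attached to the worse zones
#' (moving the transection line, diverting ileostomy, end colostomy) are
#' reported as informational text only.
#'
#' @param params A [perfusion_params()] or [fit_perfusion()] result.
#' @param cutoffs A [perfusion_cutoffs()].
#' @return An object of class `perfusion_status`: list with `category` (named
#'   factor vector over slope, t_half_max, tr), `slow` (named logical),
#'   `risk_zone`, `censored` and `advice` (informational string).
#' @export
perfusion_status <- function(params, cutoffs = perfusion_cutoffs()) {
  if (inherits(params, "perfusion_fit")) params <- params$params
  vals <- c(slope = params$slope, t_half_max = params$t_half_max,
            tr = params$tr)
  category <- c(
    slope = as.character(classify_factor(vals["slope"], "slope", cutoffs)),
    t_half_max = as.character(classify_factor(vals[["t_half_max"]],
                                              "t_half_max", cutoffs)),
    tr = as.character(classify_factor(vals[["tr"]], "tr", cutoffs))
  )
  slow <- category == "slow"
  if (isTRUE(params$censored)) {
    # incomplete inflow at window end is treated as slow time factors
    slow[c("t_half_max", "tr")] <- slow[c("t_half_max", "tr")] |
      category[c("t_half_max", "tr")] == "slow"
  }
  zone <- risk_zone(params, cutoffs)
  advice <- switch(as.character(zone),
    safe = "fast perfusion; minimal anastomotic risk expected",
    intermediate = "moderate perfusion; standard management",
    dangerous = paste("one slow time factor; consider perfusion-improving",
                      "measures (splenic flexure mobilization, low IMA",
                      "ligation, diverting ileostomy) [informational only]"),
    critical = paste("both time factors slow; consider moving the transection",
                     "line proximally or end colostomy instead of primary",
                     "anastomosis [informational only]")
  )
  structure(
    list(values = vals, category = category, slow = slow, risk_zone = zone,
         censored = isTRUE(params$censored), advice = advice),
    class = "perfusion_status"
  )
}

#' @export
print.perfusion_status <- function(x, ...) {
  cat("Perfusion status\n")
  for (f in names(x$category)) {
    cat(sprintf("  %-10s %8.4g  -> %s%s\n", f, x$values[[f]], x$category[[f]],
                if (x$slow[[f]]) " (slow)" else ""))
  }
  cat(sprintf("  risk zone: %s%s\n", as.character(x$risk_zone),
              if (x$censored) " (t_max censored)" else ""))
  cat("  note:", x$advice, "\n")
  invisible(x)
}
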