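#' Round half-up to a fixed number of decimals
#'
#' Clinical tables conventionally round 0.5 up (so 62.45 -> 62.5), unlike
#' [base::round()]'s round-half-even. Used for rendering percentages.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' 2x2 contingency table of a binary predictor against outcomes
#'
#' @param tp,fp,fn,tn Non-negative counts (true positive, false positive,
#'   false negative, true negative). Alternatively supply logical/0-1 vectors
#'   `predicted` and `outcome` to tabulate.
#' @param predicted,outcome Optional aligned binary vectors, used when the
#'   counts are not given directly.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77)
#' @export
contingency_2x2 <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                            predicted = NULL, outcome = NULL) {
  if (!is.null(predicted)) {
    if (length(predicted) != length(outcome)) {
      stop("`predicted` and `outcome` must have the same length", call. = FALSE)
    }
    p <- as.logical(predicted)
    o <- as.logical(outcome)
    tp <- sum(p & o); fp <- sum(p & !o); fn <- sum(!p & o); tn <- sum(!p & !o)
  }
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("table total must be > 0", call. = FALSE)
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              outcome = c("event", "no event")))
  print(m)
  invisible(x)
}

ratio_metric <- function(num, den, what) {
  if (den == 0) {
    list(value = NA_real_, num = num, den = den, pct = NA_real_,
         undefined = TRUE, reason = paste0(what, " undefined: zero denominator"))
  } else {
    list(value = num / den, num = num, den = den,
         pct = round_half_up(100 * num / den, 1), undefined = FALSE,
         reason = NULL)
  }
}

#' Diagnostic values of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values `tp/(tp+fp)`, `tn/(tn+fn)` and accuracy
#' `(tp+tn)/total`, each carried as an exact fraction with its counts and a
#' half-up one-decimal percentage. Ratios with a zero denominator are flagged
#' undefined rather than silently reported as 0.
#'
#' @param table A [contingency_2x2()].
#' @return An object of class `diagnostic_result`: named list of metrics, each
#'   with `value`, `num`, `den`, `pct`, `undefined`.
#' @examples
#' diagnostic_values(contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77))
#' @export
diagnostic_values <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  out <- list(
    sensitivity = ratio_metric(tp, tp + fn, "sensitivity"),
    specificity = ratio_metric(tn, tn + fp, "specificity"),
    ppv = ratio_metric(tp, tp + fp, "PPV"),
    npv = ratio_metric(tn, tn + fn, "NPV"),
    accuracy = ratio_metric(tp + tn, tp + fp + fn + tn, "accuracy")
  )
  structure(out, class = "diagnostic_result", table = table)
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("Diagnostic values\n")
  for (nm in names(x)) {
    m <- x[[nm]]
    if (m$undefined) {
      cat(sprintf("  %-12s undefined (%d/%d)\n", nm, m$num, m$den))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%d/%d)\n", nm, m$pct, m$num, m$den))
    }
  }
  invisible(x)
}

#' Per-zone complication rates
#'
#' Complication fraction per risk zone (or per any categorical status), with
#' exact counts. Empty zones are reported with count 0 and an undefined rate.
#' Either supply aligned `zones` and `outcomes` vectors, or precomputed
#' `events` and `totals` counts (named vectors).
#'
#' @param zones Factor/character vector of zone labels per subject.
#' @param outcomes Binary outcome vector (1 = complication), aligned.
#' @param events,totals Optional named count vectors, used instead of the
#'   per-subject vectors.
#' @return A data.frame with columns `zone`, `events`, `total`, `rate`,
#'   `pct` (half-up, one decimal; `NA` for empty zones).
#' @examples
#' zone_rates(events = c(safe = 0, intermediate = 1, dangerous = 5),
#'            totals = c(safe = 47, intermediate = 31, dangerous = 8))
#' @export
zone_rates <- function(zones = NULL, outcomes = NULL, events = NULL,
                       totals = NULL) {
  if (is.null(events)) {
    if (length(zones) != length(outcomes)) {
      stop("`zones` and `outcomes` must be aligned and of equal length",
           call. = FALSE)
    }
    outcomes <- as.integer(as.logical(outcomes))
    zones <- if (is.factor(zones)) zones else factor(zones)
    events <- tapply(outcomes, zones, sum)
    totals <- tapply(outcomes, zones, length)
    events[is.na(events)] <- 0L
    totals[is.na(totals)] <- 0L
  } else {
    if (is.null(totals) || length(events) != length(totals)) {
      stop("`events` and `totals` must be aligned and of equal length",
           call. = FALSE)
    }
    if (any(events > totals)) {
      stop("`events` cannot exceed `totals`", call. = FALSE)
    }
  }
  rate <- ifelse(totals > 0, events / totals, NA_real_)
  data.frame(
    zone = names(events) %||% as.character(seq_along(events)),
    events = as.integer(events), total = as.integer(totals),
    rate = as.numeric(rate),
    pct = ifelse(is.na(rate), NA_real_, round_half_up(100 * rate, 1)),
    row.names = NULL
  )
}

# Brute-force tie-aware Mann-Whitney AUC; O(n1*n0), used internally only as a
# fallback-free reference for small inputs (tests use their own copy).
mw_auc <- function(values, outcomes) {
  pos <- values[outcomes == 1]
  neg <- values[outcomes == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC analysis with cut-off selection
#'
#' Empirical (tie-aware trapezoidal) ROC curve of a perfusion factor against
#' a binary outcome. The AUC is always reported in the "larger value implies
#' complication" orientation, so a protective factor such as the slope
#' yields an AUC below 0.5 (with the flipped value reported alongside for
#' clarity) instead of being silently reoriented. The confidence interval
#' uses the DeLong variance estimator by default, with a seeded bootstrap
#' fallback. The cut-off maximises Youden's J (sensitivity + specificity - 1)
#' in the stated risk `direction`, evaluated at midpoints between adjacent
#' distinct values; ties are broken toward the higher-specificity threshold.
#'
#' @param values Numeric factor values.
#' @param outcomes Binary outcomes (1 = complication), aligned with `values`.
#' @param direction `"greater"` when larger values indicate complication
#'   (time factors), `"less"` when smaller values do (slope).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf Confidence level.
#' @param boot_n Bootstrap replicates for `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap CI.
#' @return An object of class `roc_result`: list with `auc` (greater
#'   orientation), `auc_flipped`, `ci_low`, `ci_high`, `chosen_cutoff`,
#'   `sensitivity`/`specificity` at the cut-off, `direction` and `curve`
#'   (data.frame of threshold, sensitivity, specificity in the risk
#'   direction).
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1: perfect separation
#' @export
roc_analysis <- function(values, outcomes, direction = c("greater", "less"),
                         ci_method = c("delong", "bootstrap"), conf = 0.95,
                         boot_n = 2000, seed = 1L) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  outcomes <- as.integer(as.logical(outcomes))
  if (length(values) != length(outcomes)) {
    stop("`values` and `outcomes` must have the same length", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2L) {
    stop("undefined AUC: both outcome classes must be present", call. = FALSE)
  }
  constant <- length(unique(values)) == 1L
  if (constant) {
    auc <- 0.5
    ci <- c(NA_real_, NA_real_)
  } else {
    r <- pROC::roc(response = outcomes, predictor = values, direction = "<",
                   quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    ci <- suppressWarnings(if (ci_method == "delong") {
      as.numeric(pROC::ci.auc(r, method = "delong", conf.level = conf))[c(1, 3)]
    } else {
      with_seed(seed,
        as.numeric(pROC::ci.auc(r, method = "bootstrap", conf.level = conf,
                                boot.n = boot_n, progress = "none"))[c(1, 3)])
    })
    ci <- pmin(pmax(ci, 0), 1)
  }

  # Youden cut-off in the stated risk direction
  sv <- sort(unique(values))
  thr <- if (length(sv) > 1L) (sv[-1] + sv[-length(sv)]) / 2 else sv
  thr <- c(min(sv) - 1, thr, max(sv) + 1)
  npos <- sum(outcomes == 1L); nneg <- sum(outcomes == 0L)
  stat <- vapply(thr, function(th) {
    pred <- if (direction == "greater") values > th else values < th
    c(sens = sum(pred & outcomes == 1L) / npos,
      spec = sum(!pred & outcomes == 0L) / nneg)
  }, c(sens = 0, spec = 0))
  j <- stat["sens", ] + stat["spec", ] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(stat["spec", best])]
  structure(
    list(auc = auc, auc_flipped = 1 - auc, ci_low = ci[1], ci_high = ci[2],
         conf = conf, ci_method = if (constant) NA_character_ else ci_method,
         chosen_cutoff = thr[best],
         sensitivity = unname(stat["sens", best]),
         specificity = unname(stat["spec", best]),
         direction = direction,
         curve = data.frame(threshold = thr, sensitivity = stat["sens", ],
                            specificity = stat["spec", ]),
         n_pos = npos, n_neg = nneg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis (%d events / %d non-events)\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (larger => complication orientation; flipped %.3f)\n",
              x$auc, x$auc_flipped))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %d%% CI %.3f-%.3f (%s)\n", round(100 * x$conf),
                x$ci_low, x$ci_high, x$ci_method))
  }
  cat(sprintf("  Youden cut-off %.4g (risk when value %s cut-off): sens %.3f, spec %.3f\n",
              x$chosen_cutoff, if (x$direction == "greater") ">" else "<",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  graphics::plot(1 - x$curve$specificity[o], x$curve$sensitivity[o],
                 type = "l", xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (tp * tn) / (fp * fn)` with a Wald log-scale confidence interval.
#' Tables containing a zero cell get the Haldane-Anscombe 0.5 continuity
#' correction (flagged in the result). When a full row or column of the table
#' is zero the OR is undefined and returned as `NA` with a reason.
#'
#' @param table A [contingency_2x2()].
#' @param conf Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`, `corrected`, `undefined`,
#'   `reason`; class `odds_ratio_result`.
#' @examples
#' odds_ratio(contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77))$or  # 128.33
#' @export
odds_ratio <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$tp; b <- table$fp; c_ <- table$fn; d <- table$tn
  rowcol_zero <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
  if (rowcol_zero) {
    return(structure(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          corrected = FALSE, undefined = TRUE,
                          reason = "a full row or column of the table is zero"),
                     class = "odds_ratio_result"))
  }
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(or = or, ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se), corrected = corrected,
         undefined = FALSE, reason = NULL),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  if (x$undefined) {
    cat("Odds ratio undefined:", x$reason, "\n")
  } else {
    cat(sprintf("OR %.2f (95%% CI %.2f-%.2f)%s\n", x$or, x$ci_low, x$ci_high,
                if (x$corrected) "  [Haldane-Anscombe 0.5 correction]" else ""))
  }
  invisible(x)
}

#' Binary logistic regression on dichotomised covariates
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on binary covariates, reporting
#' per-covariate odds ratios with Wald confidence intervals and p-values.
#' Quasi- or complete separation — likely with few events, and recognisable
#' by enormous estimates and intervals — is detected and flagged
#' diagnostically rather than silently reported.
#'
#' @param x Matrix or data.frame of covariates (will be coerced to numeric).
#' @param outcomes Binary outcome vector (1 = event).
#' @param conf Confidence level.
#' @return An object of class `logistic_result`: data.frame `coefficients`
#'   with columns `estimate`, `or`, `ci_low`, `ci_high`, `p`, plus flags
#'   `converged` and `separation`.
#' @export
logistic_model <- function(x, outcomes, conf = 0.95) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  outcomes <- as.integer(as.logical(outcomes))
  n <- length(outcomes)
  if (nrow(x) != n) stop("covariates and outcomes must be aligned", call. = FALSE)
  if (ncol(x) >= n) {
    stop("need fewer covariates than observations", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: covariates are linearly dependent",
         call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, outcomes, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(fit$coefficients) > 15)
  co <- fit$coefficients
  # Wald covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(
    estimate = co, or = exp(co),
    ci_low = exp(co - z * se), ci_high = exp(co + z * se),
    p = 2 * stats::pnorm(-abs(co / se)),
    row.names = colnames(X)
  )
  structure(
    list(coefficients = tab, converged = fit$converged,
         separation = separation, n = n, n_events = sum(outcomes)),
    class = "logistic_result"
  )
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("Logistic regression (%d events / %d observations)\n",
              x$n_events, x$n))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) {
    cat("  WARNING: (quasi-)separation detected; estimates and intervals unreliable\n")
  }
  print(round(x$coefficients[-1, c("or", "ci_low", "ci_high", "p")], 4))
  invisible(x)
}
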