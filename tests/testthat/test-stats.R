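test_that("diagnostic values carry exact fractions and flag zero denominators", {
  dv <- diagnostic_values(contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77))
  expect_equal(dv$sensitivity$value, 5 / 6)
  expect_equal(dv$sensitivity$pct, 83.3)
  expect_equal(dv$accuracy$num, 82)
  expect_equal(dv$accuracy$den, 86)
  empty_pos <- diagnostic_values(contingency_2x2(tp = 0, fp = 0, fn = 0,
                                                 tn = 10))
  expect_true(empty_pos$sensitivity$undefined)
  expect_true(empty_pos$ppv$undefined)
  expect_equal(empty_pos$specificity$pct, 100)
  expect_false(empty_pos$specificity$undefined)
})

test_that("accuracy is the prevalence-weighted combination of sensitivity and specificity", {
  set.seed(31)
  for (i in 1:20) {
    cells <- rpois(4, 10) + 1
    tab <- contingency_2x2(tp = cells[1], fp = cells[2], fn = cells[3],
                           tn = cells[4])
    dv <- diagnostic_values(tab)
    prev <- (tab$tp + tab$fn) / (tab$tp + tab$fp + tab$fn + tab$tn)
    expect_equal(dv$accuracy$value,
                 prev * dv$sensitivity$value + (1 - prev) * dv$specificity$value)
  }
})

test_that("2x2 construction validates counts and tabulates vectors", {
  expect_error(contingency_2x2(tp = -1, fp = 0, fn = 0, tn = 2), "non-negative")
  expect_error(contingency_2x2(tp = 0, fp = 0, fn = 0, tn = 0), "total")
  tab <- contingency_2x2(predicted = c(1, 1, 0, 0, 1),
                         outcome = c(1, 0, 1, 0, 1))
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 1))
})

test_that("zone rates reproduce counts, flag empty zones, and match vector input", {
  zr <- zone_rates(events = c(safe = 0, intermediate = 1, dangerous = 5),
                   totals = c(safe = 47, intermediate = 31, dangerous = 8))
  expect_equal(zr$pct, c(0, 3.2, 62.5))
  empty <- zone_rates(zones = factor(rep("safe", 4),
                                     levels = c("safe", "dangerous")),
                      outcomes = c(0, 0, 1, 0))
  expect_equal(empty$total, c(4L, 0L))
  expect_true(is.na(empty$rate[2]))
  expect_equal(empty$rate[1], 0.25)
  # all subjects in one zone: rate equals overall incidence
  one <- zone_rates(zones = rep("dangerous", 10),
                    outcomes = c(rep(1, 3), rep(0, 7)))
  expect_equal(one$rate, 0.3)
})

test_that("AUC equals the brute-force pairwise Mann-Whitney oracle", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    out <- c(0, 1, rbinom(n - 2, 1, 0.3))
    vals <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    r <- roc_analysis(vals, out)
    expect_equal(r$auc, pairwise_auc(vals, out), tolerance = 1e-12)
  }
})

test_that("ROC degenerate cases: perfect separation and ties-only", {
  perf <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perf$auc, 1.0)
  expect_equal(perf$ci_low, 1.0)
  ties <- roc_analysis(rep(5, 8), c(0, 1, 0, 1, 0, 1, 0, 0))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("DeLong interval brackets the AUC and bootstrap agrees roughly", {
  set.seed(8)
  vals <- c(rnorm(60, 0), rnorm(15, 1.5))
  out <- rep(c(0, 1), c(60, 15))
  r <- roc_analysis(vals, out)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  b <- roc_analysis(vals, out, ci_method = "bootstrap", boot_n = 500, seed = 3)
  expect_equal(b$auc, r$auc)
  expect_lt(abs(b$ci_low - r$ci_low), 0.1)
})

test_that("the Youden cut-off separates well-separated groups", {
  for (s in 1:40) {
    set.seed(400 + s)
    tr <- c(rnorm(1700, 0.40, 0.05), rnorm(300, 0.65, 0.05))
    out <- rep(c(0, 1), c(1700, 300))
    r <- roc_analysis(tr, out, direction = "greater")
    expect_gt(r$chosen_cutoff, 0.40)
    expect_lt(r$chosen_cutoff, 0.65)
  }
})

test_that("risk direction drives cut-off orientation while AUC keeps the raw orientation", {
  vals <- c(2.4, 2.6, 2.1, 3.0, 0.5, 0.8)  # small slope => complication
  out <- c(0, 0, 0, 0, 1, 1)
  r <- roc_analysis(vals, out, direction = "less")
  expect_lt(r$auc, 0.5)           # printed as-is, below 0.5
  expect_equal(r$auc_flipped, 1 - r$auc)
  expect_equal(r$sensitivity, 1)  # cut-off achieves the separation
  expect_equal(r$specificity, 1)
  expect_gt(r$chosen_cutoff, 0.8)
  expect_lt(r$chosen_cutoff, 2.1)
})

test_that("odds ratio matches the arithmetic oracle and handles zero cells", {
  or <- odds_ratio(contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77))
  expect_equal(or$or, (5 * 77) / (3 * 1), tolerance = 1e-12)
  expect_false(or$corrected)
  expect_lt(or$ci_low, or$or)
  expect_gt(or$ci_high, or$or)
  expect_equal(odds_ratio(contingency_2x2(tp = 1, fp = 1, fn = 1, tn = 1))$or, 1)
  corr <- odds_ratio(contingency_2x2(tp = 6, fp = 13, fn = 0, tn = 67))
  expect_true(corr$corrected)
  expect_true(is.finite(corr$or))
  und <- odds_ratio(contingency_2x2(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(und$undefined)
})

test_that("single-covariate logistic regression reproduces the contingency OR", {
  # cohort realizing tp=5, fp=3, fn=1, tn=77
  slow <- rep(c(1, 1, 0, 0), c(5, 3, 1, 77))
  out <- rep(c(1, 0, 1, 0), c(5, 3, 1, 77))
  fit <- logistic_model(cbind(slow_tr = slow), out)
  expect_equal(fit$coefficients["slow_tr", "or"], (5 * 77) / (3 * 1),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("null covariates produce intervals covering 1 in most replicates", {
  base_cov <- rep(c(1, 0), c(20, 66))
  out <- rep(c(1, 0), c(10, 76))
  cover <- vapply(1:100, function(s) {
    set.seed(600 + s)
    cov_perm <- sample(base_cov)
    fit <- logistic_model(cbind(x = cov_perm), out)
    fit$coefficients["x", "ci_low"] <= 1 && fit$coefficients["x", "ci_high"] >= 1
  }, NA)
  expect_gte(mean(cover), 0.9)
})

test_that("rank deficiency and separation are reported, not silently estimated", {
  x <- rep(c(1, 0), c(10, 20))
  expect_error(logistic_model(cbind(a = x, b = x), rbinom(30, 1, 0.3)),
               "rank-deficient")
  sep <- logistic_model(cbind(x = x), x)  # covariate identical to outcome
  expect_true(sep$separation)
  expect_error(logistic_model(cbind(x = x[1:10]), rep(0:1, 10)), "aligned")
})

test_that("half-up rounding matches clinical table conventions", {
  expect_equal(round_half_up(62.45, 1), 62.5)
  expect_equal(round_half_up(83.33, 1), 83.3)
  expect_equal(round_half_up(6.976744, 0), 7)
  expect_equal(round_half_up(-2.5, 0), -3)
})
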