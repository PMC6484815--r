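#' Published reference cohort summaries
#'
#' Summary statistics of an 86-patient laparoscopic colorectal cancer cohort
#' (80 without / 6 with anastomotic complications requiring invasive
#' treatment) in which quantitative ICG angiography was evaluated. These
#' numbers calibrate the synthetic cohort generator ([cohort_spec()] defaults)
#' and let the diagnostic machinery be exercised on the published counts.
#'
#' Components:
#' \describe{
#'   \item{n, n_complication}{cohort size 86 and the enumerated complications
#'     (colonic necrosis 1, anastomotic leak 3, pelvic abscess 1, delayed
#'     dehiscence 1 = 6 events).}
#'   \item{group_stats}{per-group mean and standard error (mean +/- SE) of the
#'     perfusion factors: F_MIN, dF, slope, T_MAX, T_1/2MAX, TR.}
#'   \item{cutoffs}{the ROC-derived fast/slow cut-offs shipped as
#'     [perfusion_cutoffs()] defaults.}
#'   \item{contingency}{2x2 counts of each slow/not-slow factor split against
#'     complications ([contingency_2x2()] objects).}
#'   \item{zone_counts}{per-zone complication events and totals for each
#'     factor's three-way (fast/moderate/slow) split.}
#'   \item{roc}{the published AUCs, CIs and chosen cut-offs per factor.}
#' }
#'
#' @return A list as described above.
#' @examples
#' ref <- reference_cohort()
#' diagnostic_values(ref$contingency$tr)
#' @export
reference_cohort <- function() {
  list(
    n = 86L,
    n_complication = 6L,
    complication_types = c(colonic_necrosis = 1L, anastomotic_leak = 3L,
                           pelvic_abscess = 1L, delayed_dehiscence = 1L),
    group_stats = data.frame(
      factor = c("f_min", "delta_f", "slope", "t_max", "t_half_max", "tr"),
      mean_no_complication = c(10.6, 58.0, 2.5, 30.3, 11.7, 0.4),
      se_no_complication = c(1.0, 3.4, 0.2, 2.3, 0.8, 0.0),
      mean_complication = c(11.5, 34.9, 0.7, 64.0, 40.37, 0.6),
      se_complication = c(2.5, 7.4, 0.2, 11.7, 7.8, 0.0)
    ),
    cutoffs = perfusion_cutoffs(),
    contingency = list(
      slope = contingency_2x2(tp = 4, fp = 6, fn = 2, tn = 74),
      t_half_max = contingency_2x2(tp = 6, fp = 13, fn = 0, tn = 67),
      tr = contingency_2x2(tp = 5, fp = 3, fn = 1, tn = 77)
    ),
    zone_counts = list(
      slope = list(events = c(safe = 1, intermediate = 1, dangerous = 4),
                   totals = c(safe = 60, intermediate = 16, dangerous = 10)),
      t_half_max = list(events = c(safe = 0, intermediate = 0, dangerous = 6),
                        totals = c(safe = 44, intermediate = 23, dangerous = 19)),
      tr = list(events = c(safe = 0, intermediate = 1, dangerous = 5),
                totals = c(safe = 47, intermediate = 31, dangerous = 8))
    ),
    roc = data.frame(
      factor = c("slope", "t_half_max", "tr"),
      cutoff = c(0.7, 18, 0.6),
      auc = c(0.123, 0.963, 0.929),
      ci_low = c(0.001, 0.910, 0.845),
      ci_high = c(0.245, 1.0, 1.0)
    )
  )
}
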