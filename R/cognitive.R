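#' Binary cognitive outcomes: MoCA cutoff and PACC composite
#'
#' Two complementary classifications are derived for every participant:
#' possible cognitive impairment (PCI) from the Montreal Cognitive Assessment
#' total at the standard `<= 23` cutoff, and poor cognitive performance (PCP)
#' from the preclinical Alzheimer's cognitive composite (PACC), the mean of
#' component z-scores with the timed Trail-Making tests reverse-coded, at one
#' SD below the sample mean.
#'
#' @name cognitive_outcomes
NULL

#' Classify possible cognitive impairment from the MoCA total
#'
#' @param moca_total Integer MoCA totals in 0..30.
#' @param cutoff Inclusive impairment cutoff (default 23).
#' @return Integer 0/1 vector, 1 = possible cognitive impairment.
#' @examples
#' classify_moca(c(23, 24, 30))  # 1 0 0
#' @export
classify_moca <- function(moca_total, cutoff = 23) {
  ok <- is.na(moca_total) | (moca_total >= 0 & moca_total <= 30)
  if (!all(ok))
    stop("classify_moca: MoCA totals must lie in 0..30; offending values: ",
         paste(utils::head(moca_total[!ok], 5), collapse = ", "))
  as.integer(moca_total <= cutoff)
}

#' Compute the PACC z-score composite
#'
#' Each component is z-scored against the analytic sample (n - 1 SD), timed
#' components listed in `reversed` are negated so higher always means better,
#' and the composite is the unweighted mean of the component z-scores.
#'
#' @param data Data frame holding the component columns.
#' @param components Component column names. The default uses four
#'   components: combined free and cued selective-reminding recall, Trails A,
#'   Trails B, and animal-naming fluency. Episodic memory can instead enter
#'   as two components (free and cued recall separately) by naming both
#'   columns here.
#' @param reversed Subset of `components` to reverse-code (timed tests where
#'   larger = worse).
#' @return Numeric vector of PACC scores (sample mean 0 by construction).
#' @export
compute_pacc <- function(data,
                         components = c("free_cued_recall", "trails_a_seconds",
                                        "trails_b_seconds", "animal_naming"),
                         reversed = c("trails_a_seconds", "trails_b_seconds")) {
  missing_cols <- setdiff(components, names(data))
  if (length(missing_cols))
    stop("compute_pacc: missing component columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(data) < 2L) stop("compute_pacc: need >= 2 participants")
  if (length(bad <- setdiff(reversed, components)))
    stop("compute_pacc: reversed names not in components: ",
         paste(bad, collapse = ", "))
  z <- vapply(components, function(comp) {
    x <- data[[comp]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      stop("compute_pacc: component '", comp, "' has zero SD")
    zc <- (x - mean(x, na.rm = TRUE)) / s
    if (comp %in% reversed) -zc else zc
  }, numeric(nrow(data)))
  rowMeans(z)
}

#' Classify poor cognitive performance from PACC scores
#'
#' @param pacc_scores Numeric PACC composite scores for the analytic sample.
#' @param strict If `TRUE` use a strict `<` at the boundary; the default is
#'   the inclusive `<=` used by the index's other one-SD rules.
#' @return Integer 0/1 vector, 1 = poor cognitive performance
#'   (score at or below sample mean - 1 SD).
#' @export
classify_pacc <- function(pacc_scores, strict = FALSE) {
  if (length(pacc_scores) < 2L) stop("classify_pacc: need >= 2 scores")
  s <- stats::sd(pacc_scores, na.rm = TRUE)
  if (!is.finite(s) || s <= 0)
    stop("classify_pacc: degenerate PACC distribution (SD = 0)")
  cut <- mean(pacc_scores, na.rm = TRUE) - s
  if (strict) as.integer(pacc_scores < cut) else as.integer(pacc_scores <= cut)
}

#' Append cognitive labels to a cohort table
#'
#' Adds `pci`, `pacc_score` and `pcp` columns derived from the cohort's raw
#' cognitive measures.
#'
#' @param cohort Data frame with `moca_total` and the PACC component columns.
#' @param ... Passed to [compute_pacc()] (component configuration).
#' @return The cohort with three added columns.
#' @export
cognitive_labels <- function(cohort, ...) {
  cohort$pci <- classify_moca(cohort$moca_total)
  cohort$pacc_score <- compute_pacc(cohort, ...)
  cohort$pcp <- classify_pacc(cohort$pacc_score)
  cohort
}
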