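#' Standard-deviation deprivation thresholds
#'
#' Scale scores are dichotomized against the analytic sample's own mean and
#' standard deviation (n - 1 denominator): deficits at `score <= mean - t*SD`,
#' adverse exposures at `score >= mean + t*SD`. Both boundaries are inclusive.
#' External norms can be supplied to threshold against a reference population
#' instead of the sample.
#'
#' @param scores Numeric vector of scale scores; `NA` propagates to `NA` in
#'   the output.
#' @param threshold_sd Positive SD multiplier (default 1).
#' @param center,scale Optional external norm mean and SD; when omitted the
#'   sample statistics over non-missing scores are used.
#' @param name Indicator name used in error messages.
#' @return Integer 0/1 vector (1 = deprived), `NA` where the score is missing.
#' @examples
#' threshold_deficit(c(0, 0, 0, 10))      # cut at -2.5: nobody deprived
#' threshold_adverse(c(0, 0, 0, 10))      # cut at 7.5: one deprived
#' @export
threshold_deficit <- function(scores, threshold_sd = 1, center = NULL,
                              scale = NULL, name = "indicator") {
  ms <- sd_norms(scores, center, scale, name)
  as.integer(scores <= ms$center - threshold_sd * ms$scale)
}

#' @rdname threshold_deficit
#' @export
threshold_adverse <- function(scores, threshold_sd = 1, center = NULL,
                              scale = NULL, name = "indicator") {
  ms <- sd_norms(scores, center, scale, name)
  as.integer(scores >= ms$center + threshold_sd * ms$scale)
}

sd_norms <- function(scores, center, scale, name) {
  obs <- scores[!is.na(scores)]
  if (is.null(center) || is.null(scale)) {
    if (length(obs) < 2L)
      stop("indicator '", name, "': need >= 2 non-missing scores to compute sample norms")
    center <- center %||% mean(obs)
    scale <- scale %||% stats::sd(obs)
  }
  if (!is.finite(scale) || scale <= 0)
    stop("indicator '", name, "': degenerate scale (SD = 0); cannot threshold")
  list(center = center, scale = scale)
}
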