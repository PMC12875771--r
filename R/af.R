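#' Alkire-Foster dual-cutoff deprivation measures
#'
#' The engine behind the composite index: indicator weighting (equal
#' indicator weights, EIW, or equal nested factor weights, ENW),
#' identification of the multidimensionally deprived at cutoff `d`,
#' aggregation into the headcount ratio H, the average deprivation share A
#' among the poor, and the adjusted headcount ratio M0 = H * A, plus censored
#' headcounts and contribution decompositions, robustness curves over `d`,
#' subgroup decomposition, bootstrap group comparisons, and the
#' per-participant burden covariate used in the regression stage.
#'
#' @name af_engine
NULL

# tolerance for >= comparisons on weighted counts (ENW weights are rationals
# like 1/3 whose sums carry floating-point error)
AF_EPS <- 1e-9

#' Build an indicator weight scheme
#'
#' EIW gives every indicator weight 1 (total weight = number of indicators;
#' the cutoff is a raw count). ENW gives every factor equal weight split
#' evenly among its indicators (each factor's indicator weights sum to 1;
#' total weight = number of factors; the cutoff is a share of total weight).
#'
#' @param registry An `indicator_registry`.
#' @param scheme_name `"EIW"` or `"ENW"`.
#' @return A `weight_scheme`: named weight vector, total weight, and cutoff
#'   convention (`"count"` for EIW, `"share"` for ENW).
#' @export
build_weight_scheme <- function(registry, scheme_name = c("EIW", "ENW")) {
  scheme_name <- match.arg(toupper(scheme_name), c("EIW", "ENW"))
  h <- registry_hierarchy(registry)
  w <- if (scheme_name == "EIW") {
    rep(1, nrow(h))
  } else {
    1 / table(h$factor)[h$factor]
  }
  structure(
    list(scheme_name = scheme_name,
         weights = stats::setNames(as.numeric(w), h$indicator),
         total_weight = sum(w),
         cutoff_convention = if (scheme_name == "EIW") "count" else "share"),
    class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight_scheme:", x$scheme_name, "-", length(x$weights),
      "indicators, total weight", format(x$total_weight),
      paste0("(", x$cutoff_convention, " cutoff)\n"))
  invisible(x)
}

#' Alkire-Foster configuration: cutoff plus weight scheme
#'
#' @param d Deprivation cutoff: a weighted indicator count under the
#'   `"count"` convention, or a share of total weight in (0, 1] under
#'   `"share"`.
#' @param weight_scheme A `weight_scheme`.
#' @return An `af_config`.
#' @export
af_config <- function(d, weight_scheme) {
  stopifnot(inherits(weight_scheme, "weight_scheme"), is.numeric(d),
            length(d) == 1L, d > 0)
  if (weight_scheme$cutoff_convention == "count") {
    if (d > weight_scheme$total_weight + AF_EPS)
      stop("af_config: count cutoff d exceeds total weight")
  } else if (d > 1 + AF_EPS) {
    stop("af_config: share cutoff d must lie in (0, 1]")
  }
  structure(list(d = d, weight_scheme = weight_scheme), class = "af_config")
}

check_matrix <- function(matrix, w) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (!all(matrix %in% c(0L, 1L)))
    stop("deprivation matrix entries must be 0/1")
  if (ncol(matrix) != length(w$weights))
    stop("deprivation matrix has ", ncol(matrix), " columns but the weight ",
         "scheme has ", length(w$weights))
  matrix
}

#' Per-participant weighted deprivation scores
#'
#' @param matrix Participants x indicators 0/1 matrix in registry order.
#' @param weight_scheme A `weight_scheme` over the same indicators.
#' @return Numeric vector `c_i = sum_j w_j g_ij`.
#' @export
deprivation_scores <- function(matrix, weight_scheme) {
  matrix <- check_matrix(matrix, weight_scheme)
  as.vector(matrix %*% weight_scheme$weights)
}

#' Identify the multidimensionally deprived
#'
#' Poor iff the weighted score reaches the cutoff: `c_i >= d` under the count
#' convention, `c_i / total_weight >= d` under the share convention (the
#' boundary is inclusive: deprived on the cutoff number of indicators counts
#' as poor).
#'
#' @param scores Weighted scores from [deprivation_scores()].
#' @param config An `af_config`.
#' @return Logical vector.
#' @export
identify_poor <- function(scores, config) {
  w <- config$weight_scheme
  if (w$cutoff_convention == "count") scores >= config$d - AF_EPS
  else scores / w$total_weight >= config$d - AF_EPS
}

#' Aggregate Alkire-Foster measures
#'
#' H = poor fraction; A = mean weighted deprivation share among the poor;
#' M0 = H * A, equal to the censored weighted deprivations divided by
#' `n * total_weight`. Both computational routes are evaluated and checked
#' against each other. With no poor, H = M0 = 0 and A is `NA`.
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param config An `af_config`.
#' @return An `af_result` with fields `H`, `A`, `M0`, `n`, `n_poor`, `d`,
#'   `scheme`.
#' @export
af_measures <- function(matrix, config) {
  matrix <- check_matrix(matrix, config$weight_scheme)
  if (nrow(matrix) == 0L) stop("af_measures: empty deprivation matrix")
  w <- config$weight_scheme
  scores <- deprivation_scores(matrix, w)
  poor <- identify_poor(scores, config)
  n <- length(scores); n_poor <- sum(poor)
  H <- n_poor / n
  if (n_poor == 0L) {
    A <- NA_real_; M0 <- 0
  } else {
    A <- mean(scores[poor] / w$total_weight)
    M0 <- H * A
    M0_direct <- sum(scores[poor]) / (n * w$total_weight)
    stopifnot(abs(M0 - M0_direct) < 1e-12)
  }
  structure(list(H = H, A = A, M0 = M0, n = n, n_poor = n_poor,
                 d = config$d, scheme = w$scheme_name),
            class = "af_result")
}

#' @export
print.af_result <- function(x, ...) {
  cat(sprintf("af_result (%s, d = %s): H = %.4f, A = %s, M0 = %.4f  [n = %d, poor = %d]\n",
              x$scheme, format(x$d), x$H,
              if (is.na(x$A)) "NA" else sprintf("%.4f", x$A), x$M0, x$n, x$n_poor))
  invisible(x)
}

#' Indicator, factor and dimension contributions to M0
#'
#' The censored headcount of indicator j, `CH_j`, is the fraction of the
#' whole sample that is both poor and deprived on j; its contribution is
#' `w_j * CH_j / (total_weight * M0)`, which sums to 1 over indicators.
#' Censoring (ignoring deprivations of the non-poor) is what guarantees the
#' unit sum; an uncensored variant (raw headcounts, sums above 1 in general)
#' is available via `censored = FALSE`.
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param config An `af_config`.
#' @param registry Optional `indicator_registry` supplying the factor and
#'   dimension roll-ups.
#' @param censored Use censored headcounts (default TRUE).
#' @return A `contribution_table`: data frames `indicators`, and (with a
#'   registry) `factors` and `dimensions`, plus the underlying `M0`.
#' @export
contributions <- function(matrix, config, registry = NULL, censored = TRUE) {
  matrix <- check_matrix(matrix, config$weight_scheme)
  w <- config$weight_scheme
  res <- af_measures(matrix, config)
  if (res$M0 <= 0)
    stop("contributions: M0 = 0 (no one is poor); contributions are undefined")
  poor <- identify_poor(deprivation_scores(matrix, w), config)
  head_j <- if (censored) colMeans(matrix * poor) else colMeans(matrix)
  contrib <- w$weights * head_j / (w$total_weight * res$M0)
  ind <- data.frame(indicator = names(w$weights), weight = unname(w$weights),
                    censored_headcount = unname(head_j),
                    contribution = unname(contrib),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(indicators = ind, M0 = res$M0, censored = censored)
  if (!is.null(registry)) {
    h <- registry_hierarchy(registry)
    stopifnot(identical(h$indicator, ind$indicator))
    roll <- function(by) {
      agg <- stats::aggregate(ind$contribution, list(group = by), sum)
      agg <- agg[match(unique(by), agg$group), ]
      data.frame(group = agg$group, contribution = agg$x,
                 row.names = NULL, stringsAsFactors = FALSE)
    }
    out$factors <- roll(h$factor)
    names(out$factors)[1] <- "factor"
    out$dimensions <- roll(h$dimension)
    names(out$dimensions)[1] <- "dimension"
  }
  structure(out, class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("contribution_table over", nrow(x$indicators), "indicators (M0 =",
      format(round(x$M0, 4)), ")\n")
  top <- x$indicators[order(-x$indicators$contribution), ][1:min(5, nrow(x$indicators)), ]
  cat("top contributors:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Robustness curve of the AF measures over a cutoff sweep
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param weight_scheme A `weight_scheme`.
#' @param d_values Cutoff values to evaluate (counts or shares per the
#'   scheme's convention).
#' @return Data frame with one row per cutoff: `d`, `H`, `A`, `M0`,
#'   `n_poor`, `n`.
#' @export
m0_curve <- function(matrix, weight_scheme, d_values) {
  stopifnot(length(d_values) >= 1L)
  rows <- lapply(d_values, function(d) {
    r <- af_measures(matrix, af_config(d, weight_scheme))
    data.frame(d = d, H = r$H, A = r$A, M0 = r$M0, n_poor = r$n_poor, n = r$n)
  })
  do.call(rbind, rows)
}

#' Calibrate the deprivation cutoff to a target poverty prevalence
#'
#' Returns the cutoff whose headcount ratio is closest to the target
#' prevalence, ties broken toward the smaller cutoff. Count-convention
#' schemes search the integer cutoffs `1..total_weight`; share-convention
#' schemes search the achievable score shares.
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param weight_scheme A `weight_scheme`.
#' @param target_prevalence Target headcount ratio in (0, 1).
#' @return The selected cutoff `d`.
#' @export
calibrate_cutoff <- function(matrix, weight_scheme, target_prevalence) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  cand <- if (weight_scheme$cutoff_convention == "count") {
    seq_len(floor(weight_scheme$total_weight + AF_EPS))
  } else {
    s <- deprivation_scores(matrix, weight_scheme) / weight_scheme$total_weight
    sort(unique(s[s > 0]))
  }
  H <- m0_curve(matrix, weight_scheme, cand)$H
  cand[which.min(abs(H - target_prevalence))]  # which.min takes first = smaller d
}

#' Subgroup decomposition of the adjusted headcount ratio
#'
#' M0 is population-share decomposable: the overall value equals the
#' population-share-weighted sum of subgroup values. The identity is
#' asserted on every call.
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param config An `af_config`.
#' @param groups Vector of group labels partitioning the rows.
#' @return Data frame with one row per group (`group`, `n`, `pop_share`,
#'   `n_poor`, `H`, `A`, `M0`), carrying the overall `af_result` in the
#'   `"overall"` attribute. Empty groups get `n = 0` and missing measures.
#' @export
subgroup_decompose <- function(matrix, config, groups) {
  matrix <- check_matrix(matrix, config$weight_scheme)
  stopifnot(length(groups) == nrow(matrix))
  overall <- af_measures(matrix, config)
  lev <- if (is.factor(groups)) levels(groups) else unique(groups)
  rows <- lapply(lev, function(g) {
    idx <- which(groups == g)
    if (length(idx) == 0L)
      return(data.frame(group = g, n = 0L, pop_share = 0, n_poor = NA_integer_,
                        H = NA_real_, A = NA_real_, M0 = NA_real_))
    r <- af_measures(matrix[idx, , drop = FALSE], config)
    data.frame(group = g, n = r$n, pop_share = r$n / overall$n,
               n_poor = r$n_poor, H = r$H, A = r$A, M0 = r$M0)
  })
  out <- do.call(rbind, rows)
  recon <- sum(out$pop_share * ifelse(is.na(out$M0), 0, out$M0))
  stopifnot(abs(recon - overall$M0) < 1e-9)
  attr(out, "overall") <- overall
  out
}

#' Relative gap between two adjusted headcount ratios
#'
#' @param a,b `af_result` objects (or lists with an `M0` field); `b` is the
#'   reference group.
#' @return Percent difference `100 * (a$M0 - b$M0) / b$M0`.
#' @export
relative_gap <- function(a, b) {
  if (is.na(b$M0) || b$M0 <= 0)
    stop("relative_gap: reference group has M0 = 0; the gap is undefined")
  100 * (a$M0 - b$M0) / b$M0
}

#' Bootstrap test of an M0 difference between two groups
#'
#' Participants are resampled with replacement within each group; the M0
#' difference (group a minus reference b) is recomputed per replicate and a
#' two-sided percentile p-value is taken as twice the smaller tail mass of
#' the bootstrap distribution around zero.
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param config An `af_config`.
#' @param groups Two-level label vector; the second sorted level (or second
#'   factor level) is the reference unless `reference` is given.
#' @param reference Reference group label.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List: `gap_percent` (observed relative gap), `m0_diff`,
#'   `p_value`, `n_boot`, and `flagged` (TRUE when a group has no poor
#'   members in the observed data, making the percentile p fragile).
#' @export
group_difference_test <- function(matrix, config, groups, reference = NULL,
                                  n_boot = 1000, seed = 1) {
  matrix <- check_matrix(matrix, config$weight_scheme)
  lev <- if (is.factor(groups)) levels(droplevels(factor(groups))) else sort(unique(groups))
  if (length(lev) != 2L) stop("group_difference_test: need exactly two groups")
  if (is.null(reference)) reference <- lev[2L]
  other <- setdiff(lev, reference)
  ia <- which(groups == other); ib <- which(groups == reference)
  if (!length(ia) || !length(ib)) stop("group_difference_test: empty group")

  m0_of <- function(idx) af_measures(matrix[idx, , drop = FALSE], config)$M0
  ra <- af_measures(matrix[ia, , drop = FALSE], config)
  rb <- af_measures(matrix[ib, , drop = FALSE], config)
  obs <- ra$M0 - rb$M0
  flagged <- ra$n_poor == 0L || rb$n_poor == 0L

  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    m0_of(sample(ia, length(ia), replace = TRUE)) -
      m0_of(sample(ib, length(ib), replace = TRUE))
  }, numeric(1))
  # two-sided percentile p: how unusual is a zero difference under the
  # bootstrap distribution centered on the observed difference
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(1, max(p, 1 / n_boot))
  list(gap_percent = if (rb$M0 > 0) 100 * obs / rb$M0 else NA_real_,
       m0_diff = obs, p_value = p, n_boot = n_boot, flagged = flagged)
}

#' Per-participant deprivation burden
#'
#' The regression exposure: each participant's weighted deprivation score as
#' a share of total weight, between 0 and 1. The default is uncensored (every
#' participant keeps their share); `censored = TRUE` zeroes the burden of
#' participants below the poverty cutoff (the censored-score convention).
#'
#' @param matrix Participants x indicators 0/1 matrix.
#' @param config An `af_config`.
#' @param censored Zero out non-poor burdens (default FALSE).
#' @return Numeric vector between 0 and 1.
#' @export
burden <- function(matrix, config, censored = FALSE) {
  matrix <- check_matrix(matrix, config$weight_scheme)
  w <- config$weight_scheme
  scores <- deprivation_scores(matrix, w)
  b <- scores / w$total_weight
  if (censored) b[!identify_poor(scores, config)] <- 0
  b
}
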