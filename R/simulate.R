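#' Seeded synthetic cohort generator
#'
#' Generates cohorts with the statistical structure the downstream analysis
#' assumes, so every stage is testable without restricted cohort data. Binary
#' deprivation indicators share a single standard-normal latent propensity:
#' indicator j is deprived with probability `plogis(alpha_j + lambda_j *
#' theta)`, where `alpha_j` is solved numerically so the marginal prevalence
#' matches its target. A common small loading produces the weak positive
#' pairwise indicator dependence seen in survey deprivation data. Cognitive
#' outcomes are Bernoulli draws from a logistic model on the weighted
#' deprivation burden with age and sex terms, and every raw scale column is
#' constructed so that re-applying the registry rules reproduces the drawn
#' binary matrix (the asset indicator, whose cut depends on the realized
#' polychoric component scores, is instead defined by running the asset rule
#' on generated ordinal items).
#'
#' @name synthetic_cohort
NULL

gh_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gh <- pracma::gaussHermite(40)
      cache <<- list(t = gh$x * sqrt(2), w = gh$w / sqrt(pi))
    }
    cache
  }
})

# marginal deprivation prevalence of logistic(alpha + lambda * theta),
# theta ~ N(0,1), by Gauss-Hermite quadrature
latent_prevalence <- function(alpha, lambda) {
  gh <- gh_nodes()
  sum(gh$w * stats::plogis(alpha + lambda * gh$t))
}

# solve alpha so the marginal prevalence hits p
latent_intercept <- function(p, lambda, name = "indicator") {
  if (lambda == 0) return(stats::qlogis(p))
  f <- function(a) latent_prevalence(a, lambda) - p
  out <- tryCatch(stats::uniroot(f, c(-35, 35), tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(out))
    stop("unreachable prevalence target for indicator '", name, "' (p = ",
         format(p), ", loading = ", format(lambda), ")")
  out$root
}

# Poisson-binomial tail P(count >= d) for success probabilities p
poisbin_tail <- function(p, d) {
  pmf <- 1
  for (pj in p) pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  sum(pmf[(floor(d) + 1L):length(pmf)])
}

# theoretical poor fraction P(sum_j g_ij >= d) under the latent-factor model
theoretical_poor_fraction <- function(p_targets, loadings, d) {
  gh <- gh_nodes()
  alpha <- mapply(latent_intercept, p_targets, loadings)
  sum(vapply(seq_along(gh$t), function(k) {
    gh$w[k] * poisbin_tail(stats::plogis(alpha + loadings * gh$t[k]), d)
  }, numeric(1)))
}

# shift base prevalences on the logit scale (except indicators in `fixed`)
# so the theoretical poor fraction at cutoff d matches the target
calibrate_prevalence_shift <- function(base, loadings, d, target,
                                       fixed = logical(length(base))) {
  shift_p <- function(s) ifelse(fixed, base, stats::plogis(stats::qlogis(base) + s))
  f <- function(s) theoretical_poor_fraction(shift_p(s), loadings, d) - target
  s <- stats::uniroot(f, c(-6, 6), tol = 1e-8)$root
  list(shift = s, prevalences = shift_p(s))
}

#' Simulation configuration
#'
#' @param n_participants Cohort size (>= 2).
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   byte-identical cohorts.
#' @param prevalence_targets Per-indicator marginal deprivation probability
#'   in (0,1); a scalar is recycled. May be named by indicator.
#' @param latent_loadings Nonnegative loading of each indicator on the shared
#'   latent propensity; a scalar is recycled.
#' @param outcome_log_or Log odds ratio of possible cognitive impairment per
#'   unit deprivation-burden share (burden spans 0..1).
#' @param age_effect_log_or,sex_effect_log_or Log-OR of the age-65+ and
#'   female terms in the impairment model.
#' @param outcome_prevalence Target marginal impairment prevalence; the model
#'   intercept is solved against the realized covariates to hit it.
#' @param pcp_log_or,pcp_age_effect_log_or,pcp_sex_effect_log_or,pcp_prevalence
#'   The same four quantities for the poor-cognitive-performance outcome.
#' @param frac_age_65plus,frac_female Demographic composition probabilities.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_participants, seed = 1,
                       prevalence_targets = 0.2,
                       latent_loadings = 0.8,
                       outcome_log_or = log(11.48),
                       age_effect_log_or = log(1.90),
                       sex_effect_log_or = log(0.90),
                       outcome_prevalence = 0.337,
                       pcp_log_or = log(13.84),
                       pcp_age_effect_log_or = log(6.49),
                       pcp_sex_effect_log_or = log(0.29),
                       pcp_prevalence = 0.151,
                       frac_age_65plus = 0.517,
                       frac_female = 0.776) {
  probs <- c(prevalence_targets, outcome_prevalence, pcp_prevalence,
             frac_age_65plus, frac_female)
  if (any(probs <= 0 | probs >= 1))
    stop("sim_config: all probabilities must lie strictly in (0, 1)")
  if (!is.numeric(n_participants) || n_participants < 2)
    stop("sim_config: n_participants must be >= 2")
  if (any(latent_loadings < 0))
    stop("sim_config: latent loadings must be nonnegative")
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    prevalence_targets = prevalence_targets,
    latent_loadings = latent_loadings,
    outcome_log_or = outcome_log_or,
    age_effect_log_or = age_effect_log_or,
    sex_effect_log_or = sex_effect_log_or,
    outcome_prevalence = outcome_prevalence,
    pcp_log_or = pcp_log_or,
    pcp_age_effect_log_or = pcp_age_effect_log_or,
    pcp_sex_effect_log_or = pcp_sex_effect_log_or,
    pcp_prevalence = pcp_prevalence,
    frac_age_65plus = frac_age_65plus, frac_female = frac_female),
    class = "sim_config")
}

#' Default calibrated simulation configuration
#'
#' Starts from realistic per-indicator baseline prevalences (the Gaussian
#' one-SD tail mass 0.159 for the scale-threshold indicators, higher rates
#' for hardship and the health-behavior flags) and applies a common
#' logit-scale shift so the theoretical fraction of the cohort deprived on at
#' least `poverty_cutoff` indicators equals `target_poor_fraction`. The asset
#' indicator's prevalence is pinned near the one-SD tail by its own rule and
#' is excluded from the shift.
#'
#' @param registry Indicator registry the cohort will be generated for.
#' @param n_participants Cohort size (default 312).
#' @param seed Integer seed.
#' @param target_poor_fraction Calibration target for the poor fraction
#'   (default 0.192).
#' @param poverty_cutoff Indicator-count cutoff used in the calibration
#'   (default 11, equal indicator weights).
#' @param latent_loadings Common latent loading (default 0.8, giving weak
#'   pairwise indicator association).
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config` with calibrated `prevalence_targets`.
#' @export
default_sim_config <- function(registry = default_registry(),
                               n_participants = 312, seed = 1,
                               target_poor_fraction = 0.192,
                               poverty_cutoff = 11,
                               latent_loadings = 0.8, ...) {
  base <- base_prevalences(registry)
  fixed <- registry_asset_flags(registry)
  lam <- rep_len(latent_loadings, length(base))
  cal <- calibrate_prevalence_shift(base, lam, poverty_cutoff,
                                    target_poor_fraction, fixed)
  sim_config(n_participants = n_participants, seed = seed,
             prevalence_targets = cal$prevalences,
             latent_loadings = lam, ...)
}

SD_TAIL <- stats::pnorm(-1)  # 0.1587, one-SD Gaussian tail mass

base_prevalences <- function(registry) {
  defaults <- c(education_years = 0.35, reading_skills = 0.16,
                household_goods = 0.20, asset_index = SD_TAIL,
                hardship = 0.25, smoking = 0.20, alcohol_use = 0.15,
                drug_use = 0.10, physical_inactivity = 0.35,
                food_insecurity = 0.25, poor_sleep = 0.30, poor_diet = 0.30)
  vapply(registry$rules, function(r) {
    if (r$name %in% names(defaults)) return(unname(defaults[r$name]))
    if (r$kind %in% c("deficit_sd", "adverse_sd")) return(SD_TAIL)
    if (r$kind == "composite" && identical(r$params$rule, "barriers_component"))
      return(0.10)
    0.20
  }, numeric(1))
}

registry_asset_flags <- function(registry) {
  vapply(registry$rules, function(r)
    r$kind == "composite" && identical(r$params$rule, "asset_index"),
    logical(1))
}

# ---------------------------------------------------------------------------
# Score placement: continuous scales that re-threshold to a given 0/1 vector
# ---------------------------------------------------------------------------

# Draw a continuous score vector whose sample-SD thresholding reproduces
# `deprived` exactly. Deficit direction: deprived iff x <= mean(x) - sd(x).
# Deprived values start below -1 with a gap, and are shifted further down
# until the sample cut separates the groups (the cut moves more slowly than
# the deprived maximum, so the search is monotone). With no deprived members
# a floor-effect mixture keeps every z-score above -1.
place_scores <- function(deprived, direction = c("deficit", "adverse"),
                         threshold_sd = 1) {
  direction <- match.arg(direction)
  deprived <- as.logical(deprived)
  n <- length(deprived); k <- sum(deprived)
  if (n < 2L) stop("place_scores: need n >= 2")
  if (k == n)
    stop("place_scores: all participants deprived; an SD-threshold scale ",
         "cannot place every score below its own mean - SD")
  if (k / n >= 0.5)
    stop("place_scores: deprivation prevalence >= 50% cannot be represented ",
         "by an SD-threshold scale")
  x <- if (k == 0L) {
    q <- -0.2
    n_spread <- max(1L, floor(0.4 * n))
    idx <- sample.int(n, n_spread)
    out <- rep(q, n)
    out[idx] <- q + stats::rexp(n_spread)
    out
  } else {
    lo <- stats::pnorm(-1 - 0.1 - threshold_sd + 1)  # gap below the cut
    hi <- stats::pnorm(-1 + 0.1 - threshold_sd + 1)
    out <- numeric(n)
    out[deprived] <- stats::qnorm(stats::runif(k, 1e-12, lo))
    out[!deprived] <- stats::qnorm(stats::runif(n - k, hi, 1 - 1e-12))
    out
  }
  t <- 0
  repeat {
    y <- x; y[deprived] <- y[deprived] - t
    got <- threshold_deficit(y, threshold_sd, name = "place_scores")
    if (identical(as.logical(got), deprived)) break
    t <- t + 0.25
    if (t > 60) stop("place_scores: failed to separate groups")
  }
  if (direction == "deficit") y else -y
}

#' Generate raw scale scores consistent with a binary deprivation matrix
#'
#' For every registry rule except the asset index, emits the source columns
#' whose re-thresholding under [build_deprivation_matrix()] reproduces the
#' given binary matrix cell for cell: truncated scale scores on the deprived
#' side of the SD cut, college-attendance and reading-achievement columns,
#' living-standard components, barriers item endorsements, and the direct
#' binary flags themselves.
#'
#' @param deprivation Participants x indicators 0/1 matrix (registry order).
#' @param registry The `indicator_registry` used for generation.
#' @param seed Optional integer seed (omit to continue the current RNG
#'   stream).
#' @return Data frame of raw source columns.
#' @export
generate_scale_scores <- function(deprivation, registry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(deprivation)
  cols <- list()
  for (rule in registry$rules) {
    dep <- as.logical(deprivation[, rule$name])
    new <- switch(rule$kind,
      deficit_sd = stats::setNames(
        list(50 + 10 * place_scores(dep, "deficit", rule$threshold_sd)),
        rule$source[1L]),
      adverse_sd = stats::setNames(
        list(50 + 10 * place_scores(dep, "adverse", rule$threshold_sd)),
        rule$source[1L]),
      direct_binary = stats::setNames(list(as.integer(dep)), rule$source[1L]),
      composite = scale_scores_composite(rule, dep, n))
    if (!is.null(new)) cols[names(new)] <- new
  }
  as.data.frame(cols[!vapply(cols, is.null, logical(1))])
}

scale_scores_composite <- function(rule, dep, n) {
  switch(rule$params$rule,
    no_college = stats::setNames(list(as.integer(!dep)), rule$source[1L]),
    fixed_z_deficit = {
      cut <- rule$params$cut %||% -1
      z <- numeric(n)
      z[dep] <- stats::qnorm(stats::runif(sum(dep), 1e-12, stats::pnorm(cut)))
      z[!dep] <- stats::qnorm(stats::runif(sum(!dep), stats::pnorm(cut), 1 - 1e-12))
      stats::setNames(list(z), rule$source[1L])
    },
    living_standards = {
      homeowner <- stats::rbinom(n, 1, 0.6)
      ppr <- stats::runif(n, 0.3, 1.9)
      car <- rep(1L, n); net <- rep(1L, n)
      mode <- sample(c("car", "net", "crowd"), n, replace = TRUE,
                     prob = c(0.35, 0.35, 0.30))
      car[dep & mode == "car"] <- 0L
      net[dep & mode == "net"] <- 0L
      homeowner[dep & mode == "crowd"] <- 0L
      ppr[dep & mode == "crowd"] <- stats::runif(sum(dep & mode == "crowd"), 2.05, 4)
      stats::setNames(list(homeowner, ppr, car, net), rule$source)
    },
    barriers_component = {
      m <- length(rule$source)
      need <- rule$params$min_endorsed %||% 1
      if (m < need) stop("barriers component '", rule$name,
                         "' has fewer items than its endorsement threshold")
      items <- matrix(0L, n, m)
      for (i in which(dep)) {
        extra <- if (m > need) stats::rbinom(1, m - need, 0.3) else 0
        items[i, sample.int(m, need + extra)] <- 1L
      }
      stats::setNames(lapply(seq_len(m), function(j) items[, j]), rule$source)
    },
    asset_index = NULL)  # asset items are generated from the latent factor
}

# ordinal asset items driven by the shared deprivation propensity theta
# (higher theta = more deprived = fewer assets)
generate_asset_items <- function(theta, items = 5, categories = 4, a = 0.6) {
  n <- length(theta)
  cuts <- stats::qnorm(seq_len(categories - 1) / categories)
  out <- lapply(seq_len(items), function(j) {
    u <- (-a * theta + stats::rnorm(n)) / sqrt(1 + a^2)
    findInterval(u, cuts)
  })
  stats::setNames(as.data.frame(out), paste0("asset_item_", seq_len(items)))
}

solve_outcome_intercept <- function(lp, target) {
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
                 c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' @param config A `sim_config`.
#' @param registry An `indicator_registry`; defaults to [default_registry()].
#' @return A `synthetic_cohort`: `table` (the per-participant cohort data
#'   frame), `matrix` (the ground-truth deprivation matrix, which
#'   [build_deprivation_matrix()] reproduces from `table`), `true_burden`
#'   (equal-weight deprivation share), `true_outcome_probability` (the
#'   logistic impairment probability each PCI label was drawn from), `pci`
#'   and `pcp` label vectors (`pcp` re-derived from the emitted PACC columns;
#'   the raw Bernoulli draw is kept as `pcp_drawn`), `config`, and the
#'   `registry`.
#' @export
generate_cohort <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "sim_config"))
  validate_registry(registry)
  J <- n_indicators(registry)
  p <- rep_len(config$prevalence_targets, J)
  lam <- rep_len(config$latent_loadings, J)
  if (!is.null(names(config$prevalence_targets)) &&
      length(config$prevalence_targets) == J) {
    p <- config$prevalence_targets[indicator_names(registry)]
    if (anyNA(p))
      stop("generate_cohort: named prevalence targets do not cover the registry")
  }
  n <- config$n_participants
  set.seed(config$seed)

  theta <- stats::rnorm(n)
  is_asset <- registry_asset_flags(registry)
  nm <- indicator_names(registry)
  G <- matrix(0L, n, J, dimnames = list(NULL, nm))
  for (j in which(!is_asset)) {
    alpha <- latent_intercept(p[j], lam[j], name = nm[j])
    G[, j] <- stats::rbinom(n, 1, stats::plogis(alpha + lam[j] * theta))
  }

  asset_items <- NULL
  if (any(is_asset)) {
    j <- which(is_asset)[1L]
    asset_items <- generate_asset_items(
      theta, items = length(registry$rules[[j]]$source))
    names(asset_items) <- registry$rules[[j]]$source
    G[, j] <- asset_index(asset_items,
                          registry$rules[[j]]$threshold_sd)$deprived
  }

  female <- stats::rbinom(n, 1, config$frac_female)
  age65 <- stats::rbinom(n, 1, config$frac_age_65plus)
  age <- ifelse(age65 == 1,
                65 + 28 * stats::rbeta(n, 1.1, 2.5),
                45 + 20 * stats::rbeta(n, 2.5, 1.4))
  marital <- sample(c("married", "widowed", "divorced", "separated",
                      "never_married", "partnered"),
                    n, replace = TRUE,
                    prob = c(0.224, 0.112, 0.324, 0.048, 0.269, 0.023))

  sources <- generate_scale_scores(G, registry)

  w <- build_weight_scheme(registry, "EIW")
  b <- deprivation_scores(G, w) / w$total_weight

  lp_pci <- config$outcome_log_or * b + config$age_effect_log_or * age65 +
    config$sex_effect_log_or * female
  prob_pci <- stats::plogis(solve_outcome_intercept(lp_pci,
                                                    config$outcome_prevalence) + lp_pci)
  pci <- stats::rbinom(n, 1, prob_pci)
  moca <- integer(n)
  moca[pci == 1] <- sample(14:23, sum(pci), replace = TRUE,
                           prob = c(1, 1, 2, 3, 4, 6, 8, 10, 12, 13))
  moca[pci == 0] <- sample(24:30, sum(!pci), replace = TRUE,
                           prob = c(14, 16, 17, 16, 14, 13, 10))

  lp_pcp <- config$pcp_log_or * b + config$pcp_age_effect_log_or * age65 +
    config$pcp_sex_effect_log_or * female
  prob_pcp <- stats::plogis(solve_outcome_intercept(lp_pcp,
                                                    config$pcp_prevalence) + lp_pcp)
  pcp_draw <- stats::rbinom(n, 1, prob_pcp)
  v <- place_scores(pcp_draw, "deficit")
  cog <- data.frame(
    moca_total = moca,
    free_cued_recall = pmax(0, 40 + 8 * v),
    trails_a_seconds = 45 - 9 * v,
    trails_b_seconds = 110 - 22 * v,
    animal_naming = pmax(0, round(20 + 3.5 * v)))
  # rounding/clipping can nudge borderline composites; the realized labels
  # are whatever the classification rules return on the emitted columns
  pcp <- classify_pacc(compute_pacc(cog))

  adi <- pmin(100, pmax(1, round(75 + 6 * theta + stats::rnorm(n, 0, 18))))
  svi <- pmin(7, pmax(0, round(2.3 + 0.8 * theta + stats::rnorm(n, 0, 1.8))))

  parts <- list(
    data.frame(id = seq_len(n), age = round(age, 1), age_65plus = age65,
               female = female,
               sex = ifelse(female == 1, "female", "male"),
               marital_status = marital,
               married_partnered = as.integer(marital %in% c("married", "partnered")),
               adi = adi, svi = svi),
    sources, asset_items, cog)
  tab <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])

  structure(list(table = tab, matrix = G, true_burden = b,
                 true_outcome_probability = prob_pci,
                 pci = pci, pcp = pcp, pcp_drawn = pcp_draw, theta = theta,
                 config = config, registry = registry),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$table), "participants,",
      ncol(x$matrix), "indicators (seed", x$config$seed, ")\n")
  cat(sprintf("  mean burden %.3f, PCI prevalence %.3f, PCP prevalence %.3f\n",
              mean(x$true_burden), mean(x$pci), mean(x$pcp)))
  invisible(x)
}

#' Write a cohort table with seed metadata
#'
#' @param cohort A `synthetic_cohort` or plain data frame.
#' @param path Output CSV path; metadata (seed, size) goes to
#'   `<path>.meta.yaml` for `synthetic_cohort` inputs.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  tab <- if (inherits(cohort, "synthetic_cohort")) cohort$table else cohort
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  if (inherits(cohort, "synthetic_cohort"))
    yaml::write_yaml(list(seed = cohort$config$seed,
                          n_participants = nrow(tab),
                          generator = "sdohci::generate_cohort"),
                     paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
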