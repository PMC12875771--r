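#' Declarative deprivation-indicator registry
#'
#' An `indicator_registry` describes how raw cohort measurements are
#' operationalized into binary deprivation indicators, and how indicators are
#' nested in factors and factors in dimensions. Every downstream stage
#' (deprivation matrix, weighting, contribution roll-ups) is driven by this
#' object, so alternative indicator sets or thresholds are configuration, not
#' code changes.
#'
#' @name indicator_registry
NULL

VALID_KINDS <- c("deficit_sd", "adverse_sd", "direct_binary", "composite")
VALID_COMPOSITES <- c("no_college", "fixed_z_deficit", "living_standards",
                      "asset_index", "barriers_component")

#' Define one deprivation indicator rule
#'
#' @param name Indicator identifier (unique within a registry).
#' @param kind One of `"deficit_sd"` (deprived iff score <= mean - t*SD),
#'   `"adverse_sd"` (deprived iff score >= mean + t*SD), `"direct_binary"`
#'   (the source column is already the 0/1 indicator), or `"composite"`
#'   (a named multi-input rule, see `params$rule`).
#' @param factor Factor the indicator belongs to.
#' @param dimension Dimension the factor belongs to.
#' @param source Character vector of cohort column names consumed by the rule.
#' @param threshold_sd SD multiplier for the `*_sd` kinds (default 1).
#' @param params List of rule-specific parameters. For `kind = "composite"`,
#'   `params$rule` must be one of `"no_college"`, `"fixed_z_deficit"`,
#'   `"living_standards"`, `"asset_index"`, `"barriers_component"`.
#' @return An object of class `indicator_rule`.
#' @export
indicator_rule <- function(name, kind, factor, dimension, source,
                           threshold_sd = 1, params = list()) {
  kind <- match.arg(kind, VALID_KINDS)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(source), length(source) >= 1L,
            is.numeric(threshold_sd), threshold_sd > 0)
  if (kind == "composite") {
    if (is.null(params$rule) || !params$rule %in% VALID_COMPOSITES)
      stop("composite indicator '", name, "' needs params$rule in {",
           paste(VALID_COMPOSITES, collapse = ", "), "}")
  }
  structure(
    list(name = name, kind = kind, factor = factor, dimension = dimension,
         source = source, threshold_sd = threshold_sd, params = params),
    class = "indicator_rule")
}

#' Assemble an indicator registry
#'
#' @param rules List of [indicator_rule()] objects, in indicator order.
#' @return An object of class `indicator_registry`.
#' @export
indicator_registry <- function(rules) {
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "indicator_rule")))
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  reg <- structure(list(rules = rules), class = "indicator_registry")
  validate_registry(reg)
  reg
}

#' Validate registry nesting invariants
#'
#' Checks that indicator names are unique, that each indicator maps to exactly
#' one factor and each factor to exactly one dimension.
#'
#' @param registry An `indicator_registry`.
#' @return The registry, invisibly; errors describe every violation found.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "indicator_registry"))
  nm <- indicator_names(registry)
  problems <- character(0)
  if (anyDuplicated(nm))
    problems <- c(problems, paste0("duplicated indicator names: ",
                                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  fac <- vapply(registry$rules, `[[`, character(1), "factor")
  dims <- vapply(registry$rules, `[[`, character(1), "dimension")
  # a factor must live in a single dimension
  bad <- tapply(dims, fac, function(d) length(unique(d)) > 1L)
  if (any(bad))
    problems <- c(problems, paste0("factors mapped to multiple dimensions: ",
                                   paste(names(bad)[bad], collapse = ", ")))
  if (length(problems)) stop(paste(problems, collapse = "; "))
  invisible(registry)
}

#' @export
print.indicator_registry <- function(x, ...) {
  h <- registry_hierarchy(x)
  cat("indicator_registry:", nrow(h), "indicators,",
      length(unique(h$factor)), "factors,",
      length(unique(h$dimension)), "dimensions\n")
  for (d in unique(h$dimension)) {
    hd <- h[h$dimension == d, ]
    cat("  ", d, " (", nrow(hd), " indicators)\n", sep = "")
    for (f in unique(hd$factor))
      cat("    ", f, ": ", paste(hd$indicator[hd$factor == f], collapse = ", "),
          "\n", sep = "")
  }
  invisible(x)
}

#' Indicator names in registry order
#' @param registry An `indicator_registry`.
#' @return Character vector.
#' @export
indicator_names <- function(registry) {
  unname(vapply(registry$rules, `[[`, character(1), "name"))
}

#' Number of indicators in a registry
#' @param registry An `indicator_registry`.
#' @return Integer count.
#' @export
n_indicators <- function(registry) length(registry$rules)

#' Indicator/factor/dimension hierarchy table
#'
#' @param registry An `indicator_registry`.
#' @return A data.frame with columns `indicator`, `factor`, `dimension`,
#'   `kind` in registry order.
#' @export
registry_hierarchy <- function(registry) {
  data.frame(
    indicator = indicator_names(registry),
    factor = unname(vapply(registry$rules, `[[`, character(1), "factor")),
    dimension = unname(vapply(registry$rules, `[[`, character(1), "dimension")),
    kind = unname(vapply(registry$rules, `[[`, character(1), "kind")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' All cohort columns referenced by a registry
#' @param registry An `indicator_registry`.
#' @return Character vector of unique source column names.
#' @export
registry_source_columns <- function(registry) {
  unique(unlist(lapply(registry$rules, `[[`, "source")))
}

# ---------------------------------------------------------------------------
# Default registry: 37 indicators, 10 factors, 3 HDRF dimensions
# ---------------------------------------------------------------------------

barriers_component_spec <- function() {
  # 17 difficulty items spanning 9 barriers-to-care components
  list(
    barriers_cost                 = c("barrier_item_01", "barrier_item_02"),
    barriers_transportation       = c("barrier_item_03", "barrier_item_04"),
    barriers_scheduling           = c("barrier_item_05", "barrier_item_06"),
    barriers_provider_attitudes   = c("barrier_item_07", "barrier_item_08"),
    barriers_communication        = c("barrier_item_09", "barrier_item_10"),
    barriers_navigation           = c("barrier_item_11", "barrier_item_12"),
    barriers_socioeconomic        = c("barrier_item_13", "barrier_item_14"),
    barriers_discrimination       = c("barrier_item_15", "barrier_item_16"),
    barriers_availability         = c("barrier_item_17"))
}

#' The default S/SDOH indicator registry
#'
#' Thirty-seven indicators nested in ten factors across the three HDRF
#' dimensions (environmental, sociocultural, behavioral). Scale-based
#' indicators use +/- 1 SD deprivation thresholds computed on the analytic
#' sample; composites cover education (no college attendance; reading
#' achievement z <= -1 against external norms), household living standards
#' (non-homeownership with crowding > 2 persons/room, or no car, or no
#' internet), a polychoric-PCA asset index (deprived at <= -1 SD on the first
#' component), and nine barriers-to-care components built from 17 difficulty
#' items (deprived at >= 1 endorsed item by default).
#'
#' @param barriers_min_endorsed Minimum endorsed items per barriers component
#'   to count as deprived (default 1).
#' @param living_standards_conjunctive If `TRUE`, require all living-standard
#'   shortfalls jointly instead of the default disjunctive reading.
#' @param education_conjunctive If `TRUE`, replace the two education
#'   indicators by one joint indicator (no college AND reading z <= -1); the
#'   registry then has 36 indicators.
#' @return An `indicator_registry` with 37 indicators (default options),
#'   10 factors and 3 dimensions.
#' @export
default_registry <- function(barriers_min_endorsed = 1,
                             living_standards_conjunctive = FALSE,
                             education_conjunctive = FALSE) {
  r <- list()
  add <- function(...) r[[length(r) + 1L]] <<- indicator_rule(...)

  ## environmental -----------------------------------------------------------
  add("neighborhood_cohesion", "deficit_sd", "neighborhood", "environmental",
      "neighborhood_cohesion_score")
  add("neighborhood_disorder", "adverse_sd", "neighborhood", "environmental",
      "neighborhood_disorder_score")
  if (education_conjunctive) {
    add("education_quality", "composite", "education", "environmental",
        c("attended_college", "reading_z"),
        params = list(rule = "no_college", conjunctive_reading = TRUE))
  } else {
    add("education_years", "composite", "education", "environmental",
        "attended_college", params = list(rule = "no_college"))
    add("reading_skills", "composite", "education", "environmental",
        "reading_z", params = list(rule = "fixed_z_deficit", cut = -1))
  }
  add("living_conditions", "deficit_sd", "living_standards", "environmental",
      "living_conditions_score")
  add("household_goods", "composite", "living_standards", "environmental",
      c("homeowner", "persons_per_room", "car_access", "internet_access"),
      params = list(rule = "living_standards",
                    conjunctive = living_standards_conjunctive))
  add("asset_index", "composite", "living_standards", "environmental",
      paste0("asset_item_", 1:5), params = list(rule = "asset_index"))
  for (comp in names(barriers_component_spec()))
    add(comp, "composite", "healthcare_barriers", "environmental",
        barriers_component_spec()[[comp]],
        params = list(rule = "barriers_component",
                      min_endorsed = barriers_min_endorsed))

  ## sociocultural -----------------------------------------------------------
  add("religiosity_organizational", "deficit_sd", "religiosity", "sociocultural",
      "religiosity_organizational_score")
  add("religiosity_private", "deficit_sd", "religiosity", "sociocultural",
      "religiosity_private_score")
  add("religiosity_intrinsic", "deficit_sd", "religiosity", "sociocultural",
      "religiosity_intrinsic_score")
  add("hardship", "direct_binary", "social", "sociocultural",
      "hardship_basic_needs")
  add("life_stressors", "adverse_sd", "social", "sociocultural",
      "chronic_stressors_score")
  add("extraversion", "deficit_sd", "psychological", "sociocultural",
      "extraversion_score")
  add("agreeableness", "deficit_sd", "psychological", "sociocultural",
      "agreeableness_score")
  add("openness", "deficit_sd", "psychological", "sociocultural",
      "openness_score")
  add("conscientiousness", "deficit_sd", "psychological", "sociocultural",
      "conscientiousness_score")
  add("neuroticism", "adverse_sd", "psychological", "sociocultural",
      "neuroticism_score")
  add("life_satisfaction", "deficit_sd", "psychological", "sociocultural",
      "life_satisfaction_score")

  ## behavioral --------------------------------------------------------------
  add("john_henryism", "adverse_sd", "coping", "behavioral",
      "john_henryism_score")
  add("vigilance", "adverse_sd", "discrimination", "behavioral",
      "vigilance_score")
  add("everyday_discrimination", "adverse_sd", "discrimination", "behavioral",
      "discrimination_score")
  for (b in c("smoking", "alcohol_use", "drug_use", "physical_inactivity",
              "food_insecurity", "poor_sleep", "poor_diet"))
    add(b, "direct_binary", "health_behaviors", "behavioral", paste0(b, "_flag"))

  indicator_registry(r)
}

# ---------------------------------------------------------------------------
# Serialization (declarative key-value config, YAML)
# ---------------------------------------------------------------------------

#' Write a registry to a declarative YAML file
#' @param registry An `indicator_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  out <- lapply(registry$rules, function(r)
    list(name = r$name, kind = r$kind, factor = r$factor,
         dimension = r$dimension, source = as.list(r$source),
         threshold_sd = r$threshold_sd, params = r$params))
  yaml::write_yaml(list(indicators = unname(out)), path)
  invisible(path)
}

#' Read a registry from a declarative YAML file
#' @param path File written by [write_registry()] or hand-authored in the
#'   same layout.
#' @return An `indicator_registry`.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$indicators)) stop("registry file has no 'indicators' key: ", path)
  rules <- lapply(raw$indicators, function(r)
    indicator_rule(r$name, r$kind, r$factor, r$dimension,
                   unlist(r$source), r$threshold_sd %||% 1,
                   r$params %||% list()))
  indicator_registry(rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
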