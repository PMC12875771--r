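#' Composite deprivation rules and the deprivation matrix
#'
#' The composite rules cover the indicators that are not simple one-column
#' thresholds: household living standards, education, barriers-to-care
#' components, and the polychoric asset index (see [asset_index()]).
#' [build_deprivation_matrix()] applies every registry rule to a cohort table
#' and returns the participants x indicators 0/1 matrix that feeds the
#' Alkire-Foster engine.
#'
#' @name deprivation_rules
NULL

#' Household living-standards deprivation rule
#'
#' Default (disjunctive) reading: deprived iff (not homeowner AND
#' persons_per_room > 2) OR no car access OR no internet. The crowding clause
#' is attached to home ownership; car and internet are standalone shortfalls.
#' Set `conjunctive = TRUE` to require all three shortfalls jointly.
#'
#' @param homeowner,car_access,internet_access Logical/0-1 vectors.
#' @param persons_per_room Nonnegative numeric vector; crowding is the strict
#'   `> 2` persons per room.
#' @param conjunctive Use the all-conjunctive reading instead (default FALSE).
#' @return Integer 0/1 vector (1 = deprived).
#' @export
living_standards_rule <- function(homeowner, persons_per_room, car_access,
                                  internet_access, conjunctive = FALSE) {
  if (any(persons_per_room < 0, na.rm = TRUE))
    stop("living_standards_rule: persons_per_room must be nonnegative")
  crowded_renter <- !as.logical(homeowner) & persons_per_room > 2
  no_car <- !as.logical(car_access)
  no_net <- !as.logical(internet_access)
  if (conjunctive) as.integer(crowded_renter & no_car & no_net)
  else as.integer(crowded_renter | no_car | no_net)
}

#' Education deprivation indicators
#'
#' Emits the two education indicators kept separate in the default registry:
#' `education_years` (deprived iff no college attendance) and
#' `reading_skills` (deprived iff reading achievement z-score `<= -1` against
#' external test norms). A conjunctive single-indicator variant (no college
#' AND reading z <= -1) is available.
#'
#' @param attended_college Logical/0-1 vector.
#' @param reading_z Numeric reading achievement z-scores.
#' @param conjunctive Collapse into one joint indicator (default FALSE).
#' @param cut Reading z cut (default -1, inclusive).
#' @return Data frame with columns `education_years` and `reading_skills`
#'   (or a single `education_quality` column when conjunctive).
#' @export
education_rules <- function(attended_college, reading_z, conjunctive = FALSE,
                            cut = -1) {
  no_college <- as.integer(!as.logical(attended_college))
  low_reading <- as.integer(reading_z <= cut)
  if (conjunctive)
    data.frame(education_quality = as.integer(no_college & low_reading))
  else
    data.frame(education_years = no_college, reading_skills = low_reading)
}

#' Barriers-to-care component indicators
#'
#' Collapses binary difficulty endorsements into one indicator per component:
#' deprived when at least `min_endorsed` of the component's items are
#' endorsed.
#'
#' @param items Data frame or matrix of 0/1 item endorsements.
#' @param component_map Named list: component name -> character vector of its
#'   item column names. Every item column must be covered.
#' @param min_endorsed Endorsement threshold per component (default 1).
#' @return Data frame of 0/1 component indicators, one column per component.
#' @export
barriers_components <- function(items, component_map, min_endorsed = 1) {
  items <- as.data.frame(items)
  mapped <- unlist(component_map, use.names = FALSE)
  unknown <- setdiff(mapped, names(items))
  if (length(unknown))
    stop("barriers_components: items mapped to unknown columns: ",
         paste(unknown, collapse = ", "))
  out <- lapply(component_map, function(cols)
    as.integer(rowSums(items[, cols, drop = FALSE]) >= min_endorsed))
  as.data.frame(out)
}

#' Build the binary deprivation matrix from a cohort table
#'
#' Applies each registry rule in order. Participants with any missing value in
#' a referenced source column are dropped first (complete-case analysis at the
#' participant level), with the dropped count reported via `message()`.
#'
#' @param cohort Data frame of per-participant raw measurements; an `id`
#'   column, when present, becomes the row names of the result.
#' @param registry An `indicator_registry`.
#' @return Integer matrix (participants x indicators) of 0/1 entries with
#'   indicator names as column names, in registry order. Attribute
#'   `n_dropped` records the complete-case exclusions.
#' @export
build_deprivation_matrix <- function(cohort, registry) {
  validate_registry(registry)
  cohort <- as.data.frame(cohort)
  need <- registry_source_columns(registry)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing source columns required by the registry: ",
         paste(missing_cols, collapse = ", "))

  complete <- stats::complete.cases(cohort[, need, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("build_deprivation_matrix: dropped ", n_dropped,
            " participants with incomplete registry sources")
  cohort <- cohort[complete, , drop = FALSE]

  if (nrow(cohort) == 0L) {
    G <- matrix(integer(0), nrow = 0L, ncol = n_indicators(registry),
                dimnames = list(NULL, indicator_names(registry)))
    attr(G, "n_dropped") <- n_dropped
    return(G)
  }

  cols <- lapply(registry$rules, function(rule) apply_rule(rule, cohort))
  G <- do.call(cbind, cols)
  colnames(G) <- indicator_names(registry)
  rownames(G) <- if ("id" %in% names(cohort)) as.character(cohort$id)
                 else rownames(cohort)
  storage.mode(G) <- "integer"
  attr(G, "n_dropped") <- n_dropped
  G
}

apply_rule <- function(rule, cohort) {
  src <- cohort[, rule$source, drop = FALSE]
  switch(rule$kind,
    deficit_sd = threshold_deficit(src[[1L]], rule$threshold_sd,
                                   center = rule$params$center,
                                   scale = rule$params$scale, name = rule$name),
    adverse_sd = threshold_adverse(src[[1L]], rule$threshold_sd,
                                   center = rule$params$center,
                                   scale = rule$params$scale, name = rule$name),
    direct_binary = validate_binary(src[[1L]], rule$name),
    composite = apply_composite(rule, src))
}

apply_composite <- function(rule, src) {
  switch(rule$params$rule,
    no_college = {
      if (isTRUE(rule$params$conjunctive_reading))
        education_rules(src[[1L]], src[[2L]], conjunctive = TRUE)[[1L]]
      else as.integer(!as.logical(src[[1L]]))
    },
    fixed_z_deficit = as.integer(src[[1L]] <= (rule$params$cut %||% -1)),
    living_standards = living_standards_rule(
      src[["homeowner"]], src[["persons_per_room"]], src[["car_access"]],
      src[["internet_access"]], conjunctive = isTRUE(rule$params$conjunctive)),
    asset_index = if (nrow(src) == 0L) integer(0)
                  else asset_index(src, rule$threshold_sd)$deprived,
    barriers_component = {
      m <- stats::setNames(list(rule$source), rule$name)
      if (nrow(src) == 0L) integer(0)
      else barriers_components(src, m, rule$params$min_endorsed %||% 1)[[1L]]
    },
    stop("unknown composite rule: ", rule$params$rule))
}

validate_binary <- function(x, name) {
  x <- as.integer(x)
  bad <- !is.na(x) & !x %in% c(0L, 1L)
  if (any(bad))
    stop("indicator '", name, "': direct_binary source must be 0/1")
  x
}
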