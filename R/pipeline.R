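#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains the stages — cohort (simulated or read from disk),
#' deprivation matrix, cognitive labels, AF measures overall and by subgroup,
#' cutoff robustness curves, contribution decompositions, per-indicator
#' deprivation gaps, descriptive and regression tables — and writes every
#' result as a comma-separated table plus a YAML run manifest recording the
#' configuration and seed, so a run is reproducible from its manifest alone.
#'
#' @name cli_reporting
NULL

#' Run the full deprivation-index pipeline
#'
#' @param cohort Data frame of raw cohort measurements, or `NULL` to
#'   simulate one from `sim_config`.
#' @param sim_config A `sim_config` used when `cohort` is `NULL`.
#' @param registry Indicator registry (default [default_registry()]).
#' @param scheme Weight scheme name, `"EIW"` or `"ENW"`.
#' @param d Deprivation cutoff (count for EIW, share for ENW).
#' @param d_range Cutoffs for the robustness curves (default 1..19).
#' @param n_boot Bootstrap replicates for subgroup M0 comparisons.
#' @param seed Seed for the bootstrap stage (and recorded in the manifest).
#' @param output_dir Directory for the CSV/YAML artifacts, or `NULL` to skip
#'   writing.
#' @return Invisibly, a named list with every computed artifact:
#'   `cohort`, `matrix`, `labels`, `af_overall`, `af_subgroups`, `curves`,
#'   `contributions`, `radar`, `gaps`, `table1`, `table2`, `group_tests`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, sim_config = NULL,
                         registry = default_registry(),
                         scheme = c("EIW", "ENW"), d = 11, d_range = 1:19,
                         n_boot = 500, seed = 1, output_dir = NULL) {
  scheme <- match.arg(toupper(scheme), c("EIW", "ENW"))
  if (is.null(cohort) == is.null(sim_config))
    stop("run_pipeline: supply exactly one of cohort or sim_config")
  sim <- NULL
  if (is.null(cohort)) {
    sim <- generate_cohort(sim_config, registry)
    cohort <- sim$table
  }
  message("stage cohort: ", nrow(cohort), " participants")

  G <- build_deprivation_matrix(cohort, registry)
  kept <- nrow(G)
  message("stage deprivation_matrix: ", kept, " participants x ", ncol(G),
          " indicators (", attr(G, "n_dropped"), " dropped)")
  cohort <- cohort[stats::complete.cases(
    cohort[, registry_source_columns(registry), drop = FALSE]), , drop = FALSE]

  labels <- cognitive_labels(cohort)
  message("stage cognitive_labels: PCI ", sum(labels$pci), ", PCP ",
          sum(labels$pcp))

  w <- build_weight_scheme(registry, scheme)
  cfg <- af_config(d, w)
  af_overall <- af_measures(G, cfg)

  groups <- list(
    moca_status = factor(ifelse(labels$pci == 1, "PCI", "CN"),
                         levels = c("CN", "PCI")),
    pacc_status = factor(ifelse(labels$pcp == 1, "PCP", "CN"),
                         levels = c("CN", "PCP")),
    sex = factor(labels$sex),
    age_group = factor(ifelse(labels$age_65plus == 1, "65plus", "under65"),
                       levels = c("under65", "65plus")))

  af_subgroups <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(variable = g, subgroup_decompose(G, cfg, groups[[g]]))
  }))

  curves <- do.call(rbind, c(
    list(cbind(variable = "overall", group = "all",
               m0_curve(G, w, d_range))),
    lapply(names(groups), function(g) {
      do.call(rbind, lapply(levels(groups[[g]]), function(lv) {
        cbind(variable = g, group = lv,
              m0_curve(G[groups[[g]] == lv, , drop = FALSE], w, d_range))
      }))
    })))
  message("stage af_index: H = ", round(af_overall$H, 3), ", M0 = ",
          round(af_overall$M0, 4))

  contrib_groups <- c(list(all = rep(TRUE, kept)),
                      stats::setNames(
                        lapply(c("PCI", "CN"), function(lv) groups$moca_status == lv),
                        c("PCI", "CN_moca")),
                      stats::setNames(
                        lapply(c("PCP", "CN"), function(lv) groups$pacc_status == lv),
                        c("PCP", "CN_pacc")))
  contribs <- lapply(contrib_groups, function(idx) {
    tryCatch(contributions(G[idx, , drop = FALSE], cfg, registry),
             error = function(e) NULL)
  })
  radar <- export_radar(contribs[!vapply(contribs, is.null, logical(1))])

  gaps <- indicator_gap_table(G, groups$moca_status)

  table1 <- table1_builder(
    cbind(labels, moca_status = groups$moca_status),
    "moca_status",
    list(sex = "categorical", age = "continuous",
         marital_status = "categorical", adi = "continuous",
         svi = "continuous"))

  bvec <- burden(G, cfg)
  covars <- data.frame(burden = bvec,
                       age_65plus = labels$age_65plus,
                       female = labels$female,
                       married_partnered = labels$married_partnered)
  fits <- list(
    pci_unadjusted = fit_logistic(labels$pci, covars[, "burden", drop = FALSE]),
    pci_adjusted = fit_logistic(labels$pci, covars),
    pcp_unadjusted = fit_logistic(labels$pcp, covars[, "burden", drop = FALSE]),
    pcp_adjusted = fit_logistic(labels$pcp, covars))
  table2 <- do.call(rbind, lapply(names(fits), function(nm)
    cbind(model = nm, model_table(fits[[nm]]))))
  message("stage associations: adjusted burden OR (PCI) = ",
          round(fits$pci_adjusted$odds_ratios["burden"], 2))

  group_tests <- do.call(rbind, lapply(c("moca_status", "pacc_status"), function(g) {
    gd <- group_difference_test(G, cfg, groups[[g]], reference = "CN",
                                n_boot = n_boot, seed = seed)
    data.frame(variable = g, gap_percent = gd$gap_percent,
               m0_diff = gd$m0_diff, p_value = gd$p_value,
               n_boot = gd$n_boot, flagged = gd$flagged)
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdohci")),
    seed = seed, scheme = scheme, d = d, d_range = range(d_range),
    n_boot = n_boot, n_participants = kept,
    n_dropped = attr(G, "n_dropped"),
    n_indicators = ncol(G),
    simulated = !is.null(sim),
    sim_seed = if (!is.null(sim)) sim$config$seed)

  out <- list(cohort = cohort, matrix = G, labels = labels,
              af_overall = af_overall, af_subgroups = af_subgroups,
              curves = curves, contributions = contribs, radar = radar,
              gaps = gaps, table1 = table1, table2 = table2, fits = fits,
              group_tests = group_tests, manifest = manifest)

  if (!is.null(output_dir)) write_run_artifacts(out, output_dir)
  invisible(out)
}

indicator_gap_table <- function(G, status) {
  lev <- levels(status)
  do.call(rbind, lapply(colnames(G), function(j) {
    p1 <- mean(G[status == lev[2L], j])
    p0 <- mean(G[status == lev[1L], j])
    tab <- table(factor(G[, j], levels = 0:1), status)
    p <- if (any(rowSums(tab) == 0)) NA_real_ else yates_chi_square(tab)$p_value
    data.frame(indicator = j,
               pct_deprived_case = 100 * p1, pct_deprived_control = 100 * p0,
               gap_pct_points = 100 * (p1 - p0), p_value = p)
  }))
}

#' Radar-ready long table of factor contributions
#'
#' @param contribution_tables Named list of `contribution_table` objects
#'   (one per group), each built with a registry so factor roll-ups exist.
#' @return Data frame with rows (group, factor, contribution_pct); each
#'   group's contributions sum to 100.
#' @export
export_radar <- function(contribution_tables) {
  stopifnot(length(contribution_tables) >= 1L)
  bad <- vapply(contribution_tables, function(ct) is.null(ct$factors), logical(1))
  if (any(bad)) {
    warning("export_radar: groups without factor contributions omitted: ",
            paste(names(contribution_tables)[bad], collapse = ", "))
    contribution_tables <- contribution_tables[!bad]
  }
  do.call(rbind, lapply(names(contribution_tables), function(g) {
    f <- contribution_tables[[g]]$factors
    data.frame(group = g, factor = f$factor,
               contribution_pct = 100 * f$contribution)
  }))
}

write_run_artifacts <- function(out, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, nm)
    utils::write.csv(x, file.path(output_dir, nm), row.names = FALSE, na = "")
  wcsv(cbind(id = rownames(out$matrix), as.data.frame(out$matrix)),
       "deprivation_matrix.csv")
  wcsv(out$labels[, intersect(c("id", "pci", "pcp", "pacc_score"),
                              names(out$labels))], "cognitive_labels.csv")
  ov <- out$af_overall
  wcsv(data.frame(H = ov$H, A = ov$A, M0 = ov$M0, n = ov$n, n_poor = ov$n_poor,
                  d = ov$d, scheme = ov$scheme), "af_overall.csv")
  wcsv(out$af_subgroups, "af_subgroups.csv")
  wcsv(out$curves, "m0_curves.csv")
  for (nm in names(out$contributions)) {
    ct <- out$contributions[[nm]]
    if (is.null(ct)) next
    wcsv(ct$indicators, paste0("contributions_indicator_", nm, ".csv"))
    wcsv(ct$factors, paste0("contributions_factor_", nm, ".csv"))
    wcsv(ct$dimensions, paste0("contributions_dimension_", nm, ".csv"))
  }
  wcsv(out$radar, "radar.csv")
  wcsv(out$gaps, "indicator_gaps.csv")
  wcsv(out$table1, "table1.csv")
  wcsv(out$table2, "table2.csv")
  wcsv(out$group_tests, "group_tests.csv")
  yaml::write_yaml(out$manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}
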