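#' Inferential layer: logistic models, bivariate tests, descriptive tables
#'
#' Logistic regressions of the binary cognitive outcomes on the deprivation
#' burden (with optional covariates) are reported as odds ratios with Wald
#' intervals and Tjur's discrimination R-squared. Descriptive comparisons use
#' the continuity-corrected chi-square for categorical rows and Welch's
#' t-test for continuous rows; one-way ANOVA with adjusted post-hoc pairwise
#' comparisons and a Spearman indicator-overlap matrix round out the stage.
#'
#' @name association_stats
NULL

#' Fit a logistic regression reported as odds ratios
#'
#' Maximum likelihood via [stats::glm()] (iteratively reweighted least
#' squares). Confidence intervals are Wald on the log-odds scale,
#' exponentiated. Perfect or quasi-perfect separation is detected (fitted
#' probabilities numerically 0/1 or exploding standard errors) and flagged
#' via `converged = FALSE` rather than raising an error.
#'
#' @param outcome 0/1 outcome vector with both classes present.
#' @param predictors Data frame (or named list) of numeric/binary predictor
#'   columns.
#' @param conf_level Wald interval coverage (default 0.95).
#' @return A `model_fit`: `coefficients` (log-odds), `odds_ratios`, `ci95`
#'   (matrix, exponentiated), `p_values`, `tjur_r2`, `fitted`, `n`,
#'   `converged`, and the underlying `glm` object.
#' @export
fit_logistic <- function(outcome, predictors, conf_level = 0.95) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1))
  if (length(unique(outcome)) < 2L)
    stop("fit_logistic: outcome has a single class")
  X <- as.data.frame(predictors)
  if (nrow(X) != length(outcome))
    stop("fit_logistic: outcome and predictors differ in length")
  if (length(outcome) <= ncol(X) + 1L)
    stop("fit_logistic: more terms than observations")
  dat <- cbind(data.frame(.y = outcome), X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  separated <- sep_warn || any(se > 1e3)
  structure(
    list(coefficients = beta,
         odds_ratios = exp(beta),
         ci95 = cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
         se = se,
         p_values = sm[, "Pr(>|z|)"],
         tjur_r2 = tjur_r2(outcome, stats::fitted(fit)),
         fitted = stats::fitted(fit),
         n = length(outcome),
         converged = fit$converged && !separated,
         separation = separated,
         glm = fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit (logistic):", x$n, "observations, Tjur R2 =",
      format(round(x$tjur_r2, 3)),
      if (!x$converged) "[NOT CONVERGED / separation]" else "", "\n")
  print(model_table(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy odds-ratio table from a fitted model
#'
#' @param fit A `model_fit`.
#' @return Data frame with columns `term`, `or`, `ci_low`, `ci_high`, `p`,
#'   plus `n` and `tjur_r2` repeated per row (Table-2-style layout).
#' @export
model_table <- function(fit) {
  data.frame(term = names(fit$odds_ratios),
             or = unname(fit$odds_ratios),
             ci_low = unname(fit$ci95[, "lower"]),
             ci_high = unname(fit$ci95[, "upper"]),
             p = unname(fit$p_values),
             n = fit$n, tjur_r2 = fit$tjur_r2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tjur's discrimination R-squared
#'
#' Mean fitted probability among cases minus mean fitted probability among
#' non-cases.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param fitted_probabilities Fitted probabilities in the same order.
#' @return A scalar, practically between 0 and 1.
#' @export
tjur_r2 <- function(outcome, fitted_probabilities) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("tjur_r2: outcome has a single class")
  mean(fitted_probabilities[outcome == 1L]) -
    mean(fitted_probabilities[outcome == 0L])
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates-corrected Pearson chi-square with 1 df, the variant used for the
#' categorical rows of the descriptive tables.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @param correct Apply the continuity correction (default TRUE).
#' @return A `bivariate_test`: `statistic`, `df`, `p_value`, `method`.
#' @export
yates_chi_square <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("yates_chi_square: zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value,
                 method = if (correct) "chi-square (Yates)" else "chi-square"),
            class = "bivariate_test")
}

#' Welch two-sample t-test
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @param pooled Use the pooled-variance (Student) test instead of Welch.
#' @return A `bivariate_test`.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                            p_value = 1, method = "t-test (degenerate)"),
                       class = "bivariate_test"))
    stop("welch_t_test: both groups have zero variance with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (pooled) "t-test (pooled)" else "t-test (Welch)"),
            class = "bivariate_test")
}

#' @export
print.bivariate_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' One-way ANOVA with adjusted post-hoc pairwise comparisons
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups with n >= 2 each).
#' @param method Pairwise adjustment: Tukey HSD (default) or Bonferroni on
#'   pairwise Welch tests.
#' @return List: `omnibus` (a `bivariate_test` with the F statistic),
#'   `pairwise` (data frame `comparison`, `p_adj`), `method`.
#' @export
oneway_anova_posthoc <- function(values, groups, method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("oneway_anova_posthoc: need >= 2 groups")
  if (any(table(groups) < 2L)) stop("oneway_anova_posthoc: a group has n < 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  omnibus <- structure(
    list(statistic = an[["F value"]][1L],
         df = c(an[["Df"]][1L], an[["Df"]][2L]),
         p_value = an[["Pr(>F)"]][1L], method = "one-way ANOVA"),
    class = "bivariate_test")
  if (method == "tukey") {
    tk <- stats::TukeyHSD(fit)$groups
    pairwise <- data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                           row.names = NULL, stringsAsFactors = FALSE)
  } else {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    m <- ncol(pairs)
    pairwise <- data.frame(
      comparison = apply(pairs, 2, paste, collapse = "-"),
      p_adj = apply(pairs, 2, function(pr) {
        raw <- welch_t_test(values[groups == pr[1L]],
                            values[groups == pr[2L]])$p_value
        min(1, m * raw)
      }),
      stringsAsFactors = FALSE)
  }
  list(omnibus = omnibus, pairwise = pairwise, method = method)
}

#' Spearman rank-correlation matrix of deprivation indicators
#'
#' Midrank-tied Spearman rho per indicator pair (for 0/1 columns this reduces
#' to the phi coefficient). Constant columns yield `NA` for their pairs and a
#' warning naming them; the diagonal is always 1.
#'
#' @param matrix Participants x indicators matrix (>= 2 columns).
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 2L) stop("spearman_matrix: need >= 2 indicators")
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0))
    warning("spearman_matrix: constant columns (rho undefined): ",
            paste(colnames(matrix)[sds == 0], collapse = ", "))
  rho <- suppressWarnings(stats::cor(matrix, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Build a stratified descriptive table
#'
#' One block per variable: categorical variables get per-level counts with
#' within-stratum percentages and a chi-square p-value (Yates-corrected for
#' 2x2); continuous variables get "mean (SD)" and "median \[min, max\]" rows
#' with a Welch t-test (two strata) or one-way ANOVA (more) p-value.
#'
#' @param data Cohort data frame.
#' @param strata Name of the stratifying column (e.g. a cognitive label).
#' @param variables Named character vector or list mapping variable names to
#'   `"categorical"` or `"continuous"`.
#' @return Data frame with columns `variable`, `level`, one formatted column
#'   per stratum, `p_value`, `method`.
#' @export
table1_builder <- function(data, strata, variables) {
  s <- factor(data[[strata]])
  lev <- levels(s)
  blocks <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    x <- data[[v]]
    if (type == "categorical") {
      x <- factor(x)
      tab <- table(x, s)
      cells <- sapply(lev, function(g) {
        n_g <- sum(tab[, g])
        sprintf("%d (%s%%)", tab[, g],
                ifelse(rep(n_g, nrow(tab)) > 0,
                       formatC(100 * tab[, g] / n_g, format = "f", digits = 1),
                       "NA"))
      })
      if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
      p <- if (all(dim(tab) == 2L)) yates_chi_square(tab)$p_value
           else suppressWarnings(stats::chisq.test(tab)$p.value)
      block <- data.frame(variable = v, level = rownames(tab),
                          stringsAsFactors = FALSE)
      block[lev] <- cells
      block$p_value <- c(p, rep(NA_real_, nrow(block) - 1L))
      block$method <- c("chi-square", rep(NA_character_, nrow(block) - 1L))
      block
    } else {
      msd <- sapply(lev, function(g) {
        xg <- x[s == g]
        if (!length(xg)) return(NA_character_)
        sprintf("%.1f (%.2f)", mean(xg, na.rm = TRUE), stats::sd(xg, na.rm = TRUE))
      })
      mmm <- sapply(lev, function(g) {
        xg <- x[s == g]
        if (!length(xg)) return(NA_character_)
        sprintf("%.1f [%.1f, %.1f]", stats::median(xg, na.rm = TRUE),
                min(xg, na.rm = TRUE), max(xg, na.rm = TRUE))
      })
      p <- if (length(lev) == 2L)
        welch_t_test(x[s == lev[1L]], x[s == lev[2L]])$p_value
      else oneway_anova_posthoc(x, s)$omnibus$p_value
      block <- data.frame(variable = v,
                          level = c("mean (SD)", "median [min, max]"),
                          stringsAsFactors = FALSE)
      block[lev] <- rbind(msd, mmm)
      block$p_value <- c(p, NA_real_)
      block$method <- c(if (length(lev) == 2L) "t-test (Welch)" else "ANOVA",
                        NA_character_)
      block
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
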