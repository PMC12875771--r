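test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(10, 5, 5, 10)),
                  x = rep(c(1, 0, 1, 0), c(10, 5, 5, 10)))
  fit <- fit_logistic(d$y, d["x"])
  expect_equal(unname(fit$odds_ratios["x"]), 4, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_true(fit$ci95["x", "lower"] < 4 && 4 < fit$ci95["x", "upper"])
})

test_that("saturated fits match the cross-product ratio over random tables", {
  set.seed(301)
  for (rep in 1:25) {
    cell <- rpois(4, 12) + 3   # a, b, c, d all >= 3
    y <- rep(c(1, 1, 0, 0), cell)
    x <- rep(c(1, 0, 1, 0), cell)
    fit <- fit_logistic(y, data.frame(x = x))
    expect_equal(unname(fit$odds_ratios["x"]),
                 (cell[1] * cell[4]) / (cell[2] * cell[3]), tolerance = 1e-6)
  }
})

test_that("null predictors give OR near 1 and Tjur R2 near 0", {
  set.seed(302)
  n <- 20000
  x <- rnorm(n); y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(fit$odds_ratios["x"]), 1, tolerance = 0.05)
  expect_lt(abs(fit$tjur_r2), 0.005)
  # intercept-only model: fitted probability equals the prevalence
  fit0 <- fit_logistic(y, data.frame(z = rep(0, n)))
  expect_equal(unique(round(fit0$fitted, 10)), round(mean(y), 10))
})

test_that("perfect separation is flagged, not fatal", {
  y <- rep(c(0, 1), each = 20)
  x <- y
  fit <- fit_logistic(y, data.frame(x = x))
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_equal(fit$tjur_r2, 1, tolerance = 1e-6)
})

test_that("Tjur R2 equals the case/non-case fitted-probability gap", {
  expect_equal(tjur_r2(c(1, 1, 0, 0), c(0.8, 0.6, 0.4, 0.2)), 0.4)
  expect_equal(tjur_r2(c(1, 0, 1, 0), rep(0.5, 4)), 0)
  expect_equal(tjur_r2(c(1, 0), c(1, 0)), 1)
  expect_error(tjur_r2(c(1, 1), c(0.5, 0.5)), "single class")
})

test_that("continuity-corrected chi-square reproduces published descriptives", {
  # sex x cognitive status counts; the printed p is only reproduced by the
  # Yates-corrected statistic
  p_moca <- yates_chi_square(rbind(c(44, 163), c(26, 79)))$p_value
  expect_equal(round(p_moca, 3), 0.577)
  p_pacc <- yates_chi_square(rbind(c(51, 214), c(19, 28)))$p_value
  expect_equal(round(p_pacc, 5), 0.00254)
  # hand-computed corrected statistic for (20,10; 10,20)
  tab <- rbind(c(20, 10), c(10, 20))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((abs(tab - e) - 0.5)^2 / e)
  got <- yates_chi_square(tab)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$df, 1)
  # identical row distributions: statistic floored at 0, p = 1
  same <- yates_chi_square(rbind(c(15, 30), c(10, 20)))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)
  expect_error(yates_chi_square(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("Welch t-test agrees with the explicit formula", {
  x <- c(4.1, 5.3, 6.2, 5.8, 4.9); y <- c(7.4, 6.8, 8.1, 7.9)
  got <- welch_t_test(x, y)
  se2 <- var(x) / 5 + var(y) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$df, df, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(welch_t_test(x, x)$p_value, 1)
  expect_lt(welch_t_test(c(0, 0, 1, 1), c(10, 10, 11, 11))$p_value, 1e-4)
})

test_that("one-way ANOVA with post-hoc comparisons", {
  vals <- c(1, 2, 3, 2, 3, 4, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- oneway_anova_posthoc(vals, grp)
  # hand decomposition: between/within mean squares
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  expect_equal(got$omnibus$statistic, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(nrow(got$pairwise), 3)
  # all groups identical: F = 0, p = 1
  flat <- oneway_anova_posthoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$omnibus$statistic, 0)
  expect_equal(flat$omnibus$p_value, 1)
  # Bonferroni mode multiplies raw pairwise p-values, capped at 1
  bon <- oneway_anova_posthoc(vals, grp, method = "bonferroni")
  raw_ab <- welch_t_test(vals[grp == "a"], vals[grp == "b"])$p_value
  expect_equal(bon$pairwise$p_adj[bon$pairwise$comparison == "a-b"],
               min(1, 3 * raw_ab))
  expect_error(oneway_anova_posthoc(1:3, rep("a", 3)), "2 groups")
})

test_that("Spearman matrix handles binary columns and degenerate cases", {
  set.seed(303)
  G <- cbind(a = rbinom(200, 1, 0.4), b = rbinom(200, 1, 0.3))
  G <- cbind(G, c = G[, "a"], d = 1L - G[, "a"])
  rho <- spearman_matrix(G)
  expect_equal(rho["a", "c"], 1)
  expect_equal(rho["a", "d"], -1)
  expect_true(isSymmetric(rho))
  # on 0/1 columns Spearman reduces to the phi coefficient
  tab <- table(G[, "a"], G[, "b"])
  phi <- (tab[1,1]*tab[2,2] - tab[1,2]*tab[2,1]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  expect_equal(rho["a", "b"], unname(phi), tolerance = 1e-12)
  const <- cbind(G[, 1:2], e = rep(1L, 200))
  expect_warning(rho2 <- spearman_matrix(const), "constant")
  expect_true(is.na(rho2["a", "e"]))
  expect_equal(diag(rho2), c(a = 1, b = 1, e = 1))
})

test_that("table1_builder renders stratified counts, moments and tests", {
  set.seed(304)
  n <- 312
  status <- factor(rep(c("CN", "PCI"), c(207, 105)))
  sex <- c(rep(c("male", "female"), c(44, 163)), rep(c("male", "female"), c(26, 79)))
  age <- rnorm(n, ifelse(status == "PCI", 66.7, 63.4), 9.6)
  d <- data.frame(status = status, sex = sex, age = age)
  t1 <- table1_builder(d, "status", list(sex = "categorical", age = "continuous"))
  male_row <- t1[t1$variable == "sex" & t1$level == "male", ]
  expect_equal(male_row$CN, "44 (21.3%)")
  expect_equal(male_row$PCI, "26 (24.8%)")
  expect_equal(round(t1$p_value[t1$variable == "sex"][1], 3), 0.577)
  # continuous row mean/SD matches direct computation
  msd <- t1[t1$variable == "age" & t1$level == "mean (SD)", "CN"]
  expect_equal(msd, sprintf("%.1f (%.2f)", mean(age[status == "CN"]),
                            sd(age[status == "CN"])))
  expect_equal(t1$method[t1$variable == "age"][1], "t-test (Welch)")
})
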