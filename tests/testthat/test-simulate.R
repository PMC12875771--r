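test_that("identical (config, seed) pairs reproduce identical cohorts", {
  cfg <- default_sim_config(n_participants = 120, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$pci, b$pci)
  cfg2 <- default_sim_config(n_participants = 120, seed = 100)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$matrix, c2$matrix))
  # but summary structure matches across seeds
  expect_equal(mean(a$matrix), mean(c2$matrix), tolerance = 0.15)
})

test_that("config validation enforces the declared invariants", {
  expect_error(sim_config(1), "n_participants")
  expect_error(sim_config(10, prevalence_targets = 0), "probabilities")
  expect_error(sim_config(10, prevalence_targets = 1), "probabilities")
  expect_error(sim_config(10, frac_female = 1.2), "probabilities")
  expect_error(sim_config(10, latent_loadings = -0.2), "nonnegative")
})

test_that("zero loadings give independent indicators at their targets", {
  reg <- mini_registry(paste0("x", 1:5))
  cfg <- sim_config(10000, seed = 13, prevalence_targets = 0.5,
                    latent_loadings = 0)
  coh <- generate_cohort(cfg, reg)
  prev <- colMeans(coh$matrix)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(prev - 0.5) < 3 * se))
  rho <- cor(coh$matrix)
  expect_true(all(abs(rho[upper.tri(rho)]) < 0.04))
})

test_that("positive loadings induce weak positive dependence at the targets", {
  reg <- mini_registry(paste0("x", 1:6))
  cfg <- sim_config(50000, seed = 14, prevalence_targets = 0.2,
                    latent_loadings = 0.8)
  coh <- generate_cohort(cfg, reg)
  prev <- colMeans(coh$matrix)
  se <- sqrt(0.2 * 0.8 / 50000)
  expect_true(all(abs(prev - 0.2) < 4 * se))
  rho <- cor(coh$matrix)
  off <- rho[upper.tri(rho)]
  expect_true(all(off > 0))          # shared factor: positive association
  expect_true(all(off < 0.25))       # ... but weak
})

test_that("a null burden effect yields quartile odds ratios near 1", {
  cfg <- default_sim_config(n_participants = 20000, seed = 15)
  cfg$outcome_log_or <- 0
  cfg$age_effect_log_or <- 0
  cfg$sex_effect_log_or <- 0
  coh <- generate_cohort(cfg)
  q <- quantile(coh$true_burden, c(0.25, 0.75))
  top <- coh$pci[coh$true_burden >= q[2]]
  bottom <- coh$pci[coh$true_burden <= q[1]]
  or <- (mean(top) / (1 - mean(top))) / (mean(bottom) / (1 - mean(bottom)))
  expect_equal(or, 1, tolerance = 0.15)
})

test_that("true burden equals the weighted share of the emitted matrix", {
  coh <- generate_cohort(default_sim_config(n_participants = 150, seed = 16))
  w <- build_weight_scheme(coh$registry, "EIW")
  expect_equal(coh$true_burden,
               deprivation_scores(coh$matrix, w) / w$total_weight)
  expect_true(all(coh$true_burden >= 0 & coh$true_burden <= 1))
  expect_true(all(coh$true_burden[rowSums(coh$matrix) == 0] == 0))
})

test_that("raw scale columns re-threshold to the generating binary matrix", {
  for (seed in c(51, 52)) {
    coh <- generate_cohort(default_sim_config(n_participants = 250, seed = seed))
    G2 <- suppressMessages(build_deprivation_matrix(coh$table, coh$registry))
    expect_equal(strip_attrs(G2), strip_attrs(coh$matrix))
    # MoCA classification reproduces the drawn impairment labels exactly
    expect_equal(classify_moca(coh$table$moca_total), as.integer(coh$pci))
    # PACC classification reproduces the cohort's stored performance labels
    lab <- cognitive_labels(coh$table)
    expect_equal(lab$pcp, as.integer(coh$pcp))
  }
})

test_that("score placement round-trips deficit and adverse directions", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(c(10, 60, 300), 1)
    dep <- rbinom(n, 1, runif(1, 0, 0.35)) == 1
    while (mean(dep) >= 0.5) dep[sample(which(dep), 1)] <- FALSE
    x <- sdohci:::place_scores(dep, "deficit")
    expect_equal(as.logical(threshold_deficit(x)), dep)
    y <- sdohci:::place_scores(dep, "adverse")
    expect_equal(as.logical(threshold_adverse(y)), dep)
  }
  # no-deprivation vectors must also round-trip (floor-effect construction)
  none <- rep(FALSE, 40)
  expect_equal(as.logical(threshold_deficit(sdohci:::place_scores(none, "deficit"))),
               none)
  expect_error(sdohci:::place_scores(rep(TRUE, 10), "deficit"), "all participants")
})

test_that("unreachable prevalence targets name the offending indicator", {
  reg <- mini_registry(c("ok", "weird"))
  cfg <- sim_config(50, prevalence_targets = c(ok = 0.3, weird = 1e-300),
                    latent_loadings = 0.5)
  expect_error(generate_cohort(cfg, reg), "weird")
})

test_that("cohort tables round-trip through disk with seed metadata", {
  coh <- generate_cohort(default_sim_config(n_participants = 60, seed = 18))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 60)
  expect_equal(back$moca_total, coh$table$moca_total)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  expect_equal(meta$seed, 18)
})

test_that("calibrated default prevalences imply the target poor fraction", {
  cfg <- default_sim_config(seed = 1)
  p <- cfg$prevalence_targets
  lam <- cfg$latent_loadings
  expect_equal(sdohci:::theoretical_poor_fraction(p, lam, 11), 0.192,
               tolerance = 1e-4)
})
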