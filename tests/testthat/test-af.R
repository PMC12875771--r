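test_that("weight schemes follow the EIW and ENW conventions", {
  reg <- default_registry()
  eiw <- build_weight_scheme(reg, "EIW")
  expect_equal(unname(eiw$weights), rep(1, 37))
  expect_equal(eiw$total_weight, 37)
  expect_equal(eiw$cutoff_convention, "count")
  enw <- build_weight_scheme(reg, "ENW")
  expect_equal(enw$total_weight, 10)
  expect_equal(enw$cutoff_convention, "share")
  # three-indicator religiosity factor: each weight 1/3
  h <- registry_hierarchy(reg)
  expect_equal(unname(enw$weights[h$factor == "religiosity"]), rep(1/3, 3))
  # one-indicator coping factor: weight one
  expect_equal(unname(enw$weights[h$factor == "coping"]), 1)
  # within every factor, weights are equal and sum to one
  sums <- tapply(enw$weights, h$factor, sum)
  expect_equal(as.numeric(sums), rep(1, 10), tolerance = 1e-12)
  expect_error(build_weight_scheme(reg, "XYZ"))
})

test_that("identification uses an inclusive cutoff in both conventions", {
  w <- raw_scheme(rep(1, 37))
  cfg <- af_config(11, w)
  expect_true(identify_poor(11, cfg))
  expect_false(identify_poor(10, cfg))
  ws <- raw_scheme(rep(1, 10), convention = "share")
  cfgs <- af_config(0.30, ws)
  expect_true(identify_poor(3.0, cfgs))    # exactly 30% of total weight 10
  expect_false(identify_poor(2.99, cfgs))
})

test_that("the 4x3 worked example reproduces H, A, M0 and contributions", {
  G <- toy_matrix()
  reg <- mini_registry(colnames(G))
  cfg <- af_config(2, build_weight_scheme(reg, "EIW"))
  r <- af_measures(G, cfg)
  expect_equal(r$H, 0.5)
  expect_equal(r$A, 5 / 6)
  expect_equal(r$M0, 5 / 12)
  expect_equal(r$n_poor, 2L)
  ct <- contributions(G, cfg, reg)
  expect_equal(ct$indicators$contribution, c(0.4, 0.4, 0.2))
  expect_equal(sum(ct$indicators$contribution), 1)
  expect_equal(ct$factors$contribution, c(0.4, 0.4, 0.2))
})

test_that("AF bounds: saturated and empty matrices", {
  w <- raw_scheme(rep(1, 3))
  ones <- matrix(1L, 5, 3)
  r <- af_measures(ones, af_config(2, w))
  expect_equal(c(r$H, r$A, r$M0), c(1, 1, 1))
  zero <- matrix(0L, 5, 3)
  r0 <- af_measures(zero, af_config(1, w))
  expect_equal(r0$H, 0)
  expect_equal(r0$M0, 0)
  expect_true(is.na(r0$A))
  expect_error(contributions(zero, af_config(1, w)), "M0 = 0")
  expect_error(af_measures(matrix(integer(0), 0, 3), af_config(1, w)), "empty")
})

test_that("censoring zeroes contributions of indicators held only by non-poor", {
  # indicator c deprived only for the non-poor participant
  G <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  colnames(G) <- c("a", "b", "c")
  cfg <- af_config(2, raw_scheme(rep(1, 3)))
  ct <- contributions(G, cfg)
  expect_equal(ct$indicators$contribution, c(0.5, 0.5, 0))
  # uncensored variant counts it and breaks the unit sum
  ctu <- contributions(G, cfg, censored = FALSE)
  expect_gt(sum(ctu$indicators$contribution), 1)
})

test_that("m0_curve is monotone nonincreasing with correct endpoints", {
  set.seed(42)
  for (rep in 1:10) {
    G <- random_matrix(25, 8)
    w <- raw_scheme(rep(1, 8))
    crv <- m0_curve(G, w, 1:8)
    expect_true(all(diff(crv$H) <= 1e-12))
    expect_true(all(diff(crv$M0) <= 1e-12))
  }
  G <- rbind(c(1L, 0L), c(1L, 1L))
  crv <- m0_curve(G, raw_scheme(rep(1, 2)), 1:2)
  expect_equal(crv$H, c(1, 0.5))      # everyone holds >= 1 deprivation
  expect_equal(m0_curve(G, raw_scheme(rep(1, 2)), 2)$H, 0.5)
  # beyond the maximum score the headcount vanishes
  expect_equal(m0_curve(matrix(c(1L, 0L), 2, 1), raw_scheme(1), 1)$H, 0.5)
})

test_that("calibrate_cutoff picks the nearest-H cutoff, ties to smaller d", {
  # scores 5,5,6,6,6,7,7,7,7,7: H(5)=1, H(6)=.8, H(7)=.5
  G <- matrix(0L, 10, 7)
  for (i in 1:10) G[i, seq_len(c(5,5,6,6,6,7,7,7,7,7)[i])] <- 1L
  w <- raw_scheme(rep(1, 7))
  expect_equal(calibrate_cutoff(G, w, 0.70), 6)   # H(6)=.8 is nearest
  expect_equal(calibrate_cutoff(G, w, 0.55), 7)   # H(7)=.5 is nearest
  expect_equal(calibrate_cutoff(G, w, 0.99), 1)   # ties (H=1 for d<=5): smallest d
  # exactly equidistant between H(6)=.8 and H(7)=.5: smaller d wins
  expect_equal(calibrate_cutoff(G, w, 0.65), 6)
})

test_that("subgroup decomposition satisfies the population-share identity", {
  G <- toy_matrix()
  cfg <- af_config(2, raw_scheme(rep(1, 3)))
  dec <- subgroup_decompose(G, cfg, c("g1", "g1", "g2", "g2"))
  expect_equal(sum(dec$pop_share * dec$M0), 5 / 12)
  # identical subgroups reproduce the overall M0 each
  G2 <- rbind(G, G)
  dec2 <- subgroup_decompose(G2, cfg, rep(c("a", "b"), each = 4))
  expect_equal(dec2$M0, rep(5 / 12, 2))
  # empty level reported with n = 0 and missing measures
  dec3 <- subgroup_decompose(G, cfg, factor(rep("x", 4), levels = c("x", "y")))
  expect_equal(dec3$n[dec3$group == "y"], 0L)
  expect_true(is.na(dec3$M0[dec3$group == "y"]))
})

test_that("relative gaps are plain percent differences of M0", {
  mk <- function(m) list(M0 = m)
  expect_equal(relative_gap(mk(0.2), mk(0.2)), 0)
  expect_equal(relative_gap(mk(0.25), mk(0.20)), 25)
  expect_equal(relative_gap(mk(0.10), mk(0.20)), -50)
  expect_error(relative_gap(mk(0.1), mk(0)), "undefined")
})

test_that("burden is the weighted share, optionally censored", {
  G <- toy_matrix()
  cfg <- af_config(2, raw_scheme(rep(1, 3)))
  expect_equal(burden(G, cfg), c(2/3, 1/3, 1, 0))
  expect_equal(burden(G, cfg, censored = TRUE), c(2/3, 0, 1, 0))
  wide <- matrix(1L, 1, 37)
  expect_equal(burden(wide, af_config(11, raw_scheme(rep(1, 37)))), 1)
})

test_that("production path matches the brute-force oracle on random designs", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(5:30, 1); J <- sample(3:12, 1)
    G <- random_matrix(n, J)
    wts <- runif(J, 0.2, 2)
    conv <- sample(c("count", "share"), 1)
    w <- raw_scheme(wts, convention = conv)
    d <- if (conv == "count") runif(1, 0.5, sum(wts)) else runif(1, 0.05, 1)
    cfg <- af_config(d, w)
    oracle <- af_oracle(G, wts, d, conv)
    r <- af_measures(G, cfg)
    expect_equal(r$H, oracle$H)
    expect_equal(r$A, oracle$A)
    expect_equal(r$M0, oracle$M0)
    if (oracle$M0 > 0) {
      ct <- contributions(G, cfg)
      expect_equal(ct$indicators$censored_headcount, oracle$CH)
      expect_equal(ct$indicators$contribution, unname(oracle$contrib))
      expect_equal(sum(ct$indicators$contribution), 1, tolerance = 1e-9)
    }
  }
})

test_that("flipping one cell of a poor participant moves M0 by w_j/(n*W)", {
  set.seed(78)
  for (rep in 1:20) {
    G <- random_matrix(12, 6, p = 0.5)
    wts <- runif(6, 0.5, 1.5)
    cfg <- af_config(sum(wts) * 0.4, raw_scheme(wts))
    scores <- deprivation_scores(G, cfg$weight_scheme)
    poor <- identify_poor(scores, cfg)
    i <- which(poor & apply(G == 0, 1, any))[1]
    if (is.na(i)) next
    j <- which(G[i, ] == 0)[1]
    before <- af_measures(G, cfg)$M0
    G[i, j] <- 1L
    after <- af_measures(G, cfg)$M0
    expect_equal(after - before, wts[j] / (12 * sum(wts)), tolerance = 1e-12)
  }
})

test_that("M0 is invariant to participant and indicator reordering", {
  set.seed(79)
  G <- random_matrix(20, 9)
  wts <- runif(9, 0.3, 2)
  cfg <- af_config(0.3, raw_scheme(wts, "share"))
  base <- af_measures(G, cfg)$M0
  pr <- sample(20); pc <- sample(9)
  cfg2 <- af_config(0.3, raw_scheme(wts[pc], "share"))
  expect_equal(af_measures(G[pr, pc], cfg2)$M0, base)
})

test_that("EIW and ENW agree when every factor has one indicator", {
  reg <- mini_registry(paste0("x", 1:6))  # one factor per indicator
  set.seed(80)
  G <- random_matrix(30, 6)
  eiw <- build_weight_scheme(reg, "EIW")
  enw <- build_weight_scheme(reg, "ENW")
  for (k in 1:6) {
    poor_eiw <- identify_poor(deprivation_scores(G, eiw), af_config(k, eiw))
    poor_enw <- identify_poor(deprivation_scores(G, enw), af_config(k / 6, enw))
    expect_equal(poor_eiw, poor_enw)
  }
})

test_that("bootstrap group comparison behaves at the null and under signal", {
  set.seed(81)
  G <- random_matrix(60, 8, p = 0.4)
  cfg <- af_config(3, raw_scheme(rep(1, 8)))
  # identical groups (same rows duplicated): gap 0, p near 1
  gd <- group_difference_test(rbind(G, G), cfg,
                              rep(c("a", "b"), each = 60), reference = "b",
                              n_boot = 300, seed = 5)
  expect_equal(gd$gap_percent, 0)
  expect_gt(gd$p_value, 0.5)
  # strong signal: heavily deprived group vs sparse group
  Ga <- random_matrix(80, 8, p = 0.7); Gb <- random_matrix(80, 8, p = 0.15)
  gd2 <- group_difference_test(rbind(Ga, Gb), cfg,
                               rep(c("a", "b"), each = 80), reference = "b",
                               n_boot = 300, seed = 6)
  expect_lt(gd2$p_value, 0.05)
  expect_gt(gd2$gap_percent, 0)
})
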