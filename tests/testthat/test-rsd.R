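test_that("kinetic coordinates standardize with the sample-SD convention", {
  p <- cbind(R1 = c(0.8, 1.2), k2 = c(0.2, 0.4), k2a = c(0.1, 0.2))
  z <- zscore_params(p)
  expect_equal(unclass(z)[, 1], c(-1, 1) / sqrt(2), ignore_attr = TRUE)
  set.seed(3)
  p2 <- matrix(rnorm(60), 20, 3)
  z2 <- zscore_params(p2)
  expect_equal(colMeans(z2), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(z2, 2, sd), rep(1, 3), ignore_attr = TRUE)
  p2[, 2] <- 7
  expect_error(zscore_params(p2), "degenerate")
})

test_that("NLM weights obey the closed form, symmetry, and zero diagonal", {
  co <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.5, 0.5, 0))
  W <- nlm_weights(co, h2 = 0.5)
  expect_equal(diag(W), rep(0, 3))
  expect_equal(W[1, 2], 1)                 # identical coordinates
  expect_equal(W[1, 3], exp(-1))           # squared distance 0.5 / h2 0.5
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
  # h2 scales as a squared-distance bandwidth
  expect_equal(nlm_weights(co, 1)[1, 3], exp(-0.5))
})

test_that("regressor selection follows the F-test threshold exactly", {
  tacs <- rbind(1:5, 6:10, 11:15)
  imr <- rbind(rep(0, 5), rep(1, 5), rep(2, 5))
  all_data <- build_regressor_set(tacs, c(1, 0.9, 0.8), imr)
  expect_equal(all_data$regressors, tacs)
  expect_true(all(all_data$provenance == "data"))
  all_model <- build_regressor_set(tacs, c(0, 0, 0), imr)
  expect_equal(all_model$regressors, imr)
  mixed <- build_regressor_set(tacs[1:2, ], c(0.04, 0.06), imr[1:2, ])
  expect_equal(mixed$provenance, c("model", "data"))
  expect_equal(mixed$regressors[1, ], imr[1, ])
  expect_equal(mixed$regressors[2, ], tacs[2, ])
  expect_error(build_regressor_set(tacs, c(0.01, 1, 1), NULL), "IMRTM")
})

test_that("the NLM baseline is the weighted mean, bounded by its inputs", {
  regs <- rbind(rep(4, 6), rep(8, 6))
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  nb <- nlm_baseline(W, regs)
  expect_equal(nb$c_nlm[1, ], rep(8, 6))
  W3 <- rbind(c(0, 1, 1), c(1, 0, 3), c(1, 3, 0))
  regs3 <- rbind(rep(4, 4), rep(8, 4), rep(4, 4))
  nb3 <- nlm_baseline(W3, regs3)
  # voxel 3: weights (1, 3) over constant TACs (4, 8) -> constant 7
  expect_equal(nb3$c_nlm[3, ], rep(7, 4))
  expect_true(all(nb3$c_nlm >= 4 & nb3$c_nlm <= 8))
  # identical regressors pass through unchanged
  same <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(nlm_baseline(W, same)$c_nlm[1, ], c(1, 2, 3))
})

test_that("the scale/spill NNLS fit recovers exact mixtures and clamps at
           the constraint boundary", {
  sch <- sched_small(20, 3)
  ref <- ref_curve(sch)
  c_nlm <- forward_mrtm(ref, 0.9, 0.3, 0.1)$values
  t1 <- tac(1.5 * c_nlm, sch)
  f1 <- scale_and_spill_fit(t1, c_nlm, ref, tD = 30)
  expect_equal(f1$theta_nlm, 1.5, tolerance = 1e-9)
  expect_equal(f1$theta_r, 0, tolerance = 1e-9)
  t2 <- tac(c_nlm + 0.2 * ref$values, sch)
  f2 <- scale_and_spill_fit(t2, c_nlm, ref, tD = 30)
  expect_equal(f2$theta_nlm, 1, tolerance = 1e-9)
  expect_equal(f2$theta_r, 0.2, tolerance = 1e-9)
  expect_equal(f2$predicted, t2$values, tolerance = 1e-9)
  t3 <- tac(-c_nlm, sch)
  f3 <- scale_and_spill_fit(t3, c_nlm, ref, tD = 30)
  expect_equal(f3$theta_nlm, 0)
})

test_that("the internal 2-term NNLS agrees with an established solver on
           random problems", {
  skip_if_not_installed("pracma")
  set.seed(14)
  for (i in 1:50) {
    A <- matrix(rnorm(40), 20, 2)
    y <- rnorm(20)
    th <- rsdpet:::nnls2(A, y)
    or <- pracma::lsqnonneg(A, y)$x
    expect_equal(th, or, tolerance = 1e-8)
  }
})

test_that("percent residuals are exact, floored, and scale-invariant", {
  sch <- sched_small(5)
  C <- c(10, 10, 9, 10, 10)
  B <- rep(10, 5)
  r <- percent_residuals(tac(C, sch), B)
  expect_equal(r, c(0, 0, 10, 0, 0))
  # scaling both series leaves residuals unchanged
  expect_equal(percent_residuals(7 * C, 7 * B), r)
  # frames below the positivity floor are excluded
  B2 <- c(0.01, 10, 10, 10, 10)
  r2 <- percent_residuals(C, B2, floor_frac = 0.05)
  expect_true(is.na(r2[1]))
  expect_error(percent_residuals(C, rep(0.1, 5), floor_frac = 2), "floor")
})

test_that("the task predictor is causal, unit-peak, and approaches the
           block indicator for small L", {
  sch <- default_schedule()
  p <- make_predictor(list(c(36, 46)), L = 10, schedule = sch)
  expect_equal(max(p$P_fine), 1)
  expect_true(all(p$P_fine[p$t_fine <= 36] == 0))
  expect_equal(p$P[sch$mid <= 36], rep(0, 36))
  pk <- p$t_fine[which.max(p$P_fine)]
  expect_true(all(diff(p$P_fine[p$t_fine > 36 & p$t_fine <= pk]) >= 0))
  expect_true(all(diff(p$P_fine[p$t_fine >= pk + 1]) <= 0))

  tiny <- make_predictor(list(c(36, 46)), L = 0.01, schedule = sch)
  ind <- as.numeric(sch$mid > 36 & sch$mid <= 46)
  expect_true(mean(abs(tiny$P - ind)) < 0.05)

  # superposition: the two-block response dominates each single block
  two <- make_predictor(list(c(36, 40), c(50, 54)), L = 10, schedule = sch)
  one <- make_predictor(list(c(36, 40)), L = 10, schedule = sch)
  expect_true(all(two$P_fine / two$lambda >=
                    one$P_fine / one$lambda - 1e-9))
  expect_error(make_predictor(list()), "blocks")
  expect_error(make_predictor(list(c(40, 36))), "non-overlapping")
})

test_that("the GLM beta estimate is exact on noiseless input and unbiased
           under seeded noise", {
  sch <- default_schedule()
  p <- make_predictor(list(c(36, 46)), schedule = sch)
  expect_equal(fit_beta(4 * p$P, p)$beta, 4)
  expect_equal(fit_beta(rep(0, 75), p)$beta, 0)
  betas <- vapply(1:100, function(s) {
    set.seed(s)
    fit_beta(2 * p$P + rnorm(75), p)$beta
  }, numeric(1))
  se <- sd(betas)
  expect_lt(abs(mean(betas) - 2), 3 * se / sqrt(100))
  expect_lt(abs(mean(betas) - 2), 0.05)
  expect_error(fit_beta(rep(1, 75), rep(0, 75)), "zero")
})

test_that("the full pipeline recovers baselines and localizes release on
           noise-free phantoms", {
  nf0 <- cached_noise_free("localized", 0)
  ph <- nf0$phantom
  res0 <- run_rsd_hybrid(nf0$release, ph$striatum, ph$cerebellum)
  # beta centred on zero with a small spread; the worst voxels sit at the
  # edge of the Bmax distribution where the NLM neighborhood is one-sided
  expect_lt(abs(mean(res0$beta_values, na.rm = TRUE)), 0.25)
  expect_gt(mean(abs(res0$beta_values) < 0.5, na.rm = TRUE), 0.80)
  expect_lt(max(abs(res0$beta_values), na.rm = TRUE), 1.5)

  # baseline predictions within 1% RMSE of the ground-truth baselines
  truth <- extract_tacs(nf0$baseline, ph$striatum)$tacs
  keep <- match(TRUE, TRUE)  # voxel rows align with extraction order
  rel_rmse <- sqrt(rowMeans((res0$baselines - truth)^2)) / rowMeans(truth)
  expect_lt(max(rel_rmse), 0.01)

  nf1 <- cached_noise_free("localized", 100)
  res1 <- run_rsd_hybrid(nf1$release, ph$striatum, ph$cerebellum)
  incl <- nf1$release_mask[cbind(res1$index)]
  expect_gt(mean(res1$beta_values[incl]), 3)
  expect_lt(abs(mean(res1$beta_values[!incl])), 0.75)
  expect_gt(mean(res1$beta_values[incl]) - mean(res1$beta_values[!incl]), 3)
})

test_that("global release drives far more IMRTM replacement than a
           release-free phantom, and the hybrid replacement matters", {
  nfg <- cached_noise_free("global", 100)
  ph <- nfg$phantom
  resg <- run_rsd_hybrid(nfg$release, ph$striatum, ph$cerebellum)
  nf0 <- cached_noise_free("localized", 0)
  # release-free: flags come only from model mismatch; global release must
  # flag at least the bulk of the release ROI on top of that
  rel <- nfg$release_mask[cbind(resg$index)]
  expect_gt(mean(resg$replaced[rel]), 0.9)

  # ablation: without hybrid replacement the global-release beta estimates
  # collapse toward zero (contaminated regressors)
  res_no <- run_rsd_hybrid(nfg$release, ph$striatum, ph$cerebellum,
                           hybrid = FALSE)
  expect_gt(mean(resg$beta_values[rel]), 1.5 * mean(res_no$beta_values[rel]))
})

test_that("beta is invariant to the task start time on noise-free data", {
  spec <- small_spec()
  betas <- vapply(c(30, 35, 40, 45), function(td) {
    nf <- simulate_noise_free(
      spec, "localized", DA_peak = 200,
      profile_shape = release_profile(tD = td, tP = td + 4, alpha = 1,
                                      DA_peak = 0))
    res <- run_rsd_hybrid(nf$release, nf$phantom$striatum,
                          nf$phantom$cerebellum,
                          task_blocks = list(c(td, td + 10)), tD = td)
    incl <- nf$release_mask[cbind(res$index)]
    mean(res$beta_values[incl], na.rm = TRUE)
  }, numeric(1))
  cv <- sd(betas) / mean(betas)
  expect_lt(cv, 0.05)
})
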