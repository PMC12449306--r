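test_that("MRTM recovers forward-generated parameters and matches the
           normal-equations oracle", {
  sch <- sched_small(10, 2)
  ref <- ref_curve(sch)
  tgt <- forward_mrtm(ref, R1 = 0.9, k2 = 0.3, k2a = 0.12)
  fit <- fit_mrtm(tgt, ref)
  expect_equal(fit$R1, 0.9, tolerance = 1e-6)
  expect_equal(fit$k2, 0.3, tolerance = 1e-6)
  expect_equal(fit$k2a, 0.12, tolerance = 1e-6)
  expect_lt(fit$wrss, 1e-18)

  # oracle agreement on a noisy 10-frame fixture
  set.seed(4)
  noisy <- tac(tgt$values + rnorm(10, sd = 0.05), sch,
               weights = runif(10, 0.5, 2))
  f2 <- fit_mrtm(noisy, ref)
  X <- cbind(ref$values, cumulative_integral(ref),
             -cumulative_integral(noisy))
  co <- wls_oracle(X, noisy$values, noisy$weights)
  expect_equal(unname(f2$coef), unname(co), tolerance = 1e-10)
})

test_that("a self-referential fit is exactly degenerate, with R1 = 1 and
           k2 = k2a an exact zero-residual solution", {
  sch <- sched_small(12, 1.5)
  ref <- ref_curve(sch)
  # target = reference makes the two integral columns collinear: the
  # solution family R1 = 1, k2 = k2a all attain zero residual
  ic <- cumulative_integral(ref)
  for (k in c(0.1, 0.3)) {
    resid <- ref$values - (1 * ref$values + k * ic - k * ic)
    expect_equal(sum(resid^2), 0)
  }
  expect_error(fit_mrtm(ref, ref), "degenerate")
})

test_that("MRTM window restriction extrapolates with window coefficients", {
  sch <- sched_small(20, 2)
  ref <- ref_curve(sch)
  tgt <- forward_mrtm(ref, 0.85, 0.25, 0.1)
  fit <- fit_mrtm(tgt, ref, window = c(0, 20))
  expect_equal(sum(fit$window_frames), 10L)
  expect_equal(fit$fitted, tgt$values, tolerance = 1e-8)
  expect_error(fit_mrtm(tgt, ref, window = c(0, 5)), "4 frames")
})

test_that("the basis library has the documented shape properties", {
  sch <- default_schedule()
  bs <- make_basis_set(schedule = sch)
  expect_length(bs, 17L)
  expect_equal(range(vapply(bs, `[[`, numeric(1), "tP")), c(37, 51))
  for (b in bs[c(1, 9, 17)]) {
    expect_equal(max(b$h_fine), 1, tolerance = 1e-9)
    expect_equal(b$t_fine[which.max(b$h_fine)], b$tP, tolerance = 0.05)
    expect_true(all(b$h_fine[b$t_fine <= b$tD] == 0))
    # unimodal for alpha = 1: rising to tP, decaying after
    up <- b$h_fine[b$t_fine > b$tD & b$t_fine <= b$tP]
    dn <- b$h_fine[b$t_fine >= b$tP]
    expect_true(all(diff(up) >= 0))
    expect_true(all(diff(dn) <= 0))
  }
  expect_error(make_basis_set(36, c(35, 40), 1, sch), "exceed")
})

test_that("lp-ntPET recovers forward-generated release parameters and
           selects the true basis", {
  sch <- default_schedule()
  ref <- ref_curve(sch)
  bs <- make_basis_set(36, c(38, 42, 46), 1, sch)
  tgt <- forward_mrtm(ref, 0.95, 0.28, 0.09, gamma = 0.05, h = bs[[2]]$h)
  fit <- fit_lpntpet(tgt, ref, bs)
  expect_equal(fit$basis_index, 2L)
  expect_equal(fit$R1, 0.95, tolerance = 1e-6)
  expect_equal(fit$k2, 0.28, tolerance = 1e-6)
  expect_equal(fit$k2a, 0.09, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.05, tolerance = 1e-6)
})

test_that("baseline-only data give gamma 0, F 0, and the nested-model
           inequality holds against an exhaustive basis loop", {
  sch <- default_schedule()
  ref <- ref_curve(sch)
  bs <- make_basis_set(36, seq(38, 50, by = 4), 1, sch)
  base <- forward_mrtm(ref, 0.9, 0.3, 0.1)
  fit <- fit_lpntpet(base, ref, bs)
  expect_equal(fit$gamma, 0)
  expect_equal(fit$F, 0)

  # wrss of the returned fit never exceeds any single-basis wrss
  set.seed(9)
  noisy <- tac(base$values + rnorm(75, sd = 0.02), sch)
  fitn <- fit_lpntpet(noisy, ref, bs)
  per_basis <- vapply(seq_along(bs), function(k)
    fit_lpntpet(noisy, ref, bs[k])$wrss, numeric(1))
  expect_true(all(fitn$wrss <= per_basis + 1e-12))
  expect_lte(fitn$wrss, fitn$mrtm$wrss)
})

test_that("an empty basis set degenerates lp-ntPET to MRTM exactly", {
  sch <- sched_small(12, 2)
  ref <- ref_curve(sch)
  set.seed(5)
  tgt <- tac(forward_mrtm(ref, 0.9, 0.3, 0.1)$values + rnorm(12, sd = 0.05),
             sch)
  lp <- fit_lpntpet(tgt, ref, structure(list(), class = "basis_set"))
  mr <- fit_mrtm(tgt, ref)
  expect_equal(lp$wrss, mr$wrss, tolerance = 1e-12)
  expect_equal(c(lp$R1, lp$k2, lp$k2a), unname(mr$coef), tolerance = 1e-12)
  expect_equal(lp$gamma, 0)
})

test_that("the F-test follows its closed form and distribution", {
  f <- f_test(10, 8, 75, 3, 4)
  expect_equal(f$F, 2 / (8 / 71))
  expect_equal(f$F, 17.75)
  expect_equal(f$p, pf(17.75, 1, 71, lower.tail = FALSE))
  expect_equal(f_test(5, 5, 75)$F, 0)
  expect_equal(f_test(5, 5, 75)$p, 1)
  # full model can only look worse by chance; clamped at zero
  expect_equal(f_test(5, 6, 75)$F, 0)
  expect_equal(f_test(3, 0, 75)$F, Inf)
  expect_equal(f_test(3, 0, 75)$p, 0)
  # p decreases monotonically in F at fixed dof
  ps <- vapply(c(1, 2, 5, 10), function(F)
    pf(F, 1, 71, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("IMRTM is a fixed point on MRTM-consistent data and converges
           on release data", {
  sch <- default_schedule()
  ref <- ref_curve(sch)
  base <- forward_mrtm(ref, 0.9, 0.3, 0.1)
  im <- imrtm(base, ref, tD = 36, n_iter = 3)
  expect_equal(im$iterates[2, ], base$values, tolerance = 1e-8,
               ignore_attr = TRUE)

  # k2a_pre = 0 makes the iteration independent of the previous iterate
  flat <- forward_mrtm(ref, 0.9, 0.25, 0)
  imf <- imrtm(flat, ref, tD = 36, n_iter = 5, tol = 1e-10)
  expect_equal(imf$iterates[3, ], imf$iterates[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("IMRTM on a noise-free 400 nM release TAC approaches the MRTM
           fit of the true baseline with sub-1% RMSE fluctuation", {
  sch <- default_schedule()
  st <- simulate_tac(competition_params(), input_function(),
                     release_profile(36, 40, 1, 400), sch)
  ref_par <- competition_params(); ref_par$Bmax <- 0
  ref <- simulate_tac(ref_par, input_function(),
                      release_profile(DA_peak = 0), sch)$baseline
  im <- imrtm(st$release, ref, tD = 36, n_iter = 12, truth = st$baseline)
  r <- im$rmse_history
  fluct <- abs(diff(r)) / r[-length(r)]
  expect_lt(fluct[10], 0.01)

  # contraction: sup-norm distance between successive iterates shrinks
  sup <- vapply(seq_len(nrow(im$iterates) - 1L), function(i)
    max(abs(im$iterates[i + 1L, ] - im$iterates[i, ])), numeric(1))
  ratios <- sup[-1] / sup[-length(sup)]
  expect_true(all(ratios[-1] < 1))

  # the limit is the MRTM fit of the ground-truth baseline
  mfit <- fit_mrtm(st$baseline, ref)
  lim <- imrtm(st$release, ref, tD = 36, n_iter = 30)$baseline$values
  rel_rmse <- sqrt(mean((lim - mfit$fitted)^2)) / mean(st$baseline$values)
  expect_lt(rel_rmse, 0.005)
})

test_that("the vectorized map fitters agree with the single-TAC fitters", {
  sch <- default_schedule()
  ref <- ref_curve(sch)
  bs <- make_basis_set(36, c(40, 44), 1, sch)
  set.seed(21)
  M <- t(vapply(1:6, function(i)
    forward_mrtm(ref, 0.9 + 0.02 * i, 0.3, 0.08 + 0.01 * i,
                 gamma = 0.02 * (i %% 2), h = bs[[1]]$h)$values +
      rnorm(75, sd = 0.01),
    numeric(75)))
  w <- frame_weights(sch)
  mm <- rsdpet:::mrtm_map(M, ref$values, sch$mid, w)
  lm_ <- rsdpet:::lpntpet_map(M, ref$values, sch$mid, w, bs)
  for (i in 1:6) {
    tt <- tac(M[i, ], sch)
    f1 <- fit_mrtm(tt, ref)
    expect_equal(unname(mm$coef[i, ]), unname(f1$coef), tolerance = 1e-6)
    expect_equal(mm$wrss[i], f1$wrss, tolerance = 1e-6)
    f2 <- fit_lpntpet(tt, ref, bs)
    expect_equal(lm_$gamma[i], f2$gamma, tolerance = 1e-5)
    expect_equal(lm_$wrss[i], f2$wrss, tolerance = 1e-6)
  }
})
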