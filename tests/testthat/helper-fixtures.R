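# Shared fixtures and independent oracles, all built in code.

# small uniform schedule for closed-form checks
sched_small <- function(n = 10, dur = 1) frame_schedule(seq(0, by = dur,
                                                            length.out = n),
                                                        rep(dur, n))

# a smooth, realistic reference-like TAC on an arbitrary schedule
ref_curve <- function(schedule) {
  t <- schedule$mid
  vals <- 5 * (1 - exp(-1.5 * t)) * exp(-0.035 * t)
  tac(vals, schedule)
}

# Forward-generate a TAC satisfying the MRTM relation exactly under the
# package's trapezoid quadrature, solving frame by frame:
#   C[k] = R1 CR[k] + k2 icr[k] - k2a I_CT(k)
# where I_CT(k) depends linearly on C[k] through the trapezoid rule.
forward_mrtm <- function(ref, R1, k2, k2a, gamma = 0, h = NULL) {
  t <- ref$schedule$mid
  n <- length(t)
  dt <- diff(c(0, t))
  icr <- cumulative_integral(ref)
  if (is.null(h)) h <- rep(0, n)
  C <- numeric(n)
  I <- 0   # integral of C up to previous mid-time
  Ih <- 0  # integral of C*h
  for (k in seq_len(n)) {
    prevC <- if (k == 1) 0 else C[k - 1]
    prevCh <- if (k == 1) 0 else C[k - 1] * h[k - 1]
    rhs <- R1 * ref$values[k] + k2 * icr[k] -
      k2a * (I + dt[k] * prevC / 2) -
      gamma * (Ih + dt[k] * prevCh / 2)
    C[k] <- rhs / (1 + k2a * dt[k] / 2 + gamma * h[k] * dt[k] / 2)
    I <- I + dt[k] * (prevC + C[k]) / 2
    Ih <- Ih + dt[k] * (prevCh + C[k] * h[k]) / 2
  }
  tac(C, ref$schedule)
}

# brute-force normal-equations WLS oracle
wls_oracle <- function(X, y, w = rep(1, length(y))) {
  A <- t(X) %*% (w * X)
  drop(solve(A, t(X) %*% (w * y)))
}

# reduced phantom for pipeline tests: same layout at half grid scale
small_spec <- function() {
  phantom_spec(grid_shape = c(32, 32, 8),
               cluster_sizes = c(caudate_L = 8, putamen_L = 14,
                                 putamen_R = 11))
}

# cache noise-free studies across tests within one run
.study_cache <- new.env(parent = emptyenv())
cached_noise_free <- function(scenario, DA_peak, spec = small_spec()) {
  key <- sprintf("%s_%g_%d", scenario, DA_peak, spec$grid_shape[1])
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_noise_free(spec, scenario, DA_peak)
  .study_cache[[key]]
}
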