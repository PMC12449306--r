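#' Z-scored kinetic coordinates
#'
#' Standardizes per-voxel pre-task MRTM parameters (R1, k2, k2a) across the
#' striatal voxels, removing unit/scale differences so Euclidean distance
#' is meaningful. Sample SD (n - 1 denominator).
#'
#' @param params Numeric matrix, n_voxels x 3, columns R1, k2, k2a.
#' @return Matrix of the same shape, each column mean 0 / SD 1, class
#'   `kinetic_coords`.
#' @export
zscore_params <- function(params) {
  params <- as.matrix(params)
  if (nrow(params) < 2L)
    stop("need at least 2 voxels to z-score", call. = FALSE)
  sds <- apply(params, 2L, stats::sd)
  if (any(sds == 0) || any(!is.finite(sds)))
    stop("degenerate mask: a kinetic parameter has zero spread",
         call. = FALSE)
  z <- scale(params)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  colnames(z) <- c("R1", "k2", "k2a")[seq_len(ncol(z))]
  structure(z, class = c("kinetic_coords", class(z)))
}

#' Non-local-means weights in kinetic-parameter space
#'
#' Gaussian similarity weights
#' `w(i, j) = exp(-||d_j - d_i||^2 / h2)` between voxels in the z-scored
#' (R1, k2, k2a) space, with zero self-weight.
#'
#' @param coords Matrix of z-scored coordinates (rows = voxels), e.g. from
#'   [zscore_params()].
#' @param h2 Bandwidth (squared-distance scale, dimensionless in z-space);
#'   default 0.5.
#' @return Symmetric n x n weight matrix with zero diagonal.
#' @export
nlm_weights <- function(coords, h2 = 0.5) {
  stopifnot(h2 > 0)
  X <- unclass(as.matrix(coords))
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  W <- exp(-D2 / h2)
  diag(W) <- 0
  W
}

#' Hybrid baseline regressor set
#'
#' Per-voxel baseline regressor selection: voxels whose lp-ntPET F-test
#' p-value falls below the threshold (likely release-containing) contribute
#' their IMRTM model-derived baseline; all others contribute their measured
#' TAC.
#'
#' @param tacs n_voxels x n_frames matrix of measured TACs.
#' @param lpntpet_p Per-voxel lp-ntPET p-values.
#' @param imrtm_baselines n_voxels x n_frames matrix of IMRTM baselines.
#' @param p_threshold Replacement threshold (default 0.05).
#' @return List: `regressors` (matrix), `provenance` (`"model"` /
#'   `"data"` per voxel), `p` (the inputs).
#' @export
build_regressor_set <- function(tacs, lpntpet_p, imrtm_baselines,
                                p_threshold = 0.05) {
  tacs <- as.matrix(tacs)
  if (length(lpntpet_p) != nrow(tacs))
    stop("p-values and TACs are not aligned", call. = FALSE)
  flagged <- lpntpet_p < p_threshold
  if (any(flagged)) {
    if (is.null(imrtm_baselines))
      stop("flagged voxels need IMRTM baselines", call. = FALSE)
    imrtm_baselines <- as.matrix(imrtm_baselines)
    if (!identical(dim(imrtm_baselines), dim(tacs)))
      stop("IMRTM baselines not aligned with TACs", call. = FALSE)
  }
  reg <- tacs
  if (any(flagged)) reg[flagged, ] <- imrtm_baselines[flagged, , drop = FALSE]
  list(regressors = reg,
       provenance = ifelse(flagged, "model", "data"),
       p = lpntpet_p)
}

#' Non-local-means baseline aggregation
#'
#' Weighted average of the hybrid regressor TACs:
#' `C_NLM,j(t) = sum_i w(i, j) C~_i(t) / sum_i w(i, j)`.
#' A voxel whose weight row sums below `1e-12` (kinetically isolated) falls
#' back to its own regressor TAC and is reported.
#'
#' @param weights Symmetric weight matrix from [nlm_weights()].
#' @param regressors n_voxels x n_frames regressor matrix (e.g.
#'   `build_regressor_set()$regressors`).
#' @return List: `c_nlm` (matrix), `isolated` (logical per voxel).
#' @export
nlm_baseline <- function(weights, regressors) {
  regressors <- as.matrix(regressors)
  if (nrow(weights) != nrow(regressors))
    stop("weights and regressors are not aligned", call. = FALSE)
  wsum <- colSums(weights)
  isolated <- wsum < 1e-12
  c_nlm <- crossprod(weights, regressors)
  c_nlm[!isolated, ] <- c_nlm[!isolated, , drop = FALSE] / wsum[!isolated]
  if (any(isolated))
    c_nlm[isolated, ] <- regressors[isolated, , drop = FALSE]
  list(c_nlm = c_nlm, isolated = isolated)
}

# exact nonnegative least squares for two columns: try the unconstrained
# solution, else the best single-column nonnegative fit
nnls2 <- function(A, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  a <- A[, 1L]; b <- A[, 2L]
  aa <- sum(w * a * a); bb <- sum(w * b * b); ab <- sum(w * a * b)
  ay <- sum(w * a * y); by <- sum(w * b * y)
  det <- aa * bb - ab * ab
  if (det > .Machine$double.eps * aa * bb) {
    th <- c(bb * ay - ab * by, aa * by - ab * ay) / det
    if (all(th >= 0)) return(th)
  }
  t1 <- if (aa > 0) max(0, ay / aa) else 0
  t2 <- if (bb > 0) max(0, by / bb) else 0
  r1 <- sum(w * (y - t1 * a)^2)
  r2 <- sum(w * (y - t2 * b)^2)
  if (r1 <= r2) c(t1, 0) else c(0, t2)
}

#' Scale the NLM baseline and correct spill-in
#'
#' Nonnegative least squares on the pre-task frames,
#' `C_j(t) = theta_NLM C_NLM,j(t) + theta_R C_R(t)`, then extrapolation of
#' the fit to all frames. The reference term models spill-in from
#' surrounding non-binding tissue; nonnegativity encodes the physiological
#' assumption that measured signal is a mixture of true signal and
#' spill-in.
#'
#' @param target A [tac()] (the measured voxel TAC).
#' @param c_nlm Numeric series, the voxel's NLM-aggregated baseline.
#' @param ref A [tac()], the reference-region TAC.
#' @param tD Task start (min); pre-task frames have mid-time `< tD`.
#' @return List of class `baseline_prediction`: `predicted` (all frames),
#'   `theta_nlm`, `theta_r`, `c_nlm`, `degenerate` (both coefficients zero
#'   with nonzero data).
#' @export
scale_and_spill_fit <- function(target, c_nlm, ref, tD = 36) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  use <- target$schedule$mid < tD
  if (sum(use) < 2L)
    stop("need at least 2 pre-task frames", call. = FALSE)
  A <- cbind(c_nlm, ref$values)
  th <- nnls2(A[use, , drop = FALSE], target$values[use],
              target$weights[use])
  pred <- drop(A %*% th)
  structure(list(predicted = pred, theta_nlm = th[1L], theta_r = th[2L],
                 c_nlm = c_nlm,
                 degenerate = all(th == 0) && any(target$values[use] != 0)),
            class = "baseline_prediction")
}

#' Percent-difference residuals
#'
#' `R_pct(t) = 100 [1 - C(t) / C_hat(t)]`. Frames where the predicted
#' baseline falls below a positivity floor (default 5% of its maximum) are
#' excluded (set `NA`) to avoid exploding ratios at near-zero activity.
#'
#' @param target A [tac()] or numeric series (measured TAC).
#' @param baseline A `baseline_prediction` or numeric series.
#' @param floor_frac Positivity floor as a fraction of the baseline's
#'   maximum.
#' @return Numeric percent series with `NA` at excluded frames.
#' @export
percent_residuals <- function(target, baseline, floor_frac = 0.05) {
  C <- if (inherits(target, "tac")) target$values else as.numeric(target)
  B <- if (inherits(baseline, "baseline_prediction")) baseline$predicted
       else as.numeric(baseline)
  if (length(C) != length(B))
    stop("series lengths differ", call. = FALSE)
  floor <- floor_frac * max(B)
  ok <- B > floor
  if (!any(ok))
    stop("all frames below the baseline positivity floor", call. = FALSE)
  out <- rep(NA_real_, length(C))
  out[ok] <- 100 * (1 - C[ok] / B[ok])
  out
}

#' Residual-level task response predictor
#'
#' Task-block indicator convolved with the gamma-variate kernel
#' `g(u) = (u/L) exp(-u/L)` on a 0.1-min grid, normalized to unit maximum
#' and sampled at frame mid-times. `P(t) = 0` before the first block.
#'
#' @param blocks List or matrix of task blocks `[start, end]` in minutes,
#'   ordered and non-overlapping.
#' @param L Kernel broadness (min); default 10.
#' @param schedule A [frame_schedule()].
#' @param kernel `"gamma"` for `(u/L) exp(-u/L)` (default) or a function
#'   of `u` for alternatives.
#' @return List of class `predictor_spec`: `P` (at frame mid-times),
#'   `t_fine`, `P_fine`, `blocks`, `L`, `lambda` (normalization constant).
#' @export
make_predictor <- function(blocks, L = 10, schedule = default_schedule(),
                           kernel = "gamma") {
  if (is.matrix(blocks)) blocks <- split(blocks, row(blocks))
  blocks <- lapply(blocks, as.numeric)
  if (length(blocks) == 0L) stop("no task blocks given", call. = FALSE)
  starts <- vapply(blocks, `[`, numeric(1), 1L)
  ends <- vapply(blocks, `[`, numeric(1), 2L)
  if (any(ends <= starts) || is.unsorted(starts) ||
      any(starts[-1L] < ends[-length(ends)]))
    stop("blocks must be ordered, non-overlapping, with end > start",
         call. = FALSE)
  t_end <- max(schedule$start + schedule$duration)
  dt <- 0.1
  t_fine <- seq(0, t_end, by = dt)
  ind <- rep(0, length(t_fine))
  for (k in seq_along(starts))
    ind[t_fine > starts[k] & t_fine <= ends[k]] <- 1
  g <- if (is.function(kernel)) kernel else
    function(u) (u / L) * exp(-u / L)
  ker <- g(seq(0, t_end, by = dt))
  conv <- stats::convolve(ind, rev(ker), type = "open")[seq_along(t_fine)] * dt
  lambda <- 1 / max(conv)
  P_fine <- conv * lambda
  P_fine[t_fine <= starts[1L]] <- 0
  P <- stats::approx(t_fine, P_fine, xout = schedule$mid, rule = 2)$y
  P[schedule$mid <= starts[1L]] <- 0
  structure(list(P = P, t_fine = t_fine, P_fine = P_fine,
                 blocks = cbind(start = starts, end = ends),
                 L = L, lambda = lambda),
            class = "predictor_spec")
}

#' GLM estimate of the residual response magnitude
#'
#' Single-regressor, no-intercept weighted least squares of the percent
#' residuals on the task predictor:
#' `beta = sum(w P R) / sum(w P^2)`. `beta` reads as the voxel TAC's
#' maximal percent decrease from baseline. `NA` residual frames are
#' dropped.
#'
#' @param residuals Percent-residual series (may contain `NA`).
#' @param predictor A [make_predictor()] result or numeric `P` series.
#' @param weights Optional per-frame weights (default uniform).
#' @return List: `beta`, `se` (residual-based standard error), `df`.
#' @export
fit_beta <- function(residuals, predictor, weights = NULL) {
  P <- if (inherits(predictor, "predictor_spec")) predictor$P else
    as.numeric(predictor)
  if (length(P) != length(residuals))
    stop("predictor and residuals lengths differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(P))
  ok <- !is.na(residuals)
  P <- P[ok]; R <- residuals[ok]; w <- weights[ok]
  if (all(P == 0))
    stop("predictor is zero on all usable frames; beta undefined",
         call. = FALSE)
  spp <- sum(w * P^2)
  beta <- sum(w * P * R) / spp
  res <- R - beta * P
  df <- length(R) - 1L
  se <- if (df > 0) sqrt(sum(w * res^2) / df / spp) else NA_real_
  list(beta = beta, se = se, df = df)
}

#' Run the full RSD-Hybrid-IMRTM pipeline
#'
#' Pre-task MRTM over the striatum, z-scored kinetic coordinates,
#' non-local-means weights, an lp-ntPET detection pass, IMRTM baselines
#' for flagged voxels, NLM aggregation of the hybrid regressor set,
#' per-voxel scale/spill-in fitting, percent residuals and the GLM
#' estimate of `beta`.
#'
#' @param image A [dynamic_image()].
#' @param striatal_mask Logical or integer 3D array, the striatal voxels.
#' @param ref_mask Logical or integer 3D array, the reference region.
#' @param task_blocks Task blocks for [make_predictor()]; default a single
#'   10-min block at `tD`.
#' @param tD Task start (min).
#' @param basis_set lp-ntPET detection basis library; default the 17-member
#'   set.
#' @param h2 NLM bandwidth.
#' @param L Predictor kernel broadness (min).
#' @param p_threshold F-test replacement threshold.
#' @param weights_mode Frame weight mode, `"uniform"` or `"duration"`.
#' @param hybrid Replace flagged voxels with IMRTM baselines (`TRUE`,
#'   the full pipeline); `FALSE` keeps measured TACs as regressors
#'   everywhere (ablation).
#' @param gamma_nonneg Passed to the lp-ntPET pass.
#' @return List of class `rsd_result`: `beta` ([parametric_map()]),
#'   `beta_values`, `residuals` (matrix), `baselines` (matrix),
#'   `theta_nlm`, `theta_r`, `p_lpntpet`, `replaced` (logical),
#'   `index` (voxel indices), `diagnostics`.
#' @export
run_rsd_hybrid <- function(image, striatal_mask, ref_mask,
                           task_blocks = NULL, tD = 36,
                           basis_set = NULL, h2 = 0.5, L = 10,
                           p_threshold = 0.05,
                           weights_mode = c("uniform", "duration"),
                           hybrid = TRUE, gamma_nonneg = TRUE) {
  stopifnot(inherits(image, "dynamic_image"))
  weights_mode <- match.arg(weights_mode)
  sch <- image$schedule
  mid <- sch$mid
  w <- frame_weights(sch, weights_mode)
  if (is.null(task_blocks)) task_blocks <- list(c(tD, tD + 10))
  if (is.null(basis_set))
    basis_set <- make_basis_set(tD = tD,
                                tP_list = seq(tD + 1, tD + 15,
                                              length.out = 17),
                                alpha = 1, schedule = sch)
  ex <- extract_tacs(image, striatal_mask)
  M <- ex$tacs
  ref <- reference_tac(image, ref_mask)

  pre <- mrtm_map(M, ref$values, mid, w, use = mid < tD)
  ok <- stats::complete.cases(pre$coef)
  if (!all(ok)) {
    # degenerate pre-task fits: drop those voxels from the analysis
    M <- M[ok, , drop = FALSE]
    ex$index <- ex$index[ok, , drop = FALSE]
    pre$coef <- pre$coef[ok, , drop = FALSE]
  }
  coords <- zscore_params(pre$coef)
  W <- nlm_weights(coords, h2)

  lp <- lpntpet_map(M, ref$values, mid, w, basis_set, gamma_nonneg)
  im <- imrtm_map(M, ref$values, mid, w, tD)
  p_use <- if (hybrid) lp$p else rep(1, nrow(M))
  rs <- build_regressor_set(M, p_use, im$baseline, p_threshold)
  nb <- nlm_baseline(W, rs$regressors)
  c_nlm <- nb$c_nlm
  if (any(nb$isolated))  # isolated voxels fall back to their IMRTM baseline
    c_nlm[nb$isolated, ] <- im$baseline[nb$isolated, , drop = FALSE]

  nvox <- nrow(M)
  use_pre <- mid < tD
  theta <- matrix(0, nvox, 2L)
  A2 <- ref$values[use_pre]
  for (v in seq_len(nvox))
    theta[v, ] <- nnls2(cbind(c_nlm[v, use_pre], A2), M[v, use_pre],
                        w[use_pre])
  baselines <- theta[, 1L] * c_nlm + theta[, 2L] %o% ref$values

  pred <- make_predictor(task_blocks, L, sch)
  beta <- rep(NA_real_, nvox)
  residuals <- matrix(NA_real_, nvox, length(mid))
  for (v in seq_len(nvox)) {
    r <- tryCatch(percent_residuals(M[v, ], baselines[v, ]),
                  error = function(e) NULL)
    if (is.null(r)) next
    residuals[v, ] <- r
    beta[v] <- tryCatch(fit_beta(r, pred, w)$beta, error = function(e)
      NA_real_)
  }

  vol <- array(NA_real_, dim(image$data)[1:3])
  vol[ex$index] <- beta
  msk <- array(FALSE, dim(image$data)[1:3])
  msk[ex$index] <- !is.na(beta)
  bmap <- parametric_map(vol, "beta", msk)
  attr(bmap, "voxel_size") <- image$voxel_size

  structure(list(
    beta = bmap, beta_values = beta, residuals = residuals,
    baselines = baselines, theta_nlm = theta[, 1L], theta_r = theta[, 2L],
    p_lpntpet = lp$p, replaced = rs$provenance == "model",
    gamma_lpntpet = lp$gamma, F_lpntpet = lp$F,
    index = ex$index, predictor = pred, ref_tac = ref,
    pre_coef = pre$coef,
    diagnostics = list(
      n_voxels = nvox,
      frac_replaced = mean(rs$provenance == "model"),
      frac_theta_r_pos = mean(theta[, 2L] > 0),
      n_isolated = sum(nb$isolated),
      n_failed = sum(is.na(beta)))),
    class = "rsd_result")
}
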