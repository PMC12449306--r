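#' Remove in-plane edge voxels from a mask
#'
#' Per axial slice, removes voxels with any 4-neighbor outside the mask
#' (one-voxel in-plane erosion), limiting partial-volume false positives
#' at region edges.
#'
#' @param mask Logical or integer 3D array.
#' @return Logical 3D array. May be empty (with a warning).
#' @export
remove_inplane_edges <- function(mask) {
  m <- mask_logical(mask)
  stopifnot(length(dim(m)) == 3L)
  d <- dim(m)
  pad <- function(shift_x, shift_y) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]) + shift_x
    ys <- seq_len(d[2]) + shift_y
    okx <- xs >= 1 & xs <= d[1]
    oky <- ys >= 1 & ys <= d[2]
    out[okx, oky, ] <- m[xs[okx], ys[oky], , drop = FALSE]
    out
  }
  er <- m & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  if (!any(er) && any(m))
    warning("in-plane erosion removed every voxel", call. = FALSE)
  er
}

#' ROC curve from parametric maps across noisy realizations
#'
#' Binarizes each realization's map at thresholds from 0 to the maximum
#' value across all realizations; the true-positive rate pools all
#' ground-truth release voxels and the false-positive rate is computed
#' within the release-free evaluation mask; mean curves are taken across
#' realizations.
#'
#' @param maps List of [parametric_map()]s (or 3D arrays), one per
#'   realization.
#' @param truth_mask Logical 3D array of ground-truth release voxels.
#' @param fpr_mask Logical 3D array of release-free voxels (disjoint from
#'   `truth_mask`).
#' @param n_thresholds Number of evenly spaced thresholds (default 201).
#' @return List of class `roc_curve`: `thresholds`, `tpr`, `fpr` (mean
#'   across realizations), `tpr_all` / `fpr_all` (realization x threshold
#'   matrices).
#' @export
roc_from_maps <- function(maps, truth_mask, fpr_mask, n_thresholds = 201) {
  if (length(maps) < 1L) stop("need at least one realization", call. = FALSE)
  truth_mask <- mask_logical(truth_mask)
  fpr_mask <- mask_logical(fpr_mask)
  if (!any(truth_mask) || !any(fpr_mask))
    stop("truth and FPR masks must be nonempty", call. = FALSE)
  if (any(truth_mask & fpr_mask))
    stop("truth and FPR masks must be disjoint", call. = FALSE)
  vals <- lapply(maps, function(m)
    if (inherits(m, "parametric_map")) m$values else m)
  vmax <- max(vapply(vals, function(v)
    max(v[truth_mask | fpr_mask], na.rm = TRUE), numeric(1)))
  if (!is.finite(vmax) || vmax <= 0) vmax <- 1
  thr <- seq(0, vmax, length.out = n_thresholds)
  nr <- length(vals)
  tpr_all <- matrix(0, nr, n_thresholds)
  fpr_all <- matrix(0, nr, n_thresholds)
  for (i in seq_len(nr)) {
    tv <- vals[[i]][truth_mask]
    fv <- vals[[i]][fpr_mask]
    tv[is.na(tv)] <- -Inf
    fv[is.na(fv)] <- -Inf
    # value > threshold detection; vapply over the threshold grid
    tpr_all[i, ] <- vapply(thr, function(th) mean(tv > th), numeric(1))
    fpr_all[i, ] <- vapply(thr, function(th) mean(fv > th), numeric(1))
  }
  # complete the curve with the threshold -Inf endpoint (FPR = TPR = 1)
  structure(list(thresholds = c(-Inf, thr),
                 tpr = c(1, colMeans(tpr_all)),
                 fpr = c(1, colMeans(fpr_all)),
                 tpr_all = cbind(1, tpr_all), fpr_all = cbind(1, fpr_all)),
            class = "roc_curve")
}

#' Interpolate the mean TPR at a requested mean FPR
#'
#' @param roc A [roc_from_maps()] result.
#' @param fpr Requested false-positive rate (within the achieved range).
#' @return Interpolated true-positive rate.
#' @export
tpr_at_fpr <- function(roc, fpr) {
  stopifnot(inherits(roc, "roc_curve"))
  # upper envelope: best mean TPR attainable at each mean FPR, made
  # monotone so the query interpolates along achievable operating points
  fo <- sort(unique(roc$fpr))
  to <- vapply(fo, function(f) max(roc$tpr[roc$fpr == f]), numeric(1))
  to <- cummax(to)
  if (fpr < min(fo) || fpr > max(fo))
    stop(sprintf("requested FPR %.3g outside achieved range [%.3g, %.3g]",
                 fpr, min(fo), max(fo)), call. = FALSE)
  stats::approx(fo, to, xout = fpr)$y
}

#' Track a release metric across amplitude levels
#'
#' Cluster-mean metric per dopamine amplitude level, with error bars
#' combining the across-voxel and across-realization standard deviations
#' in quadrature.
#'
#' @param maps_by_level Named list; element `l` is the list of maps
#'   (realizations) at that amplitude level.
#' @param cluster_mask Logical 3D array over which voxels are averaged.
#' @return Data frame: `level`, `mean`, `sd_voxels`, `sd_nrs`, `error`.
#' @export
tracking_curve <- function(maps_by_level, cluster_mask) {
  if (length(maps_by_level) < 2L)
    stop("need at least two amplitude levels", call. = FALSE)
  cluster_mask <- mask_logical(cluster_mask)
  rows <- lapply(names(maps_by_level), function(lv) {
    maps <- maps_by_level[[lv]]
    if (length(maps) == 0L)
      stop(sprintf("no maps for level %s", lv), call. = FALSE)
    per_nr <- vapply(maps, function(m) {
      v <- if (inherits(m, "parametric_map")) m$values else m
      mean(v[cluster_mask], na.rm = TRUE)
    }, numeric(1))
    allv <- unlist(lapply(maps, function(m) {
      v <- if (inherits(m, "parametric_map")) m$values else m
      v[cluster_mask]
    }))
    sd_vox <- stats::sd(allv, na.rm = TRUE)
    sd_nr <- if (length(per_nr) > 1L) stats::sd(per_nr) else 0
    data.frame(level = lv, mean = mean(per_nr),
               sd_voxels = sd_vox, sd_nrs = sd_nr,
               error = sqrt(sd_vox^2 + sd_nr^2))
  })
  do.call(rbind, rows)
}

#' Sparsity-binarize a parametric map
#'
#' Keeps the top `1 - s` fraction of strictly positive values (`s = 0`
#' keeps all positive voxels, `s = 1` none), ties broken by voxel index.
#'
#' @param map A [parametric_map()] or 3D array.
#' @param s Sparsity in `[0, 1]`: fraction of lowest positive voxels
#'   removed.
#' @return Logical 3D array.
#' @export
sparsity_binarize <- function(map, s) {
  stopifnot(s >= 0, s <= 1)
  v <- if (inherits(map, "parametric_map")) map$values else map
  pos <- which(!is.na(v) & v > 0)
  out <- array(FALSE, dim(v))
  if (length(pos) == 0L) {
    warning("no positive voxels to threshold", call. = FALSE)
    return(out)
  }
  keep <- round((1 - s) * length(pos))
  if (keep == 0L) return(out)
  ord <- pos[order(-v[pos], pos)]
  out[ord[seq_len(keep)]] <- TRUE
  out
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 0 when both masks are
#' empty.
#'
#' @param a,b Logical 3D arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- mask_logical(a); b <- mask_logical(b)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0L) {
    message("both masks empty; dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' One-sample t-map across subjects
#'
#' Voxelwise `t = mean / (SD / sqrt(n))` testing mean > 0 over subject
#' maps. Zero-variance voxels get an infinite-t sentinel (sign of the
#' mean) and are flagged.
#'
#' @param maps List of per-subject [parametric_map()]s (or 3D arrays) on a
#'   common grid.
#' @return List: `tmap` ([parametric_map()]), `n` (per-voxel subject
#'   count), `zero_variance` (logical array of flagged voxels).
#' @export
one_sample_tmap <- function(maps) {
  vals <- lapply(maps, function(m)
    if (inherits(m, "parametric_map")) m$values else m)
  stk <- simplify2array(vals)  # x, y, z, subject
  n <- apply(!is.na(stk), 1:3, sum)
  mu <- apply(stk, 1:3, mean, na.rm = TRUE)
  sdv <- apply(stk, 1:3, stats::sd, na.rm = TRUE)
  ok <- n >= 2L
  tval <- array(NA_real_, dim(mu))
  zerovar <- ok & sdv == 0
  normal <- ok & sdv > 0
  tval[normal] <- mu[normal] / (sdv[normal] / sqrt(n[normal]))
  tval[zerovar] <- sign(mu[zerovar]) * Inf
  msk <- ok & is.finite(tval)
  tval[zerovar] <- NA_real_  # sentinel voxels excluded from the map proper
  list(tmap = parametric_map(tval, "t", msk), n = n,
       zero_variance = zerovar)
}

#' Simplified RSD-k-means comparator
#'
#' The earlier data-driven baseline pipeline, kept as a comparator:
#' k = 3 k-means on unit-area-normalized pre-task voxel TACs; cluster-mean
#' TACs as baseline regressors; per-voxel multiple regression on pre-task
#' frames extrapolated to all frames; one removal iteration excluding
#' voxels whose preliminary beta z-score exceeds `z_remove` from the
#' regressor averages; percent residuals and the GLM beta as in the main
#' pipeline. Inherits the localized-release assumption: with wide-spread
#' release the cluster means are contaminated and beta is biased toward
#' zero.
#'
#' @inheritParams run_rsd_hybrid
#' @param k Number of k-means clusters.
#' @param z_remove Removal z-threshold on preliminary beta.
#' @param seed RNG seed for k-means.
#' @return List of class `rsd_kmeans_result`: `beta` ([parametric_map()]),
#'   `beta_values`, `index`, `diagnostics`.
#' @export
rsd_kmeans_comparator <- function(image, striatal_mask, ref_mask,
                                  task_blocks = NULL, tD = 36,
                                  L = 10, k = 3, z_remove = 2, seed = 1,
                                  weights_mode = c("uniform", "duration")) {
  stopifnot(inherits(image, "dynamic_image"))
  weights_mode <- match.arg(weights_mode)
  sch <- image$schedule
  mid <- sch$mid
  w <- frame_weights(sch, weights_mode)
  if (is.null(task_blocks)) task_blocks <- list(c(tD, tD + 10))
  ex <- extract_tacs(image, striatal_mask)
  M <- ex$tacs
  ref <- reference_tac(image, ref_mask)
  use_pre <- mid < tD
  pre <- M[, use_pre, drop = FALSE]
  area <- rowSums(pre)
  shapes <- pre / pmax(area, .Machine$double.eps)

  km <- NULL
  for (attempt in 0:4) {
    set.seed(as.integer(seed + attempt))
    km <- tryCatch(stats::kmeans(shapes, centers = k, nstart = 3,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, k) > 0)) break
    km <- NULL
  }
  if (is.null(km))
    stop("k-means failed to produce nonempty clusters", call. = FALSE)

  pred <- make_predictor(task_blocks, L, sch)

  fit_pass <- function(include) {
    regs <- t(vapply(seq_len(k), function(g) {
      sel <- km$cluster == g & include
      if (!any(sel)) sel <- km$cluster == g  # empty after removal: keep all
      colMeans(M[sel, , drop = FALSE])
    }, numeric(ncol(M))))
    X <- t(regs)                     # frames x k
    Xp <- X[use_pre, , drop = FALSE]
    co <- tryCatch(qr.solve(Xp * sqrt(w[use_pre]),
                            t(M[, use_pre, drop = FALSE] *
                                rep(sqrt(w[use_pre]),
                                    each = nrow(M)))),
                   error = function(e) NULL)
    if (is.null(co)) stop("degenerate comparator regression", call. = FALSE)
    baselines <- t(X %*% co)         # voxels x frames
    beta <- rep(NA_real_, nrow(M))
    for (v in seq_len(nrow(M))) {
      r <- tryCatch(percent_residuals(M[v, ], baselines[v, ]),
                    error = function(e) NULL)
      if (is.null(r)) next
      beta[v] <- tryCatch(fit_beta(r, pred, w)$beta,
                          error = function(e) NA_real_)
    }
    beta
  }

  beta0 <- fit_pass(rep(TRUE, nrow(M)))
  z <- (beta0 - mean(beta0, na.rm = TRUE)) / stats::sd(beta0, na.rm = TRUE)
  keep <- !is.na(z) & z <= z_remove
  beta <- fit_pass(keep)

  vol <- array(NA_real_, dim(image$data)[1:3])
  vol[ex$index] <- beta
  msk <- array(FALSE, dim(image$data)[1:3])
  msk[ex$index] <- !is.na(beta)
  bmap <- parametric_map(vol, "beta", msk)
  attr(bmap, "voxel_size") <- image$voxel_size
  structure(list(beta = bmap, beta_values = beta, index = ex$index,
                 diagnostics = list(k = k,
                                    n_removed = sum(!keep),
                                    cluster_sizes = tabulate(km$cluster, k))),
            class = "rsd_kmeans_result")
}
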