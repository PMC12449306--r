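#' Analytic plasma input function
#'
#' A rise-and-triexponential-decay plasma curve Cp(t) of the Feng family,
#' rescaled to a chosen peak concentration. Cp(0) = 0 and Cp(t) >= 0 on the
#' scan window. The reference-tissue models never see Cp directly; it only
#' drives the forward competition model.
#'
#' @param peak_value Peak plasma concentration (kBq/mL-equivalent, the
#'   simulator's nominal activity unit; on the nM scale of the competition
#'   model, so the default keeps tracer receptor occupancy in the trace
#'   regime, a few percent of Bmax).
#' @param A1,A2,A3,l1,l2,l3 Shape parameters of
#'   `Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t)`
#'   before rescaling (t in minutes).
#' @return Object of class `input_function`: a list with the vectorized
#'   function `cp(t)`, `peak_time` and the parameters.
#' @export
input_function <- function(peak_value = 2,
                           A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
                           l1 = 4.1339, l2 = 0.1191, l3 = 0.0104) {
  raw <- function(t) {
    v <- (A1 * t - A2 - A3) * exp(-l1 * t) + A2 * exp(-l2 * t) +
      A3 * exp(-l3 * t)
    v[t <= 0] <- 0
    pmax(v, 0)
  }
  tg <- seq(0, 10, by = 0.001)
  vg <- raw(tg)
  scale <- peak_value / max(vg)
  structure(
    list(cp = function(t) scale * raw(t),
         peak_time = tg[which.max(vg)],
         peak_value = peak_value,
         params = c(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3)),
    class = "input_function")
}

#' Competition-model kinetic parameters
#'
#' Tracer and dopamine rate constants for the ntPET receptor-competition
#' model. Defaults describe striatal [11C]raclopride binding: tracer
#' KD = koff/kon = 10 nM with fast association/dissociation (so baseline
#' TACs are near-exactly one-tissue / MRTM-representable, as observed for
#' denoised raclopride data), DA KD = 250 nM, basal DA 96.4 nM (about 28%
#' basal D2 occupancy), giving a baseline BPND of about 3.
#'
#' @param K1 Plasma-to-tissue delivery (mL/min/g).
#' @param k2 Tissue-to-plasma clearance (1/min).
#' @param kon,koff Tracer-receptor association (1/(nM min)) and
#'   dissociation (1/min) rates.
#' @param Bmax Receptor density (nM).
#' @param kon_DA,koff_DA Dopamine-receptor rates.
#' @param DA_basal Basal synaptic dopamine concentration (nM).
#' @return Object of class `competition_params`.
#' @export
competition_params <- function(K1 = 0.1, k2 = 0.25,
                               kon = 0.1, koff = 1, Bmax = 42,
                               kon_DA = 0.04, koff_DA = 10,
                               DA_basal = 96.4) {
  p <- list(K1 = K1, k2 = k2, kon = kon, koff = koff, Bmax = Bmax,
            kon_DA = kon_DA, koff_DA = koff_DA, DA_basal = DA_basal)
  rates <- unlist(p[c("K1", "k2", "kon", "koff", "kon_DA", "koff_DA")])
  if (any(rates <= 0)) stop("all rate constants must be > 0", call. = FALSE)
  if (p$Bmax < 0) stop("Bmax must be >= 0", call. = FALSE)
  if (p$DA_basal < 0) stop("DA_basal must be >= 0", call. = FALSE)
  structure(p, class = "competition_params")
}

#' Dopamine release profile
#'
#' Timecourse shape of task-induced dopamine release: a gamma-variate
#' response starting at `tD`, peaking at `tP`, with sharpness `alpha`,
#' scaled to `DA_peak` nM above basal.
#'
#' @param tD Release start time (min).
#' @param tP Peak time (min), `tP > tD`.
#' @param alpha Sharpness (dimensionless, > 0).
#' @param DA_peak Peak dopamine increase above basal (nM, >= 0).
#' @return Object of class `release_profile`.
#' @export
release_profile <- function(tD = 36, tP = 40, alpha = 1, DA_peak = 100) {
  if (!(tP > tD) || tD < 0) stop("need tP > tD >= 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (DA_peak < 0) stop("DA_peak must be >= 0", call. = FALSE)
  structure(list(tD = tD, tP = tP, alpha = alpha, DA_peak = DA_peak),
            class = "release_profile")
}

# unit-peak gamma-variate response: 0 for t <= tD, 1 at t = tP
response_shape <- function(t, tD, tP, alpha) {
  u <- (t - tD) / (tP - tD)
  h <- ifelse(t > tD, u^alpha * exp(alpha * (1 - u)), 0)
  h[!is.finite(h)] <- 0
  h
}

#' Dopamine concentration timecourse
#'
#' `DA(t) = DA_basal + DA_peak * h(t)` with the unit-peak gamma-variate
#' response `h`; `DA(t) = DA_basal` for `t < tD`.
#'
#' @param profile A [release_profile()].
#' @param t Time(s) in minutes.
#' @param DA_basal Basal dopamine (nM); default the package's standard
#'   96.4 nM.
#' @return DA concentration (nM) at `t`.
#' @export
da_timecourse <- function(profile, t, DA_basal = 96.4) {
  stopifnot(inherits(profile, "release_profile"))
  DA_basal + profile$DA_peak *
    response_shape(t, profile$tD, profile$tP, profile$alpha)
}

# Solve the competition ODE system on a fine grid; returns total tissue
# activity F + B at the fine times. states: F free tracer, B bound tracer,
# B_DA receptor sites occupied by DA (nM).
solve_competition <- function(params, input, profile, t_fine, rtol = 1e-8) {
  prm <- params
  cpf <- input$cp
  deriv <- function(t, y, parms) {
    DA <- da_timecourse(profile, t, prm$DA_basal)
    avail <- prm$Bmax - y[2L] - y[3L]
    bindF <- prm$kon * y[1L] * avail
    bindDA <- prm$kon_DA * DA * avail
    list(c(
      prm$K1 * cpf(t) - prm$k2 * y[1L] - bindF + prm$koff * y[2L],
      bindF - prm$koff * y[2L],
      bindDA - prm$koff_DA * y[3L]))
  }
  out <- deSolve::lsoda(c(F = 0, B = 0, B_DA = 0), t_fine, deriv,
                        parms = NULL, rtol = rtol, atol = rtol * 1e-2)
  if (nrow(out) < length(t_fine) || any(!is.finite(out[, "F"])))
    stop("competition ODE integration failed to reach the final time",
         call. = FALSE)
  out[, "F"] + out[, "B"]
}

# Average a fine-grid curve over frames (duration average).
frame_average <- function(values, t_fine, schedule) {
  idx <- findInterval(t_fine, schedule$start, left.open = TRUE)
  ends <- schedule$start + schedule$duration
  keep <- idx >= 1L & t_fine <= ends[pmax(idx, 1L)] + 1e-9
  vapply(seq_along(schedule$start), function(k)
    mean(values[keep & idx == k]), numeric(1))
}

#' Simulate release and baseline TACs with the competition model
#'
#' Integrates the three-state receptor-competition ODE system (free tracer,
#' bound tracer, DA-occupied sites) from a zero initial state and returns
#' frame-duration-averaged TACs for the release condition and its
#' `DA_peak = 0` baseline twin. Setting `Bmax = 0` in `params` yields a
#' reference-region (non-binding) TAC.
#'
#' @param params A [competition_params()].
#' @param input An [input_function()].
#' @param profile A [release_profile()].
#' @param schedule A [frame_schedule()].
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param dt_fine Fine output grid spacing (min) used for frame averaging.
#' @return List with [tac()] elements `release` and `baseline`.
#' @export
simulate_tac <- function(params, input, profile, schedule,
                         rtol = 1e-8, dt_fine = 0.1) {
  stopifnot(inherits(params, "competition_params"),
            inherits(input, "input_function"),
            inherits(profile, "release_profile"),
            inherits(schedule, "frame_schedule"))
  t_end <- max(schedule$start + schedule$duration)
  t_fine <- seq(0, t_end, by = dt_fine)
  rel <- solve_competition(params, input, profile, t_fine, rtol)
  base_prof <- release_profile(profile$tD, profile$tP, profile$alpha, 0)
  bas <- if (profile$DA_peak == 0) rel else
    solve_competition(params, input, base_prof, t_fine, rtol)
  list(release = tac(frame_average(rel, t_fine, schedule), schedule),
       baseline = tac(frame_average(bas, t_fine, schedule), schedule))
}

#' Digital phantom specification
#'
#' Grid geometry, ellipsoidal bilateral caudate/putamen ROIs, a cerebellar
#' reference ellipsoid, localized release-cluster sizes, and the amplitude
#' of the smooth Bmax modulation field. Defaults: 64 x 64 x 12 voxels at
#' 1.4 x 1.4 x 2.8 mm; localized clusters of 46 / 85 / 69 voxels in the
#' left caudate / left putamen / right putamen (17-22% of their ROIs); the
#' right caudate is release-free in every scenario.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_size mm triplet.
#' @param cluster_sizes Named localized cluster voxel counts
#'   (`caudate_L`, `putamen_L`, `putamen_R`).
#' @param mid_fraction Fraction of ROI volume used by mid-sized clusters.
#' @param bmax_mod Half-range of the relative Bmax modulation (0.2 = +/-20%).
#' @param rois Optional list overriding the ellipsoid definitions; each
#'   element is `list(center = c(x, y, z), radii = c(rx, ry, rz))` in voxel
#'   units, named `caudate_L`, `caudate_R`, `putamen_L`, `putamen_R`,
#'   `cerebellum`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 12),
                         voxel_size = c(1.4, 1.4, 2.8),
                         cluster_sizes = c(caudate_L = 46, putamen_L = 85,
                                           putamen_R = 69),
                         mid_fraction = 0.36,
                         bmax_mod = 0.2,
                         rois = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  cx <- (grid_shape[1] + 1) / 2
  cy <- (grid_shape[2] + 1) / 2
  cz <- (grid_shape[3] + 1) / 2
  sc <- grid_shape / c(64, 64, 12)  # scale ellipsoids with the grid
  if (is.null(rois)) {
    rois <- list(
      caudate_L = list(center = c(cx - 7 * sc[1], cy + 4 * sc[2], cz),
                       radii = c(3.0, 5.2, 3.5) * sc),
      caudate_R = list(center = c(cx + 7 * sc[1], cy + 4 * sc[2], cz),
                       radii = c(3.0, 5.2, 3.5) * sc),
      putamen_L = list(center = c(cx - 14 * sc[1], cy - 2 * sc[2], cz),
                       radii = c(3.6, 6.6, 4.0) * sc),
      putamen_R = list(center = c(cx + 14 * sc[1], cy - 2 * sc[2], cz),
                       radii = c(3.6, 6.6, 4.0) * sc),
      cerebellum = list(center = c(cx, 6 * sc[2], cz),
                        radii = c(11, 4.5, 3.5) * sc))
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 cluster_sizes = cluster_sizes, mid_fraction = mid_fraction,
                 bmax_mod = bmax_mod, rois = rois),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2])
  z <- seq_len(grid_shape[3])
  dx2 <- ((x - center[1]) / radii[1])^2
  dy2 <- ((y - center[2]) / radii[2])^2
  dz2 <- ((z - center[3]) / radii[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  arr
}

# grow a cluster of exactly n voxels inside roi_mask from its most anterior
# (max y) point, by distance to the seed; lexicographic tie-break
grow_cluster <- function(roi_mask, n) {
  idx <- which(roi_mask)
  if (n > length(idx))
    stop("requested cluster larger than its ROI", call. = FALSE)
  co <- arrayInd(idx, dim(roi_mask))
  seed <- co[order(-co[, 2], co[, 1], co[, 3])[1L], ]
  d2 <- (co[, 1] - seed[1])^2 + (co[, 2] - seed[2])^2 +
    ((co[, 3] - seed[3]) * 2)^2  # z weighted by slice anisotropy
  ord <- order(d2, co[, 3], co[, 2], co[, 1])
  m <- array(FALSE, dim(roi_mask))
  m[idx[ord[seq_len(n)]]] <- TRUE
  m
}

#' Build the phantom geometry
#'
#' Deterministic ROI label masks, scenario release-cluster masks and the
#' smooth per-voxel Bmax modulation field. ROI labels: 1 = left caudate,
#' 2 = right caudate (always release-free), 3 = left putamen,
#' 4 = right putamen, 5 = cerebellum.
#'
#' @param spec A [phantom_spec()].
#' @return List with `labels` (integer 3D array), `striatum` (logical),
#'   `cerebellum` (logical), `clusters` (list of logical release masks per
#'   scenario: `localized`, `mid`, `global`), `bmax_field` (relative
#'   modulation, quantized to 1% steps) and `roi_counts`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  labels <- array(0L, gs)
  roi_names <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R")
  masks <- list()
  for (i in seq_along(roi_names)) {
    m <- ellipsoid_mask(gs, spec$rois[[roi_names[i]]]$center,
                        spec$rois[[roi_names[i]]]$radii)
    masks[[roi_names[i]]] <- m & labels == 0L
    labels[masks[[roi_names[i]]]] <- i
  }
  cereb <- ellipsoid_mask(gs, spec$rois$cerebellum$center,
                          spec$rois$cerebellum$radii) & labels == 0L
  labels[cereb] <- 5L
  striatum <- labels >= 1L & labels <= 4L

  release_rois <- c("caudate_L", "putamen_L", "putamen_R")
  loc <- array(FALSE, gs); mid <- array(FALSE, gs); glob <- array(FALSE, gs)
  for (rn in release_rois) {
    nloc <- spec$cluster_sizes[[rn]]
    nmid <- max(nloc, round(spec$mid_fraction * sum(masks[[rn]])))
    loc <- loc | grow_cluster(masks[[rn]], nloc)
    mid <- mid | grow_cluster(masks[[rn]], nmid)
    glob <- glob | masks[[rn]]
  }

  # smooth deterministic modulation field, +/- bmax_mod, 1% quantization
  x <- seq_len(gs[1]) / gs[1]; y <- seq_len(gs[2]) / gs[2]
  z <- seq_len(gs[3]) / gs[3]
  f <- outer(outer(sin(2 * pi * (0.9 * x + 0.13)),
                   cos(2 * pi * (0.7 * y - 0.21)), "+") / 2,
             sin(pi * z), "*")
  bmax_field <- 1 + round(spec$bmax_mod * f / 0.01) * 0.01

  list(labels = labels, striatum = striatum, cerebellum = cereb,
       clusters = list(localized = loc, mid = mid, global = glob),
       bmax_field = bmax_field,
       roi_counts = vapply(masks, sum, integer(1)))
}

#' Add frame-scaled Gaussian noise to a dynamic image
#'
#' Zero-mean Gaussian noise with variance proportional to
#' `value / frame_duration`, scaled so the relative SD at the frame
#' containing 40 min, for a voxel at `calibration_value`, equals `level`.
#'
#' @param image A [dynamic_image()].
#' @param level Target relative SD (0 disables noise).
#' @param seed Integer RNG seed; realizations are reproducible.
#' @param calibration_value Activity of the calibration voxel; default the
#'   median over `calibration_mask` (or of all positive voxels) at the
#'   40-min frame.
#' @param calibration_mask Optional logical mask (e.g. the striatum).
#' @return A noisy [dynamic_image()].
#' @export
add_noise <- function(image, level, seed,
                      calibration_value = NULL, calibration_mask = NULL) {
  stopifnot(inherits(image, "dynamic_image"), level >= 0)
  if (level == 0) return(image)
  sch <- image$schedule
  k40 <- which.min(abs(sch$mid - 40))
  if (is.null(calibration_value)) {
    fr <- image$data[, , , k40]
    calibration_value <- if (!is.null(calibration_mask))
      stats::median(fr[calibration_mask]) else
        stats::median(fr[fr > 0])
  }
  s0 <- level * sqrt(calibration_value * sch$duration[k40])
  sd_arr <- sweep(pmax(image$data, 0), 4L, sch$duration, "/")
  sd_arr <- s0 * sqrt(sd_arr)
  set.seed(as.integer(seed %% .Machine$integer.max))
  noisy <- image$data + array(stats::rnorm(length(sd_arr)),
                              dim(sd_arr)) * sd_arr
  dynamic_image(noisy, image$voxel_size, sch)
}

# row-normalized 1D Gaussian convolution matrix (edge-renormalized)
gauss_filter_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  D <- outer(i, i, "-")
  K <- exp(-0.5 * (D / sigma)^2)
  K[abs(D) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

boxcar_filter_matrix <- function(n, width) {
  if (width <= 1) return(diag(n))
  offs <- seq_len(width) - ceiling(width / 2)
  K <- matrix(0, n, n)
  for (o in offs) {
    j <- seq_len(n) + o
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + 1
  }
  K / rowSums(K)
}

# multiply filter matrix along dimension `d` of 4D array
apply_along <- function(arr, K, d) {
  dm <- dim(arr)
  perm <- c(d, setdiff(seq_len(4L), d))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dm[d])
  m <- K %*% m
  a <- array(m, dim = dm[perm])
  aperm(a, order(perm))
}

#' Spatio-temporal Gaussian smoothing stand-in
#'
#' Separable Gaussian spatial smoothing (stated FWHM, edge-renormalized so
#' constants are preserved) plus a boxcar temporal average, standing in for
#' scanner-side 4D denoising.
#'
#' @param image A [dynamic_image()].
#' @param spatial_fwhm Isotropic spatial kernel FWHM in mm. The default
#'   (3 mm) models the effective resolution cost of a resolution-
#'   preserving 4D denoiser (about the scanner point-spread scale), not
#'   the denoiser's much larger noise-suppression kernel.
#' @param temporal_frames Temporal boxcar width in frames (default 2).
#' @return Smoothed [dynamic_image()].
#' @export
smooth_stand_in <- function(image, spatial_fwhm = 3, temporal_frames = 2) {
  stopifnot(inherits(image, "dynamic_image"),
            spatial_fwhm >= 0, temporal_frames >= 1)
  arr <- image$data
  sig_mm <- spatial_fwhm / (2 * sqrt(2 * log(2)))
  for (d in 1:3) {
    sig <- sig_mm / image$voxel_size[d]
    if (sig > 1e-8)
      arr <- apply_along(arr, gauss_filter_matrix(dim(arr)[d], sig), d)
  }
  if (temporal_frames > 1)
    arr <- apply_along(arr, boxcar_filter_matrix(dim(arr)[4L],
                                                 as.integer(temporal_frames)),
                       4L)
  dynamic_image(arr, image$voxel_size, image$schedule)
}

#' Default 75 x 1-minute frame schedule
#'
#' The package's standard simulation framing: 75 one-minute frames covering
#' a 0-75 min scan, resolving a 36-min task start.
#'
#' @return A [frame_schedule()].
#' @export
default_schedule <- function() frame_schedule(0:74, rep(1, 75))

#' Noise-free phantom study
#'
#' Assembles the noise-free release and ground-truth baseline dynamic
#' images for one scenario and amplitude. TACs are computed by the
#' competition model once per distinct (quantized Bmax, release) pair and
#' cached. Striatal voxels get Bmax modulated by the phantom field;
#' cerebellar voxels use `Bmax = 0`; other tissue is scaled non-binding
#' background.
#'
#' @param spec A [phantom_spec()].
#' @param scenario `"localized"`, `"mid"` or `"global"`.
#' @param DA_peak Peak dopamine increase (nM above basal).
#' @param params A [competition_params()] (cluster Bmax is modulated around
#'   `params$Bmax`).
#' @param input An [input_function()].
#' @param profile_shape A [release_profile()] giving tD/tP/alpha (its
#'   `DA_peak` is ignored in favor of the `DA_peak` argument).
#' @param schedule A [frame_schedule()].
#' @param background_scale Background tissue activity as a fraction of the
#'   reference TAC.
#' @param rtol ODE relative tolerance.
#' @return List: `release` / `baseline` ([dynamic_image()]s), `phantom`
#'   (from [build_phantom()]), `release_mask`, `ref_tac` ([tac()]),
#'   `scenario`, `DA_peak`.
#' @export
simulate_noise_free <- function(spec = phantom_spec(),
                                scenario = c("localized", "mid", "global"),
                                DA_peak = 100,
                                params = competition_params(),
                                input = input_function(),
                                profile_shape = release_profile(DA_peak = 0),
                                schedule = default_schedule(),
                                background_scale = 0.7,
                                rtol = 1e-8) {
  scenario <- match.arg(scenario)
  ph <- build_phantom(spec)
  release_mask <- ph$clusters[[scenario]]
  t_end <- max(schedule$start + schedule$duration)
  t_fine <- seq(0, t_end, by = 0.1)
  prof <- release_profile(profile_shape$tD, profile_shape$tP,
                          profile_shape$alpha, DA_peak)
  prof0 <- release_profile(prof$tD, prof$tP, prof$alpha, 0)

  # reference (non-binding) curve
  ref_par <- params; ref_par$Bmax <- 0
  ref_fine <- solve_competition(ref_par, input, prof0, t_fine, rtol)
  ref_frames <- frame_average(ref_fine, t_fine, schedule)

  curve_cache <- new.env(parent = emptyenv())
  get_curve <- function(bmax_rel, released) {
    key <- sprintf("%.2f_%d", bmax_rel, released)
    if (!is.null(curve_cache[[key]])) return(curve_cache[[key]])
    p <- params; p$Bmax <- params$Bmax * bmax_rel
    pr <- if (released) prof else prof0
    v <- frame_average(solve_competition(p, input, pr, t_fine, rtol),
                       t_fine, schedule)
    curve_cache[[key]] <- v
    v
  }

  gs <- spec$grid_shape
  nfr <- length(schedule)
  nvox <- prod(gs)
  rel_flat <- matrix(rep(background_scale * ref_frames, each = nvox),
                     nvox, nfr)
  cereb_idx <- which(ph$cerebellum)
  rel_flat[cereb_idx, ] <- matrix(ref_frames, length(cereb_idx), nfr,
                                  byrow = TRUE)
  bas_flat <- rel_flat

  stri_idx <- which(ph$striatum)
  bm <- ph$bmax_field[stri_idx]
  in_rel <- release_mask[stri_idx]
  for (lev in unique(bm)) {
    sel <- stri_idx[bm == lev & !in_rel]
    if (length(sel)) {
      v <- get_curve(lev, FALSE)
      bas_flat[sel, ] <- matrix(v, length(sel), nfr, byrow = TRUE)
      rel_flat[sel, ] <- bas_flat[sel, ]
    }
    selr <- stri_idx[bm == lev & in_rel]
    if (length(selr)) {
      vb <- get_curve(lev, FALSE)
      vr <- if (DA_peak > 0) get_curve(lev, TRUE) else vb
      bas_flat[selr, ] <- matrix(vb, length(selr), nfr, byrow = TRUE)
      rel_flat[selr, ] <- matrix(vr, length(selr), nfr, byrow = TRUE)
    }
  }

  list(release = dynamic_image(array(rel_flat, c(gs, nfr)),
                               spec$voxel_size, schedule),
       baseline = dynamic_image(array(bas_flat, c(gs, nfr)),
                                spec$voxel_size, schedule),
       phantom = ph, release_mask = release_mask,
       ref_tac = tac(ref_frames, schedule),
       scenario = scenario, DA_peak = DA_peak)
}

#' Simulate a set of noisy phantom studies
#'
#' Orchestrates [simulate_noise_free()], [add_noise()] and
#' [smooth_stand_in()] for `n_realizations` seeded noisy realizations of
#' one scenario/amplitude.
#'
#' @inheritParams simulate_noise_free
#' @param n_realizations Number of noisy realizations.
#' @param seed Base integer seed; realization `i` uses `seed + i - 1`.
#' @param noise_level Relative SD at the 40-min frame of a mid-binding
#'   striatal voxel (default 0.10; the level injected here represents
#'   post-reconstruction-and-denoising voxel noise, since the smoothing
#'   stand-in applies only a mild resolution-cost blur).
#' @param spatial_fwhm,temporal_frames Denoising stand-in settings.
#' @return List with the shared `noise_free` study and `studies`, a list of
#'   noisy [dynamic_image()]s with their seeds.
#' @export
simulate_study <- function(spec = phantom_spec(),
                           scenario = c("localized", "mid", "global"),
                           DA_peak = 100, n_realizations = 1, seed = 1,
                           noise_level = 0.10,
                           spatial_fwhm = 3, temporal_frames = 2,
                           ...) {
  scenario <- match.arg(scenario)
  nf <- simulate_noise_free(spec, scenario, DA_peak, ...)
  k40 <- which.min(abs(nf$release$schedule$mid - 40))
  cal <- stats::median(nf$release$data[, , , k40][nf$phantom$striatum])
  studies <- lapply(seq_len(n_realizations), function(i) {
    s <- seed + i - 1L
    noisy <- add_noise(nf$release, noise_level, s, calibration_value = cal)
    list(image = smooth_stand_in(noisy, spatial_fwhm, temporal_frames),
         seed = s)
  })
  list(noise_free = nf, studies = studies,
       noise_level = noise_level, seed = seed)
}
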