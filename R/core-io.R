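#' Frame schedule for a dynamic PET acquisition
#'
#' Holds per-frame start times and durations (minutes) together with derived
#' frame mid-times. All kinetic models in the package are evaluated at the
#' frame mid-times.
#'
#' @param start_times Numeric vector of frame start times in minutes,
#'   strictly increasing.
#' @param durations Numeric vector of frame durations in minutes, all
#'   positive. Frames must not overlap.
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration` and `mid` (all minutes).
#' @examples
#' sch <- frame_schedule(0:4, rep(1, 5))
#' sch$mid
#' @export
frame_schedule <- function(start_times, durations) {
  start_times <- as.numeric(start_times)
  durations <- as.numeric(durations)
  if (length(start_times) != length(durations))
    stop("start_times and durations must have the same length", call. = FALSE)
  if (length(start_times) < 1L)
    stop("schedule must contain at least one frame", call. = FALSE)
  if (any(!is.finite(start_times)) || any(!is.finite(durations)))
    stop("schedule times must be finite", call. = FALSE)
  if (any(durations <= 0))
    stop("frame durations must be positive", call. = FALSE)
  if (length(start_times) > 1L) {
    if (any(diff(start_times) <= 0))
      stop("frame start times must be strictly increasing", call. = FALSE)
    ends <- start_times + durations
    if (any(ends[-length(ends)] > start_times[-1L] + 1e-9))
      stop("frames must not overlap", call. = FALSE)
  }
  structure(
    list(start = start_times, duration = durations,
         mid = start_times + durations / 2),
    class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g - %.4g min\n",
              length(x$start), x$start[1L],
              x$start[length(x$start)] + x$duration[length(x$duration)]))
  invisible(x)
}

#' Dynamic PET image
#'
#' A 4D activity array (x, y, z, frame) in kBq/mL on a regular voxel grid,
#' with its frame schedule. The frame axis must match the schedule length.
#'
#' @param data 4D numeric array, dimensions (nx, ny, nz, n_frames).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param schedule A [frame_schedule()].
#' @return Object of class `dynamic_image` with elements `data`,
#'   `voxel_size`, `schedule`.
#' @export
dynamic_image <- function(data, voxel_size, schedule) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4D array", call. = FALSE)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(data)[4L] != length(schedule))
    stop(sprintf("frame axis (%d) does not match schedule length (%d)",
                 dim(data)[4L], length(schedule)), call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive mm values", call. = FALSE)
  if (!all(is.finite(data)))
    stop("activity values must be finite", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels x %d frames, voxel %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Time-activity curve
#'
#' One voxel or region activity time course sampled at frame mid-times,
#' carrying its frame schedule and nonnegative per-frame fit weights.
#'
#' @param values Numeric activity per frame (kBq/mL).
#' @param schedule A [frame_schedule()] of matching length.
#' @param weights Nonnegative per-frame fit weights; default all 1.
#' @return Object of class `tac`.
#' @export
tac <- function(values, schedule, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != length(schedule))
    stop("values length does not match schedule", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  weights <- as.numeric(weights)
  if (length(weights) != length(values) || any(weights < 0) ||
      all(weights == 0))
    stop("weights must be nonnegative, matching length, not all zero",
         call. = FALSE)
  structure(list(values = values, schedule = schedule, weights = weights),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, range [%.4g, %.4g] kBq/mL\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Parametric map
#'
#' A scalar statistic per voxel inside a mask, stored as a 3D array with NA
#' outside the mask.
#'
#' @param values 3D array of statistic values; NA outside `mask`.
#' @param statistic_name One of `"beta"`, `"gamma"`, `"F"`, `"pOcc"`, `"t"`,
#'   `"R1"`, `"k2"`, `"k2a"`, `"p"`, `"BPND0"`.
#' @param mask Logical or integer 3D array marking the voxels with defined
#'   values.
#' @return Object of class `parametric_map`.
#' @export
parametric_map <- function(values, statistic_name, mask) {
  allowed <- c("beta", "gamma", "F", "pOcc", "t", "R1", "k2", "k2a", "p",
               "BPND0")
  statistic_name <- match.arg(statistic_name, allowed)
  mask <- mask_logical(mask)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask shapes differ", call. = FALSE)
  if (any(!is.finite(values[mask]) & !is.na(values[mask])))
    stop("non-finite statistic inside mask", call. = FALSE)
  values[!mask] <- NA_real_
  structure(list(values = values, statistic_name = statistic_name,
                 mask = mask),
            class = "parametric_map")
}

# coerce an integer/logical mask array to logical, validating labels >= 0
mask_logical <- function(mask, label = NULL) {
  if (is.logical(mask)) return(mask)
  if (any(mask < 0, na.rm = TRUE))
    stop("mask labels must be >= 0", call. = FALSE)
  m <- if (is.null(label)) mask > 0 else mask == label
  dim(m) <- dim(mask)
  m
}

#' Read a 4D dynamic PET image with frame timing
#'
#' Loads a 4D NIfTI volume and attaches a frame schedule read either from a
#' two-column CSV (`start_min,duration_min`) / JSON sidecar path, or given
#' directly as a [frame_schedule()].
#'
#' @param path Path to a 4D NIfTI file (`.nii` / `.nii.gz`).
#' @param timing A [frame_schedule()], or path to a CSV with columns
#'   `start_min` and `duration_min`, or to a JSON file with those fields.
#' @param voxel_size Optional length-3 mm override; defaults to the NIfTI
#'   pixel dimensions.
#' @return A [dynamic_image()]. The input affine is kept as attribute
#'   `affine` for writing outputs.
#' @export
load_dynamic_image <- function(path, timing, voxel_size = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %d dimensions",
                 length(dim(arr))), call. = FALSE)
  schedule <- read_frame_schedule(timing)
  if (dim(arr)[4L] != length(schedule))
    stop(sprintf("image has %d frames but timing has %d entries",
                 dim(arr)[4L], length(schedule)), call. = FALSE)
  if (is.null(voxel_size)) {
    pd <- attr(nii, "pixdim")
    voxel_size <- if (!is.null(pd) && length(pd) >= 3) abs(pd[1:3]) else
      rep(1, 3)
    if (any(voxel_size <= 0)) voxel_size <- rep(1, 3)
  }
  img <- dynamic_image(arr, voxel_size, schedule)
  attr(img, "affine") <- tryCatch(RNifti::xform(nii), error = function(e) NULL)
  img
}

read_frame_schedule <- function(timing) {
  if (inherits(timing, "frame_schedule")) return(timing)
  if (!is.character(timing) || length(timing) != 1L)
    stop("timing must be a frame_schedule or a file path", call. = FALSE)
  if (grepl("\\.json$", timing, ignore.case = TRUE)) {
    tj <- jsonlite::read_json(timing, simplifyVector = TRUE)
    return(frame_schedule(tj$start_min, tj$duration_min))
  }
  tt <- utils::read.csv(timing)
  if (!all(c("start_min", "duration_min") %in% names(tt)))
    stop("timing CSV must have columns start_min and duration_min",
         call. = FALSE)
  frame_schedule(tt$start_min, tt$duration_min)
}

#' Write a dynamic image, mask, or parametric map to NIfTI
#'
#' @param x A [dynamic_image()], [parametric_map()] or 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param timing_path Optional path: when writing a [dynamic_image()], the
#'   frame schedule is written there as CSV (`start_min,duration_min`).
#' @param reference Optional NIfTI template (path or image) supplying the
#'   affine; defaults to the `affine` attribute of `x` when present.
#' @return `path`, invisibly.
#' @export
save_nifti <- function(x, path, timing_path = NULL, reference = NULL) {
  if (inherits(x, "dynamic_image")) {
    arr <- x$data
    vox <- x$voxel_size
    if (!is.null(timing_path))
      utils::write.csv(
        data.frame(start_min = x$schedule$start,
                   duration_min = x$schedule$duration),
        timing_path, row.names = FALSE)
  } else if (inherits(x, "parametric_map")) {
    arr <- x$values
    vox <- attr(x, "voxel_size")
    if (is.null(vox)) vox <- rep(1, 3)
  } else {
    arr <- x
    vox <- rep(1, 3)
  }
  nii <- RNifti::asNifti(arr)
  ref <- if (!is.null(reference)) reference else attr(x, "affine")
  if (!is.null(ref)) nii <- RNifti::asNifti(arr, reference = ref)
  RNifti::pixdim(nii) <- c(vox, if (length(dim(arr)) == 4L) 1 else NULL)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Extract per-voxel TACs for one mask label
#'
#' @param image A [dynamic_image()].
#' @param mask Integer or logical 3D array aligned with `image`.
#' @param label Integer label to extract (ignored for logical masks).
#' @return A list with `index` (n x 3 matrix of 1-based voxel indices in
#'   lexicographic order, x fastest) and `tacs` (n x n_frames matrix); plus
#'   `schedule`.
#' @export
extract_tacs <- function(image, mask, label = 1L) {
  stopifnot(inherits(image, "dynamic_image"))
  m <- mask_logical(mask, if (is.logical(mask)) NULL else label)
  if (!identical(dim(m), dim(image$data)[1:3]))
    stop("mask not aligned with image grid", call. = FALSE)
  idx <- which(m)
  if (length(idx) == 0L)
    stop("no voxels carry the requested label", call. = FALSE)
  nvox <- prod(dim(m))
  nfr <- dim(image$data)[4L]
  flat <- matrix(image$data, nrow = nvox, ncol = nfr)
  list(index = arrayInd(idx, dim(m)),
       tacs = flat[idx, , drop = FALSE],
       schedule = image$schedule)
}

#' Mean TAC over a reference-region mask
#'
#' Frame-wise mean of all voxels in the mask, typically the cerebellar
#' reference region.
#'
#' @inheritParams extract_tacs
#' @param weights Optional fit weights passed to the returned [tac()].
#' @return A [tac()].
#' @export
reference_tac <- function(image, mask, label = 1L, weights = NULL) {
  ex <- extract_tacs(image, mask, label)
  tac(colMeans(ex$tacs), image$schedule, weights)
}

#' Cumulative time integral of a TAC
#'
#' Integrates a frame-sampled series from time zero to each frame mid-time
#' using the trapezoidal rule on mid-times, with a leading triangle from
#' (0, 0) to the first mid-time (activity is zero at injection). Exact for
#' piecewise-linear input.
#'
#' @param x A [tac()], or a numeric vector with `schedule` supplied.
#' @param schedule A [frame_schedule()] when `x` is a plain vector.
#' @return Numeric vector, the integral (kBq min/mL) at each frame mid-time.
#' @export
cumulative_integral <- function(x, schedule = NULL) {
  if (inherits(x, "tac")) {
    schedule <- x$schedule
    x <- x$values
  }
  stopifnot(inherits(schedule, "frame_schedule"))
  cumint_vec(x, schedule$mid)
}

# trapezoid cumulative integral at sample times t, leading triangle from 0
cumint_vec <- function(v, t) {
  n <- length(v)
  dt <- diff(c(0, t))
  seg <- dt * (c(0, v[-n]) + v) / 2
  cumsum(seg)
}

# row-wise version for an n_voxels x n_frames matrix; the cumulative sum
# along rows is a matmul with an upper-triangular ones matrix
cumint_mat <- function(M, t) {
  nfr <- ncol(M)
  dt <- diff(c(0, t))
  prev <- cbind(0, M[, -nfr, drop = FALSE])
  seg <- sweep((prev + M) / 2, 2L, dt, "*")
  U <- matrix(0, nfr, nfr)
  U[upper.tri(U, diag = TRUE)] <- 1
  seg %*% U
}

#' Per-frame weights for weighted least squares
#'
#' @param schedule A [frame_schedule()].
#' @param mode `"uniform"` (all 1) or `"duration"` (proportional to frame
#'   duration, normalized to mean 1 so that the weights sum to the frame
#'   count).
#' @return Numeric weight vector.
#' @export
frame_weights <- function(schedule, mode = c("uniform", "duration")) {
  stopifnot(inherits(schedule, "frame_schedule"))
  mode <- match.arg(mode)
  n <- length(schedule)
  if (mode == "uniform") return(rep(1, n))
  w <- schedule$duration / mean(schedule$duration)
  w
}
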