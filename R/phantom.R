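#' Digital phantom specification for dual-phase parathyroid imaging
#'
#' Describes a simple neck phantom: two ellipsoidal thyroid lobes, one
#' ellipsoidal parathyroid adenoma, and a uniform cervical background, each
#' with its own early-phase uptake concentration and effective washout
#' half-life. Volumes generated from the spec stand in for reconstructed
#' SPECT count volumes; planar images are obtained by ray summation along the
#' anterior-posterior axis.
#'
#' Axis convention: `x` runs right-to-left, `y` anterior-to-posterior, `z`
#' inferior-to-superior. World coordinates are in mm at voxel centres, with
#' the origin at the grid centre.
#'
#' @param grid_shape integer vector of 3, voxels per axis (x, y, z).
#' @param voxel_spacing numeric vector of 3, mm per voxel along each axis.
#' @param adenoma_center mm coordinates of the adenoma ellipsoid centre.
#' @param adenoma_radii mm semi-axes of the adenoma ellipsoid.
#' @param thyroid_lobes list of two lobe descriptors, each a list with
#'   `center` (mm), `radii` (mm semi-axes) and `side` ("left"/"right").
#' @param uptake_early named numeric: early-phase activity concentration
#'   (expected counts per voxel before `count_scale`) for `adenoma`,
#'   `thyroid` and `background`. Must satisfy adenoma > thyroid > background
#'   (the detectable-lesion convention).
#' @param half_life named numeric, effective washout half-life in minutes per
#'   compartment; `Inf` means no washout. Defaults are configuration
#'   placeholders, not claimed 99mTc-MIBI kinetics.
#' @param time_early,time_delayed acquisition times in minutes post-injection.
#' @param psf_sigma mm, isotropic Gaussian point-spread sigma applied by
#'   [apply_noise()].
#' @param count_scale multiplier on expected counts before the Poisson draw;
#'   larger values emulate higher injected dose / longer acquisition.
#' @param seed default RNG seed used by [apply_noise()] when none is given.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(2, 2, 2),
                         adenoma_center = c(18, 4, -22),
                         adenoma_radii = c(7, 6, 8),
                         thyroid_lobes = list(
                           list(center = c(-15, 0, 0), radii = c(8, 8, 20), side = "left"),
                           list(center = c(15, 0, 0), radii = c(8, 8, 20), side = "right")
                         ),
                         uptake_early = c(adenoma = 12, thyroid = 6, background = 1),
                         half_life = c(adenoma = 360, thyroid = 120, background = 180),
                         time_early = 10, time_delayed = 90,
                         psf_sigma = 1, count_scale = 1, seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_spacing = as.numeric(voxel_spacing),
    adenoma_center = as.numeric(adenoma_center), adenoma_radii = as.numeric(adenoma_radii),
    thyroid_lobes = thyroid_lobes, uptake_early = uptake_early,
    half_life = half_life, time_early = time_early, time_delayed = time_delayed,
    psf_sigma = psf_sigma, count_scale = count_scale, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 4L),
            length(spec$voxel_spacing) == 3L, all(spec$voxel_spacing > 0))
  if (any(spec$adenoma_radii <= 0)) stop("adenoma radii must be positive")
  for (lobe in spec$thyroid_lobes) {
    if (any(lobe$radii <= 0)) stop("thyroid lobe radii must be positive")
  }
  u <- spec$uptake_early
  if (any(u < 0)) stop("uptake concentrations must be non-negative")
  if (!(u[["adenoma"]] > u[["thyroid"]] && u[["thyroid"]] > u[["background"]])) {
    stop("require adenoma > thyroid > background early uptake (detectable-lesion convention)")
  }
  if (spec$psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (any(spec$half_life <= 0)) stop("half-lives must be positive (use Inf for no washout)")
  invisible(spec)
}

#' World-coordinate grids for a phantom spec
#'
#' Voxel-centre world coordinates (mm) along one axis.
#' @param spec a `phantom_spec`.
#' @param axis 1, 2 or 3.
#' @keywords internal
axis_coords <- function(spec, axis) {
  n <- spec$grid_shape[axis]
  sp <- spec$voxel_spacing[axis]
  (seq_len(n) - (n + 1) / 2) * sp
}

# Logical 3-D mask of an ellipsoid given centre/radii in mm.
ellipsoid_mask <- function(spec, center, radii) {
  cx <- axis_coords(spec, 1); cy <- axis_coords(spec, 2); cz <- axis_coords(spec, 3)
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  out <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  out <= 1
}

decay_factor <- function(half_life, dt) ifelse(is.finite(half_life), 2^(-dt / half_life), 1)

#' Build a noise-free activity volume from a phantom spec
#'
#' Voxels inside the adenoma ellipsoid carry the adenoma concentration
#' (adenoma takes precedence over thyroid where they abut), thyroid-lobe
#' voxels the thyroid concentration, all others the background. For
#' `time_point = "delayed"` each compartment is decayed mono-exponentially by
#' its effective half-life over the early-to-delayed interval. Deterministic:
#' no blur or noise is applied here (see [apply_noise()]).
#'
#' @param spec a [phantom_spec()].
#' @param time_point `"early"` or `"delayed"`.
#' @return an `activity_volume`: list with `counts` (3-D array of expected
#'   counts/voxel), `voxel_spacing`, `time_point` and `truth` (the spec).
#' @export
build_activity_volume <- function(spec, time_point = c("early", "delayed")) {
  time_point <- match.arg(time_point)
  validate_phantom_spec(spec)
  for (axis in 1:3) {
    co <- axis_coords(spec, axis)
    half <- spec$voxel_spacing[axis] / 2
    lo <- spec$adenoma_center[axis] - spec$adenoma_radii[axis]
    hi <- spec$adenoma_center[axis] + spec$adenoma_radii[axis]
    if (lo < min(co) - half || hi > max(co) + half) {
      stop(sprintf("adenoma ellipsoid extends outside the grid along axis %d (%s)",
                   axis, c("x", "y", "z")[axis]))
    }
  }
  dt <- if (time_point == "delayed") spec$time_delayed - spec$time_early else 0
  u <- spec$uptake_early * decay_factor(spec$half_life[names(spec$uptake_early)], dt)
  counts <- array(u[["background"]], dim = spec$grid_shape)
  for (lobe in spec$thyroid_lobes) {
    counts[ellipsoid_mask(spec, lobe$center, lobe$radii)] <- u[["thyroid"]]
  }
  counts[ellipsoid_mask(spec, spec$adenoma_center, spec$adenoma_radii)] <- u[["adenoma"]]
  activity_volume(counts, spec$voxel_spacing, time_point, truth = spec)
}

#' Construct an activity volume container
#'
#' @param counts 3-D non-negative array of counts (or expected counts).
#' @param voxel_spacing mm per axis.
#' @param time_point `"early"` or `"delayed"`.
#' @param truth optional `phantom_spec` ground truth.
#' @export
activity_volume <- function(counts, voxel_spacing, time_point = "early", truth = NULL) {
  stopifnot(length(dim(counts)) == 3L, all(voxel_spacing > 0))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, voxel_spacing = as.numeric(voxel_spacing),
                 time_point = time_point, truth = truth),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("activity_volume [%s]: %s voxels @ %s mm, total counts %.4g\n",
              x$time_point, paste(dim(x$counts), collapse = "x"),
              paste(x$voxel_spacing, collapse = "x"), sum(x$counts)))
  invisible(x)
}

#' True ellipsoid volume of the phantom adenoma
#'
#' (4/3) * pi * a * b * c, in cm^3.
#' @param spec a `phantom_spec`.
#' @export
true_adenoma_volume <- function(spec) {
  4 / 3 * pi * prod(spec$adenoma_radii) / 1000
}

# Separable Gaussian blur of a 3-D array, sigma in mm per axis.
# Implemented as a banded-matrix product along each axis; truncated kernels
# are renormalised at the edges so a uniform field stays uniform.
blur_volume <- function(arr, sigma_mm, spacing) {
  sigma_mm <- rep_len(sigma_mm, 3L)
  for (axis in 1:3) {
    s_vox <- sigma_mm[axis] / spacing[axis]
    if (s_vox <= 0) next
    n <- dim(arr)[axis]
    half <- max(1L, ceiling(4 * s_vox))
    k <- stats::dnorm(seq(-half, half), sd = s_vox)
    M <- matrix(0, n, n)
    for (off in seq(-half, half)) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      M[cbind(idx[ok], j[ok])] <- k[off + half + 1]
    }
    M <- M / rowSums(M)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- M %*% matrix(a, nrow = d[1])
    dim(a) <- d
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Apply PSF blur and Poisson counting noise to an activity volume
#'
#' Blurs the expected-count volume with an isotropic Gaussian point-spread
#' function, scales by `count_scale`, then draws independent Poisson counts
#' per voxel. Bit-reproducible for a fixed seed.
#'
#' @param volume an `activity_volume` of expected counts.
#' @param seed integer RNG seed; defaults to the truth spec's seed.
#' @param psf_sigma mm; defaults to the truth spec's `psf_sigma` (0 if no truth).
#' @param count_scale multiplier on expected counts; defaults from the truth spec.
#' @return an `activity_volume` of integer counts at `count_scale` times the
#'   input intensity scale.
#' @export
apply_noise <- function(volume, seed = NULL, psf_sigma = NULL, count_scale = NULL) {
  stopifnot(inherits(volume, "activity_volume"))
  if (is.null(psf_sigma)) psf_sigma <- if (!is.null(volume$truth)) volume$truth$psf_sigma else 0
  if (is.null(count_scale)) count_scale <- if (!is.null(volume$truth)) volume$truth$count_scale else 1
  if (is.null(seed)) seed <- if (!is.null(volume$truth)) volume$truth$seed else 1L
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (count_scale <= 0) stop("count_scale must be positive")
  lambda <- blur_volume(volume$counts, psf_sigma, volume$voxel_spacing) * count_scale
  counts <- withr::with_seed(as.integer(seed), {
    array(stats::rpois(length(lambda), lambda), dim = dim(lambda))
  })
  activity_volume(counts, volume$voxel_spacing, volume$time_point, truth = volume$truth)
}

#' Blur an activity volume without adding noise
#'
#' Convenience wrapper used for noise-free partial-volume studies.
#' @inheritParams apply_noise
#' @export
apply_blur <- function(volume, psf_sigma = NULL) {
  stopifnot(inherits(volume, "activity_volume"))
  if (is.null(psf_sigma)) psf_sigma <- if (!is.null(volume$truth)) volume$truth$psf_sigma else 0
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  activity_volume(blur_volume(volume$counts, psf_sigma, volume$voxel_spacing),
                  volume$voxel_spacing, volume$time_point, truth = volume$truth)
}

#' Project a volume to an anterior planar image
#'
#' Sums counts along the anterior-posterior (y) axis, the planar-acquisition
#' stand-in. The result is a matrix with rows running inferior-to-superior
#' (z) and columns right-to-left (x), so the body midline is a column.
#'
#' @param volume an `activity_volume`.
#' @return a `planar_image`: list with `counts` (nz x nx matrix),
#'   `pixel_spacing` (mm, square pixels) and `time_point`.
#' @export
project_planar <- function(volume) {
  stopifnot(inherits(volume, "activity_volume"))
  sp <- volume$voxel_spacing
  if (abs(sp[1] - sp[3]) > 1e-9) {
    stop("in-plane spacing is anisotropic (x vs z); planar quantification assumes square pixels")
  }
  plane <- apply(volume$counts, c(1, 3), sum) # nx x nz
  planar_image(t(plane), pixel_spacing = sp[1], time_point = volume$time_point)
}

#' Construct a planar image container
#'
#' @param counts 2-D non-negative matrix, rows inferior-to-superior, columns
#'   right-to-left.
#' @param pixel_spacing mm per pixel (square).
#' @param time_point `"early"` (~10 min) or `"delayed"` (~90 min post-injection).
#' @export
planar_image <- function(counts, pixel_spacing, time_point = "early") {
  stopifnot(is.matrix(counts), pixel_spacing > 0)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, pixel_spacing = as.numeric(pixel_spacing),
                 time_point = time_point),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image [%s]: %dx%d px @ %g mm, total counts %.4g\n",
              x$time_point, nrow(x$counts), ncol(x$counts), x$pixel_spacing,
              sum(x$counts)))
  invisible(x)
}

#' Simulate the dual-phase planar study for a phantom
#'
#' Builds early and delayed volumes, optionally applies PSF blur and Poisson
#' noise, and projects both to planar images.
#'
#' @param spec a [phantom_spec()].
#' @param noise if `TRUE`, run [apply_noise()] (with distinct sub-seeds per
#'   time point derived from `seed`); otherwise project the noise-free
#'   blurred or unblurred volumes.
#' @param blur apply PSF blur when `noise = FALSE`.
#' @param seed base RNG seed for the noisy path.
#' @return list with elements `early` and `delayed` (`planar_image`s) and
#'   `volumes` (the two `activity_volume`s used).
#' @export
simulate_dual_phase <- function(spec, noise = TRUE, blur = TRUE, seed = spec$seed) {
  vols <- list(early = build_activity_volume(spec, "early"),
               delayed = build_activity_volume(spec, "delayed"))
  if (noise) {
    vols <- list(early = apply_noise(vols$early, seed = seed),
                 delayed = apply_noise(vols$delayed, seed = seed + 1L))
  } else if (blur && spec$psf_sigma > 0) {
    vols <- lapply(vols, apply_blur)
  }
  list(early = project_planar(vols$early),
       delayed = project_planar(vols$delayed),
       volumes = vols)
}
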