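#' @name spect_volumetrics
#' @title Percent-of-maximum isocontour adenoma volumetry
#' @description
#' Measures the scintigraphic adenoma volume (Svol) from a SPECT count
#' volume: a local peak is located within a search sphere around an
#' operator seed, the connected set of voxels at or above a percentage of
#' that peak (default 40%) is segmented with 26-connectivity, and the voxel
#' count is converted to cm^3. The percent-of-maximum reference is the
#' local peak, not the global image maximum, since thyroid uptake can
#' exceed adenoma uptake.
NULL

world_to_voxel <- function(volume, xyz_mm) {
  n <- dim(volume$counts)
  sp <- volume$voxel_spacing
  round(xyz_mm / sp + (n + 1) / 2)
}

#' Locate the local count maximum near a seed
#'
#' Searches the sphere of `search_radius_mm` (world mm) around `seed_mm`
#' for the maximum-count voxel. Ties are broken by smallest distance to
#' the seed, then by lexicographic voxel index, so the result is
#' deterministic (a uniform neighbourhood returns the seed voxel).
#'
#' @param volume an `activity_volume`.
#' @param seed_mm numeric length-3, seed point in world mm.
#' @param search_radius_mm search sphere radius in mm.
#' @return list with `loc` (voxel index i,j,k) and `value` (counts).
#' @export
locate_peak <- function(volume, seed_mm, search_radius_mm = 15) {
  stopifnot(inherits(volume, "activity_volume"), length(seed_mm) == 3)
  n <- dim(volume$counts)
  sp <- volume$voxel_spacing
  seed_vox <- world_to_voxel(volume, seed_mm)
  r_vox <- ceiling(search_radius_mm / sp)
  rng <- lapply(1:3, function(a) {
    seq(max(1L, seed_vox[a] - r_vox[a]), min(n[a], seed_vox[a] + r_vox[a]))
  })
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  world <- sweep(sweep(g, 2, (n + 1) / 2), 2, sp, `*`)
  d2 <- rowSums(sweep(world, 2, seed_mm)^2)
  g <- g[d2 <= search_radius_mm^2, , drop = FALSE]
  d2 <- d2[d2 <= search_radius_mm^2]
  if (nrow(g) == 0L) stop("search sphere lies entirely outside the volume grid")
  vals <- volume$counts[g]
  ord <- order(-vals, d2, g[, 1], g[, 2], g[, 3])
  best <- g[ord[1], ]
  list(loc = unname(best), value = unname(vals[ord[1]]))
}

# 26-neighbourhood offsets (3x3x3 cube minus centre).
neighbour_offsets_26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Segment the percent-of-maximum isocontour VOI
#'
#' Returns the 26-connected component, containing the peak voxel, of voxels
#' with counts at or above `threshold_pct`% of the peak value. The flood
#' fill is frontier-based and exact; no shape prior is applied unless an
#' optional ellipsoid clip mask is supplied.
#'
#' @param volume an `activity_volume`.
#' @param peak result of [locate_peak()] (or a list with `loc`, `value`).
#' @param threshold_pct percent of the peak value in (0, 100].
#' @param clip_ellipsoid optional list(center, radii) in world mm; voxels
#'   outside it are excluded before the flood fill (vendor bounding-shape
#'   emulation; off by default).
#' @return an object of class `voi`: `voxels` (n x 3 index matrix),
#'   `threshold_pct`, `peak_value`, `peak_loc`, and `touches_boundary`
#'   (flag set when the component reaches the grid edge).
#' @export
segment_isocontour <- function(volume, peak, threshold_pct = 40, clip_ellipsoid = NULL) {
  stopifnot(inherits(volume, "activity_volume"))
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]")
  }
  if (peak$value <= 0) stop("peak value must be positive")
  n <- dim(volume$counts)
  thr <- threshold_pct / 100 * peak$value
  mask <- volume$counts >= thr
  if (!is.null(clip_ellipsoid)) {
    sp <- volume$voxel_spacing
    co <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * sp[a])
    d <- outer(outer(((co[[1]] - clip_ellipsoid$center[1]) / clip_ellipsoid$radii[1])^2,
                     ((co[[2]] - clip_ellipsoid$center[2]) / clip_ellipsoid$radii[2])^2, `+`),
               ((co[[3]] - clip_ellipsoid$center[3]) / clip_ellipsoid$radii[3])^2, `+`)
    mask <- mask & (d <= 1)
  }
  p <- matrix(as.integer(peak$loc), ncol = 3)
  if (!mask[p]) stop("peak voxel is below the threshold (inconsistent peak)")
  visited <- array(FALSE, dim = n)
  visited[p] <- TRUE
  frontier <- p
  members <- list(p)
  while (nrow(frontier) > 0L) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(neighbour_offsets_26)), , drop = FALSE] +
      neighbour_offsets_26[rep(seq_len(nrow(neighbour_offsets_26)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= n[1] &
      cand[, 2] >= 1 & cand[, 2] <= n[2] &
      cand[, 3] >= 1 & cand[, 3] <= n[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    cand <- unique(cand)
    keep <- mask[cand] & !visited[cand]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L) visited[cand] <- TRUE
    members[[length(members) + 1L]] <- cand
    frontier <- cand
  }
  vox <- do.call(rbind, members)
  colnames(vox) <- c("i", "j", "k")
  touches <- any(vox == 1L) || any(sweep(vox, 2, n) == 0L)
  out <- list(voxels = vox, threshold_pct = threshold_pct,
              peak_value = peak$value, peak_loc = peak$loc,
              touches_boundary = touches)
  class(out) <- "voi"
  if (touches) {
    warning("isocontour component touches the grid boundary; Svol may be truncated")
  }
  out
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("voi: %d voxels at >= %g%% of peak %.4g%s\n",
              nrow(x$voxels), x$threshold_pct, x$peak_value,
              if (x$touches_boundary) " [touches boundary]" else ""))
  invisible(x)
}

#' Scintigraphic volume of a VOI
#'
#' Voxel count times voxel volume, in cm^3.
#' @param voi a [segment_isocontour()] result.
#' @param voxel_spacing mm per axis.
#' @export
compute_svol <- function(voi, voxel_spacing) {
  stopifnot(inherits(voi, "voi"))
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  nrow(voi$voxels) * prod(voxel_spacing) / 1000
}

#' Parathormone-to-volume composite
#'
#' `PTH / Svol` in ng/L per cm^3, a proxy for secretory activity per unit
#' of metabolically active adenoma volume.
#' @param pth serum parathormone, ng/L (>= 0).
#' @param svol scintigraphic volume, cm^3 (> 0).
#' @export
compute_pth_svol <- function(pth, svol) {
  if (any(svol <= 0)) stop("svol must be positive")
  if (any(pth < 0)) stop("pth must be non-negative")
  pth / svol
}

#' Seed-to-Svol convenience pipeline
#'
#' Locates the local peak, segments the isocontour VOI and reports Svol
#' (and PTH/Svol when PTH is supplied).
#'
#' @inheritParams locate_peak
#' @inheritParams segment_isocontour
#' @param pth optional serum PTH (ng/L) for the composite.
#' @return list of class `volumetrics_result`: `svol`, `pth_svol` (or
#'   `NULL`), `voi`, `peak`.
#' @export
measure_adenoma_volume <- function(volume, seed_mm, search_radius_mm = 15,
                                   threshold_pct = 40, pth = NULL,
                                   clip_ellipsoid = NULL) {
  peak <- locate_peak(volume, seed_mm, search_radius_mm)
  v <- segment_isocontour(volume, peak, threshold_pct, clip_ellipsoid)
  svol <- compute_svol(v, volume$voxel_spacing)
  out <- list(svol = svol,
              pth_svol = if (!is.null(pth)) compute_pth_svol(pth, svol) else NULL,
              voi = v, peak = peak)
  class(out) <- "volumetrics_result"
  out
}

#' @export
print.volumetrics_result <- function(x, ...) {
  cat(sprintf("volumetrics_result: Svol %.3f cm^3 (%d voxels at %g%%)%s\n",
              x$svol, nrow(x$voi$voxels), x$voi$threshold_pct,
              if (!is.null(x$pth_svol)) sprintf(", PTH/Svol %.2f", x$pth_svol) else ""))
  invisible(x)
}
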