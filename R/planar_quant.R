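#' @name planar_quant
#' @title Dual-phase planar uptake quantification
#' @description
#' Computes the planar dual-phase scintigraphy parameters from a lesion ROI
#' drawn over the parathyroid adenoma: early and delayed lesion/background
#' ratios (eLBR, dLBR), early and delayed lesion/thyroid ratios (eLTR,
#' dLTR), and the retention index RI = (eLTR - dLTR) / eLTR. Reference ROIs
#' of identical size and shape are obtained by mirroring the lesion ROI
#' across the body midline into the contralateral thyroid area and (with a
#' caudal offset) the contralateral background cervical region.
NULL

#' Construct a planar region of interest
#'
#' @param pixels two-column integer matrix of (row, col) pixel indices.
#' @param label one of `"lesion"`, `"thyroid_ref"`, `"background_ref"`.
#' @param source `"manual"` or `"mirrored"`.
#' @return an object of class `roi`.
#' @export
roi <- function(pixels, label = c("lesion", "thyroid_ref", "background_ref"),
                source = c("manual", "mirrored")) {
  label <- match.arg(label)
  source <- match.arg(source)
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("ROI mask is empty")
  pixels <- unique(pixels)
  structure(list(pixels = pixels, label = label, source = source), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi [%s, %s]: %d px\n", x$label, x$source, nrow(x$pixels)))
  invisible(x)
}

#' Elliptical ROI helper
#'
#' Pixels whose centres fall inside an axis-aligned ellipse; the usual way
#' an operator outlines the focal adenoma uptake.
#' @param center_rc (row, col) centre in pixel units.
#' @param radii_px (row, col) semi-axes in pixels.
#' @inheritParams roi
#' @export
roi_ellipse <- function(center_rc, radii_px, label = "lesion", source = "manual") {
  rr <- seq(floor(center_rc[1] - radii_px[1]), ceiling(center_rc[1] + radii_px[1]))
  cc <- seq(floor(center_rc[2] - radii_px[2]), ceiling(center_rc[2] + radii_px[2]))
  g <- expand.grid(row = rr, col = cc)
  inside <- ((g$row - center_rc[1]) / radii_px[1])^2 +
    ((g$col - center_rc[2]) / radii_px[2])^2 <= 1
  roi(as.matrix(g[inside, ]), label = label, source = source)
}

check_roi_on_image <- function(r, image) {
  stopifnot(inherits(r, "roi"), inherits(image, "planar_image"))
  px <- r$pixels
  if (nrow(px) == 0L) stop("ROI mask is empty")
  if (any(px[, 1] < 1L | px[, 1] > nrow(image$counts) |
          px[, 2] < 1L | px[, 2] > ncol(image$counts))) {
    stop("ROI extends outside the image bounds")
  }
  invisible(TRUE)
}

#' Mean counts per pixel over an ROI
#'
#' @param image a `planar_image`.
#' @param r an [roi()].
#' @return arithmetic mean of the counts over the mask pixels.
#' @export
roi_mean <- function(image, r) {
  check_roi_on_image(r, image)
  mean(image$counts[r$pixels])
}

#' Mirror an ROI across the body midline
#'
#' Reflects each mask pixel's column across a vertical midline column,
#' preserving pixel count and shape (congruent reflection). An optional row
#' offset translates the mirrored ROI caudally (negative rows point
#' inferior), used to place the background reference below the
#' contralateral thyroid.
#'
#' @param r lesion [roi()].
#' @param image the `planar_image` the ROI lives on (for bounds checking).
#' @param midline_col midline column index (may be half-integer).
#' @param offset_rows integer row translation applied after reflection.
#' @param label label for the mirrored ROI.
#' @return an [roi()] with `source = "mirrored"`.
#' @export
mirror_roi <- function(r, image, midline_col, offset_rows = 0L,
                       label = c("thyroid_ref", "background_ref")) {
  label <- match.arg(label)
  stopifnot(inherits(r, "roi"))
  px <- r$pixels
  out <- cbind(row = px[, 1] + as.integer(offset_rows),
               col = as.integer(round(2 * midline_col - px[, 2])))
  m <- roi(out, label = label, source = "mirrored")
  ok <- tryCatch({
    check_roi_on_image(m, image)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("mirrored ROI exits the image bounds; supply an offset_rows translation ",
         "(or adjust midline_col) to keep the reference ROI inside the field of view")
  }
  m
}

#' Lesion-to-background uptake ratio
#'
#' Ratio of the mean counts of the adenoma ROI to the contralateral
#' background cervical ROI.
#' @param lesion_mean,background_mean mean counts per pixel.
#' @export
compute_lbr <- function(lesion_mean, background_mean) {
  if (any(background_mean <= 0)) {
    stop("background ROI mean is not positive; the reference ROI is misplaced")
  }
  lesion_mean / background_mean
}

#' Lesion-to-thyroid uptake ratio
#'
#' Ratio of the mean counts of the adenoma ROI to the contralateral thyroid
#' ROI.
#' @param lesion_mean,thyroid_mean mean counts per pixel.
#' @export
compute_ltr <- function(lesion_mean, thyroid_mean) {
  if (any(thyroid_mean <= 0)) {
    stop("thyroid ROI mean is not positive; the reference ROI is misplaced")
  }
  lesion_mean / thyroid_mean
}

#' Retention index
#'
#' `RI = (eLTR - dLTR) / eLTR`, the fractional change of the
#' lesion-to-thyroid ratio between the early and delayed acquisitions.
#' Positive RI means relative tracer retention in the adenoma; RI can be
#' negative when the adenoma accumulates relative to thyroid on the delayed
#' image.
#' @param eltr,dltr early and delayed lesion-to-thyroid ratios.
#' @export
compute_ri <- function(eltr, dltr) {
  if (any(eltr <= 0)) stop("eLTR must be positive")
  (eltr - dltr) / eltr
}

#' Quantify a patient's dual-phase planar study
#'
#' Mirrors the lesion ROI across the midline to obtain the contralateral
#' thyroid reference, mirrors it again with a caudal row offset (default:
#' one ROI height, placing it below the contralateral lobe) for the
#' background reference, and applies the identical mask geometry to both
#' time points.
#'
#' @param early,delayed congruent `planar_image`s (same shape and pixel
#'   spacing).
#' @param lesion_roi lesion [roi()] drawn on the early image.
#' @param midline_col body midline column; default is the image centre.
#' @param background_offset_rows caudal translation (in rows) of the
#'   background reference; default `-(ROI height)`.
#' @return a `planar_params` list: `elbr`, `dlbr`, `eltr`, `dltr`, `ri`,
#'   plus the three ROIs used.
#' @export
quantify_patient_planar <- function(early, delayed, lesion_roi,
                                    midline_col = (ncol(early$counts) + 1) / 2,
                                    background_offset_rows = NULL) {
  stopifnot(inherits(early, "planar_image"), inherits(delayed, "planar_image"))
  if (!all(dim(early$counts) == dim(delayed$counts)) ||
      abs(early$pixel_spacing - delayed$pixel_spacing) > 1e-9) {
    stop("early and delayed images must share shape and pixel spacing")
  }
  check_roi_on_image(lesion_roi, early)
  if (is.null(background_offset_rows)) {
    background_offset_rows <- -(diff(range(lesion_roi$pixels[, 1])) + 1L)
  }
  thyroid_ref <- mirror_roi(lesion_roi, early, midline_col, label = "thyroid_ref")
  background_ref <- mirror_roi(lesion_roi, early, midline_col,
                               offset_rows = background_offset_rows,
                               label = "background_ref")
  p <- function(img) {
    les <- roi_mean(img, lesion_roi)
    thy <- roi_mean(img, thyroid_ref)
    bkg <- roi_mean(img, background_ref)
    c(lbr = compute_lbr(les, bkg), ltr = compute_ltr(les, thy))
  }
  e <- p(early); d <- p(delayed)
  out <- list(elbr = unname(e["lbr"]), dlbr = unname(d["lbr"]),
              eltr = unname(e["ltr"]), dltr = unname(d["ltr"]),
              ri = compute_ri(e[["ltr"]], d[["ltr"]]),
              lesion_roi = lesion_roi, thyroid_ref = thyroid_ref,
              background_ref = background_ref)
  class(out) <- "planar_params"
  out
}

#' @export
print.planar_params <- function(x, ...) {
  cat(sprintf("planar_params: eLBR %.3f  dLBR %.3f  eLTR %.3f  dLTR %.3f  RI %.3f\n",
              x$elbr, x$dlbr, x$eltr, x$dltr, x$ri))
  invisible(x)
}
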