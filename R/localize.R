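# Wax-block localization: find the wax insert by morphological processing
# keyed to its known physical size, estimate its rotation, and partition it
# into the 18 per-object ROIs in the de-rotated block frame.

#' Localization failure condition
#'
#' Raised when no candidate region matching the expected wax-block size can
#' be found -- notably when a large chest-wall overhang truncates the block.
#' It is a classed condition (`mammoqc_localization_failure`) so callers
#' (and the CLI) can catch it and report a clean "Fail".
#'
#' @param message description of the failure.
#' @return does not return; signals the condition.
#' @export
localization_failure <- function(message) {
  stop(structure(
    class = c("mammoqc_localization_failure", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# Otsu threshold of a value vector (histogram-based, via EBImage); large
# inputs are strided down, which leaves the 256-bin histogram essentially
# unchanged.
otsu_threshold <- function(v) {
  if (length(v) > 1e6) v <- v[seq(1, length(v), by = 7)]
  rng <- range(v) + c(-1e-6, 1e-6) * max(abs(range(v)), 1)
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = rng)
}

#' Locate the wax block in a phantom image
#'
#' Two-stage morphological segmentation using only the known physical size
#' of the insert: (1) Otsu threshold over the whole image and largest
#' connected component -> phantom body; (2) Otsu threshold within the body
#' -> wax-insert candidates; morphological closing and opening with a
#' structuring element scaled to 2 mm; connected-component selection by
#' expected physical area; principal-axis rotation estimate and
#' minimum-area rectangle fit in the de-rotated frame.
#'
#' @param image a `phantom_image`.
#' @param config a `qc_config`; supplies the expected block size and the
#'   localization tolerances.
#' @return a `wax_block_region`: list with `corners_px` (4 x 2 matrix,
#'   (row, col), clockwise from the block's top-left), `centre_px`,
#'   `rotation_deg`, `size_mm` (detected width/height), `fit_residual`
#'   (worst relative mismatch vs the expected size) and `truncated` (block
#'   edge within `border_px` of an image border).
#' @export
segment_wax_block <- function(image, config = default_config()) {
  spec <- config$spec
  s <- mean(image$pixel_spacing_mm)
  px <- image$pixels
  loc <- config$localization

  body_mask <- px > otsu_threshold(px)
  lab <- EBImage::bwlabel(eb_from_matrix(body_mask))
  sizes <- tabulate(EBImage::imageData(lab))
  if (length(sizes) == 0) localization_failure("no phantom body found")
  body_mask <- eb_to_matrix(lab) == which.max(sizes)

  wax_mask <- (px > otsu_threshold(px[body_mask])) & body_mask
  if (!any(wax_mask)) localization_failure("no wax-block candidate pixels")

  # morphology on the candidate bounding box only
  rr <- range(which(rowSums(wax_mask) > 0))
  cc <- range(which(colSums(wax_mask) > 0))
  pad <- odd_px(loc$closing_mm, s) + 1L
  r_off <- max(1L, rr[1] - pad); c_off <- max(1L, cc[1] - pad)
  crop <- wax_mask[r_off:min(nrow(px), rr[2] + pad),
                   c_off:min(ncol(px), cc[2] + pad)]
  brush <- EBImage::makeBrush(odd_px(loc$closing_mm, s), shape = "disc")
  m <- eb_from_matrix(crop)
  m <- EBImage::opening(EBImage::closing(m, brush), brush)
  lab <- EBImage::bwlabel(m)
  comp_sizes <- tabulate(EBImage::imageData(lab))

  expected_area_px <- prod(spec$wax_block_size_mm) / s^2
  ok <- which(abs(comp_sizes - expected_area_px) <=
                loc$area_tol_frac * expected_area_px)
  if (length(ok) == 0)
    localization_failure(sprintf(
      "no region matching the expected %.0f x %.0f mm wax block",
      spec$wax_block_size_mm[1], spec$wax_block_size_mm[2]))
  best <- ok[which.min(abs(comp_sizes[ok] - expected_area_px))]
  mask <- eb_to_matrix(lab) == best

  pts <- which(mask, arr.ind = TRUE)  # (row, col), crop frame
  pts[, 1] <- pts[, 1] + r_off - 1L
  pts[, 2] <- pts[, 2] + c_off - 1L
  phi <- points_orientation(pts)      # long axis, nominally vertical (90)
  rotation <- ((phi - 90 + 90) %% 180) - 90
  if (abs(rotation) > 10)
    localization_failure(sprintf(
      "estimated block rotation %.1f deg outside the supported +/-10 deg",
      rotation))

  th <- rotation * pi / 180
  cx <- mean(pts[, 2]); cy <- mean(pts[, 1])
  xr <- (pts[, 2] - cx) * cos(th) + (pts[, 1] - cy) * sin(th)
  yr <- -(pts[, 2] - cx) * sin(th) + (pts[, 1] - cy) * cos(th)
  half_w <- (max(xr) - min(xr) + 1) / 2
  half_h <- (max(yr) - min(yr) + 1) / 2
  mx <- (max(xr) + min(xr)) / 2
  my <- (max(yr) + min(yr)) / 2
  centre <- c(row = cy + mx * sin(th) + my * cos(th),
              col = cx + mx * cos(th) - my * sin(th))

  size_mm <- c(width = 2 * half_w * s, height = 2 * half_h * s)
  residual <- max(abs(size_mm - spec$wax_block_size_mm) /
                    spec$wax_block_size_mm)
  if (residual > loc$dim_tol_frac)
    localization_failure(sprintf(
      paste0("detected block %.1f x %.1f mm does not match the expected ",
             "%.0f x %.0f mm (residual %.0f%%); wax block truncated or ",
             "not found"),
      size_mm[1], size_mm[2], spec$wax_block_size_mm[1],
      spec$wax_block_size_mm[2], 100 * residual))

  rot <- function(dx, dy)  # de-rotated offsets (px) -> image (row, col)
    c(row = centre[["row"]] + dx * sin(th) + dy * cos(th),
      col = centre[["col"]] + dx * cos(th) - dy * sin(th))
  corners <- rbind(
    rot(-half_w, -half_h), rot(half_w, -half_h),
    rot(half_w, half_h), rot(-half_w, half_h)
  )
  truncated <- any(corners[, 1] <= loc$border_px |
                     corners[, 1] >= nrow(px) - loc$border_px + 1 |
                     corners[, 2] <= loc$border_px |
                     corners[, 2] >= ncol(px) - loc$border_px + 1)

  structure(list(
    corners_px = corners, centre_px = centre, rotation_deg = rotation,
    size_mm = size_mm, fit_residual = residual, truncated = truncated
  ), class = "wax_block_region")
}

#' Extract the 18 per-object ROIs from a localized wax block
#'
#' Resamples each object's grid cell ([object_roi_bounds()]) into the
#' de-rotated wax-block frame by bilinear interpolation, so the ROI content
#' of a shifted / rotated phantom matches the unperturbed one up to
#' interpolation error.
#'
#' @param image a `phantom_image`.
#' @param region a `wax_block_region` from [segment_wax_block()].
#' @param config a `qc_config`.
#' @return a `roi_set`: named list (`"<kind>_<index>"`) of 18 ROIs, each a
#'   list with `pixels`, `kind`, `index`, `bounds`, `smoothed`, `sigma_px`;
#'   the region and pixel spacing ride along as attributes.
#' @export
extract_rois <- function(image, region, config = default_config()) {
  if (region$truncated)
    localization_failure("wax block touches the image border; ROIs would be truncated")
  spec <- config$spec
  s <- mean(image$pixel_spacing_mm)
  th <- region$rotation_deg * pi / 180
  w <- spec$wax_block_size_mm[1]; h <- spec$wax_block_size_mm[2]
  centre <- region$centre_px

  rois <- list()
  for (ob in spec$objects) {
    b <- object_roi_bounds(spec, ob$kind, ob$index, s)
    cols_mm <- b$x0_mm + (seq_len(b$ncol) - 0.5) * s - w / 2
    rows_mm <- b$y0_mm + (seq_len(b$nrow) - 0.5) * s - h / 2
    dx <- rep(cols_mm, each = b$nrow) / s
    dy <- rep(rows_mm, b$ncol) / s
    ix <- centre[["col"]] + dx * cos(th) - dy * sin(th)
    iy <- centre[["row"]] + dx * sin(th) + dy * cos(th)
    v <- bilinear_sample(image$pixels, iy, ix)
    rois[[paste(ob$kind, ob$index, sep = "_")]] <- list(
      pixels = matrix(v, b$nrow, b$ncol),
      kind = ob$kind, index = ob$index, bounds = b,
      smoothed = FALSE, sigma_px = 0
    )
  }
  structure(rois, class = "roi_set",
            region = region, pixel_spacing_mm = s)
}

#' Gaussian-smooth a ROI
#'
#' Denoising applied to the 18 ROIs only (the source image is never
#' altered); `sigma_px = 0` returns the input unchanged.
#'
#' @param roi a ROI entry from [extract_rois()] (or a bare matrix).
#' @param sigma_px Gaussian sigma in pixels, >= 0.
#' @return the smoothed ROI (same type as the input).
#' @export
smooth_roi <- function(roi, sigma_px) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(roi)
  if (is.matrix(roi)) return(eb_to_matrix(EBImage::gblur(eb_from_matrix(roi),
                                                         sigma = sigma_px)))
  roi$pixels <- eb_to_matrix(EBImage::gblur(eb_from_matrix(roi$pixels),
                                            sigma = sigma_px))
  roi$smoothed <- TRUE
  roi$sigma_px <- sigma_px
  roi
}
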