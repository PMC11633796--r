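# Observer-anchored recalibration of the correlation thresholds.

#' Refit correlation thresholds from observer scores
#'
#' Reproduces the observer-anchored calibration loop: for every image in
#' the score table the pipeline is run up to the correlation stage, the
#' per-object correlation peaks are pooled per kind and matched with the
#' observer scores, and the gates are re-set at the midpoints between the
#' mean peak of zero-scored and positively scored objects (`gamma_zero`,
#' `gamma_partial`) and between the mean peaks of the 0.5 and 1 classes
#' (`gamma_full`). Classes absent from the table leave the corresponding
#' threshold unchanged.
#'
#' @param scores data frame with columns `image_path`, `kind`, `index`,
#'   `observer_score` (0, 0.5 or 1).
#' @param config a `qc_config` supplying geometry and the starting
#'   thresholds.
#' @return a `qc_config` with updated `thresholds`.
#' @export
calibrate_thresholds <- function(scores, config = default_config()) {
  stopifnot(all(c("image_path", "kind", "index", "observer_score") %in%
                  names(scores)))
  peaks <- data.frame()
  for (path in unique(scores$image_path)) {
    image <- if (inherits(path, "phantom_image")) path
             else read_phantom_image(path)
    region <- segment_wax_block(image, config)
    rois <- extract_rois(image, region, config)
    spacing <- mean(image$pixel_spacing_mm)
    rows <- scores[scores$image_path == path, ]
    for (j in seq_len(nrow(rows))) {
      roi <- rois[[paste(rows$kind[j], rows$index[j], sep = "_")]]
      sroi <- smooth_roi(roi, config$smoothing$sigma_mm / spacing)
      tm <- make_template(rows$kind[j], rows$index[j], config$spec, spacing)
      cr <- normxcorr2(tm, sroi$pixels)
      peaks <- rbind(peaks, data.frame(
        kind = rows$kind[j], score = rows$observer_score[j],
        gamma = cr$peak_gamma))
    }
  }
  for (kind in unique(peaks$kind)) {
    pk <- peaks[peaks$kind == kind, ]
    th <- config$thresholds[[kind]]
    g0 <- mean(pk$gamma[pk$score == 0])
    gpos <- mean(pk$gamma[pk$score > 0])
    ghalf <- mean(pk$gamma[pk$score == 0.5])
    gfull <- mean(pk$gamma[pk$score == 1])
    if (is.finite(g0) && is.finite(gpos)) {
      th$gamma_zero <- (g0 + gpos) / 2
      if (!is.null(th$gamma_partial)) th$gamma_partial <- th$gamma_zero
      if (!is.null(th$peak_threshold))
        th$peak_threshold <- max(th$gamma_zero, th$peak_threshold)
    }
    if (is.finite(ghalf) && is.finite(gfull) && !is.null(th$gamma_full))
      th$gamma_full <- (ghalf + gfull) / 2
    config$thresholds[[kind]] <- th
  }
  config
}
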