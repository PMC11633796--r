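# Group scoring (count-until-zero rule), pass evaluation, and the full
# analysis pipeline.

#' Apply the count-until-zero rule to one object group
#'
#' Objects are scored from the largest (index 1) down; at the first object
#' whose raw score is 0, scoring of the group stops: that object and all
#' smaller ones contribute 0 (smaller ones are marked `stopped`). A 0.5
#' does not trigger the stop -- only a zero does. The group total is the
#' sum of the six member scores.
#'
#' @param results list of six `object_result`s of one kind, indices 1-6.
#' @return a `group_score`: list with `kind`, `total` and the (possibly
#'   stop-adjusted) per-object `results`.
#' @export
score_group <- function(results) {
  idx <- vapply(results, `[[`, 1L, "index")
  if (!setequal(idx, 1:6))
    stop("score_group needs results for indices 1-6 exactly")
  results <- results[order(idx)]
  kind <- unique(vapply(results, `[[`, "", "kind"))
  if (length(kind) != 1) stop("score_group: mixed object kinds")
  hit_zero <- FALSE
  for (i in 1:6) {
    if (hit_zero) {
      results[[i]]$score <- 0
      results[[i]]$stopped <- TRUE
    } else if (results[[i]]$score == 0) {
      hit_zero <- TRUE
    }
  }
  structure(list(
    kind = kind,
    total = sum(vapply(results, `[[`, 0, "score")),
    results = results
  ), class = "group_score")
}

#' Evaluate group totals against a pass criterion
#'
#' @param totals named list or vector with elements `fiber`, `speck_group`,
#'   `mass` (group totals, 0-6).
#' @param criteria a [pass_criteria()].
#' @return `TRUE` when every group total meets its minimum.
#' @export
evaluate_pass <- function(totals, criteria) {
  totals <- unlist(totals)
  totals[["fiber"]] >= criteria$min_fibers &&
    totals[["speck_group"]] >= criteria$min_specks &&
    totals[["mass"]] >= criteria$min_masses
}

analyze_one <- function(roi, config, spacing) {
  template <- make_template(roi$kind, roi$index, config$spec, spacing)
  sroi <- smooth_roi(roi, config$smoothing$sigma_mm / spacing)
  switch(roi$kind,
    fiber = analyze_fiber(sroi, template, config, spacing),
    speck_group = analyze_speck_group(sroi, template, config, spacing),
    mass = analyze_mass(sroi, template, config, spacing))
}

#' Run the full phantom QC analysis on one image
#'
#' Pipeline: read (if given a path) -> localize the wax block -> extract
#' and smooth the 18 ROIs -> per-object template matching with the
#' correlation gate and supplementary validator (objects below a larger
#' zero-scored object of the same kind are skipped under the stop rule) ->
#' group totals -> RANZCR and ACR pass evaluation. Deterministic for a
#' fixed input and configuration. A localization failure yields a report
#' with `status = "localization_failure"` and no scores rather than an
#' error.
#'
#' @param input a DICOM file path or a `phantom_image`.
#' @param config a `qc_config`.
#' @return a `qc_report`: list with `status` (`"scored"` or
#'   `"localization_failure"`), `group_scores`, `totals`, `pass`
#'   (`RANZCR`, `ACR` flags), `objects` (per-object evidence data frame),
#'   `region`, `config_fingerprint`, `version`.
#' @export
analyze_image <- function(input, config = default_config()) {
  image <- if (is.character(input)) read_phantom_image(input) else input
  stopifnot(inherits(image, "phantom_image"))
  spacing <- mean(image$pixel_spacing_mm)

  region <- tryCatch(segment_wax_block(image, config),
                     mammoqc_localization_failure = function(e) e)
  if (inherits(region, "condition"))
    return(qc_report_failure(conditionMessage(region), config))
  rois <- tryCatch(extract_rois(image, region, config),
                   mammoqc_localization_failure = function(e) e)
  if (inherits(rois, "condition"))
    return(qc_report_failure(conditionMessage(rois), config))

  group_scores <- list()
  for (kind in OBJECT_KINDS) {
    results <- vector("list", 6)
    hit_zero <- FALSE
    for (i in 1:6) {
      if (hit_zero) {
        results[[i]] <- object_result(kind, i, 0, NA_real_,
                                      list(skipped = TRUE), stopped = TRUE)
      } else {
        results[[i]] <- analyze_one(rois[[paste(kind, i, sep = "_")]],
                                    config, spacing)
        if (results[[i]]$score == 0) hit_zero <- TRUE
      }
    }
    group_scores[[kind]] <- score_group(results)
  }

  totals <- lapply(group_scores, `[[`, "total")
  objects <- do.call(rbind, lapply(group_scores, function(g)
    do.call(rbind, lapply(g$results, function(r) data.frame(
      kind = r$kind, index = r$index, score = r$score,
      peak_gamma = r$peak_gamma %||% NA_real_,
      stopped = r$stopped
    )))))
  rownames(objects) <- NULL

  structure(list(
    status = "scored",
    group_scores = group_scores,
    totals = totals,
    pass = list(
      RANZCR = evaluate_pass(totals, pass_criteria("RANZCR")),
      ACR = evaluate_pass(totals, pass_criteria("ACR"))
    ),
    objects = objects,
    region = region[c("centre_px", "rotation_deg", "size_mm",
                      "fit_residual", "truncated")],
    config_fingerprint = config_fingerprint(config),
    version = as.character(utils::packageVersion("mammoqc"))
  ), class = "qc_report")
}

qc_report_failure <- function(message, config) {
  structure(list(
    status = "localization_failure",
    message = message,
    group_scores = NULL, totals = NULL,
    pass = list(RANZCR = FALSE, ACR = FALSE),
    objects = NULL, region = NULL,
    config_fingerprint = config_fingerprint(config),
    version = as.character(utils::packageVersion("mammoqc"))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ACR DM phantom QC report\n")
  if (x$status != "scored") {
    cat("  status: Fail (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  for (kind in names(x$totals))
    cat(sprintf("  %-12s %.1f / 6\n", kind, x$totals[[kind]]))
  cat(sprintf("  RANZCR (fibers >= 4, specks >= 3, masses >= 3): %s\n",
              if (x$pass$RANZCR) "Pass" else "Fail"))
  cat(sprintf("  ACR    (fibers >= 2, specks >= 3, masses >= 2): %s\n",
              if (x$pass$ACR) "Pass" else "Fail"))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
qc_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$group_scores <- NULL  # objects data frame carries the detail
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
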