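#' Default analysis configuration
#'
#' Bundles every tunable of the analyzer: the phantom layout, detection
#' thresholds, smoothing, and localization settings. All downstream code
#' receives one of these, so the analyzer and the simulator always share
#' the same geometry.
#'
#' Correlation thresholds (`gamma_*`) are dimensionless values of the
#' normalized cross-correlation peak: below `gamma_zero` an object scores 0
#' and the supplementary validator is skipped; in `[gamma_partial,
#' gamma_full)` a validated object scores 0.5; at `>= gamma_full` it scores
#' 1. Shipped defaults were calibrated on the synthetic phantom
#' (object-present renders across the contrast ladder vs object-free
#' regions); [calibrate_thresholds()] refits them from observer scores.
#'
#' @param spec phantom layout, default [default_phantom_spec()].
#' @return a `qc_config` list.
#' @export
default_config <- function(spec = default_phantom_spec()) {
  structure(list(
    spec = spec,
    smoothing = list(sigma_mm = 0.1),
    localization = list(
      dim_tol_frac = 0.10,     # detected block width/height vs spec
      area_tol_frac = 0.25,    # candidate component pre-filter
      closing_mm = 2.0,        # structuring element diameter
      border_px = 2L           # truncation flag margin
    ),
    thresholds = list(
      fiber = list(gamma_zero = 0.50, gamma_partial = 0.50, gamma_full = 0.65,
                   binarize_frac = 0.6, angle_tol_deg = 4),
      speck_group = list(gamma_zero = 0.18, peak_threshold = 0.30,
                         min_rel_amplitude = 0.35, spacing_tol_frac = 0.30),
      mass = list(gamma_zero = 0.50, gamma_partial = 0.50, gamma_full = 0.78,
                  fwhm_band = c(0.5, 1.8),  # x mass_diameter_mm
                  centroid_tol_px_50um = 5) # scaled by 0.05/spacing
    ),
    chest_wall_default = "left"
  ), class = "qc_config")
}

spec_to_list <- function(spec) {
  list(
    body_size_mm = spec$body_size_mm,
    thickness_mm = spec$thickness_mm,
    wax_block_size_mm = spec$wax_block_size_mm,
    wax_block_offset_mm = spec$wax_block_offset_mm,
    speck_spacing_mm = spec$speck_spacing_mm,
    fiber_length_mm = spec$fiber_length_mm,
    mass_diameter_mm = spec$mass_diameter_mm,
    objects = lapply(spec$objects, function(ob) {
      ob <- unclass(ob)
      ob[!vapply(ob, function(x) all(is.na(x)), TRUE)]
    })
  )
}

list_to_spec <- function(x) {
  objects <- lapply(x$objects, function(ob) {
    object_spec(
      kind = ob$kind, index = ob$index, size_mm = ob$size_mm,
      center_mm = unlist(ob$center_mm),
      orientation_deg = ob$orientation_deg %||% NA_real_,
      speck_spacing_mm = ob$speck_spacing_mm %||% NA_real_,
      n_specks = ob$n_specks %||% NA_integer_
    )
  })
  spec <- structure(list(
    body_size_mm = unlist(x$body_size_mm),
    thickness_mm = x$thickness_mm,
    wax_block_size_mm = unlist(x$wax_block_size_mm),
    wax_block_offset_mm = unlist(x$wax_block_offset_mm),
    speck_spacing_mm = x$speck_spacing_mm,
    fiber_length_mm = x$fiber_length_mm,
    mass_diameter_mm = x$mass_diameter_mm,
    objects = objects
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the analysis configuration as a YAML file
#'
#' The file is human-editable structured text with nested sections
#' (`phantom`, `smoothing`, `localization`, `thresholds`); any subset of
#' keys may be present in a file handed to [read_phantom_config()] -- missing
#' keys keep their built-in defaults.
#'
#' @param config a `qc_config`.
#' @param path file path.
#' @return `read_phantom_config()` returns a `qc_config`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
write_phantom_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- NULL
  x <- c(list(phantom = spec_to_list(config$spec)), x)
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- yaml::read_yaml(path)
  config <- default_config()
  if (!is.null(x$phantom)) config$spec <- list_to_spec(x$phantom)
  for (key in c("smoothing", "localization", "thresholds"))
    if (!is.null(x[[key]]))
      config[[key]] <- utils::modifyList(config[[key]], x[[key]])
  if (!is.null(x$chest_wall_default))
    config$chest_wall_default <- x$chest_wall_default
  # YAML turns length-2 vectors into lists; flatten numeric leaves
  config$thresholds <- lapply(config$thresholds, function(th)
    lapply(th, function(v) if (is.list(v)) unlist(v) else v))
  config
}

# Stable fingerprint of the resolved configuration, embedded in reports so
# longitudinal QC comparisons are auditable.
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_phantom_config(config, tmp)
  unname(tools::md5sum(tmp))
}
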