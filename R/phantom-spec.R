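#' mammoqc: automated ACR DM phantom image quality scoring
#'
#' Automated scoring of ACR Digital Mammography accreditation phantom
#' (Model 086) images: wax-insert localization, per-object template
#' matching with supplementary validators, count-until-zero group scoring
#' and RANZCR/ACR pass evaluation, plus a synthetic phantom simulator and
#' observer-agreement statistics.
#'
#' @section Coordinate conventions:
#' All physical geometry lives in millimetres. The wax-block frame has its
#' origin at the block's top-left corner, x rightward (away from the chest
#' wall), y downward. Pixel frames are `(row, col)`, 1-based as usual in R;
#' the centre of pixel `(r, c)` sits at `((c - 0.5) * spacing,
#' (r - 0.5) * spacing)` mm. In-plane angles are measured in degrees from
#' the +x axis towards +y (downward), modulo 180.
#'
#' @importFrom stats aov fft median quantile rnorm rpois runif sd setNames coef
#' @importFrom utils modifyList read.csv write.csv packageVersion
#' @importFrom tools md5sum
#' @keywords internal
"_PACKAGE"

OBJECT_KINDS <- c("fiber", "speck_group", "mass")

#' Specification of a single phantom test object
#'
#' @param kind one of `"fiber"`, `"speck_group"`, `"mass"`.
#' @param index integer 1-6; 1 is the largest / most visible object.
#' @param size_mm fiber diameter, speck diameter, or mass thickness proxy (mm).
#' @param center_mm length-2 numeric, object centre `(x, y)` in the wax-block
#'   frame (mm).
#' @param orientation_deg nominal in-plane angle (fibers only; 45 for odd
#'   indices, 135 for even).
#' @param speck_spacing_mm nominal centre-to-centre distance between a speck
#'   and the group centre (speck groups only).
#' @param n_specks number of specks per group (speck groups only).
#'
#' @return an `object_spec` list.
#' @export
object_spec <- function(kind, index, size_mm, center_mm,
                        orientation_deg = NA_real_,
                        speck_spacing_mm = NA_real_,
                        n_specks = NA_integer_) {
  kind <- match.arg(kind, OBJECT_KINDS)
  stopifnot(index %in% 1:6, size_mm > 0, length(center_mm) == 2)
  structure(list(
    kind = kind,
    index = as.integer(index),
    size_mm = size_mm,
    center_mm = as.numeric(center_mm),
    orientation_deg = orientation_deg,
    speck_spacing_mm = speck_spacing_mm,
    n_specks = as.integer(n_specks)
  ), class = "object_spec")
}

# Geometric size ladder between the printed endpoints; the fiber ladder is
# pinned at 0.61 mm for index 3 (geometric on each side of the pin).
size_ladder <- function(kind) {
  switch(kind,
    fiber = {
      a <- exp(seq(log(0.80), log(0.61), length.out = 3))
      b <- exp(seq(log(0.61), log(0.33), length.out = 4))
      c(a, b[-1])
    },
    speck_group = exp(seq(log(0.33), log(0.14), length.out = 6)),
    mass = exp(seq(log(1.00), log(0.20), length.out = 6))
  )
}

#' Default ACR DM phantom (Model 086) layout
#'
#' The shipped layout: a 31 x 19 cm, 4.1 cm thick PMMA body holding a
#' rectangular wax insert with 18 test objects -- six fibers (0.33-0.80 mm
#' diameter, alternating 45 deg / 135 deg), six groups of six
#' microcalcification specks (0.14-0.33 mm) and six masses (0.20-1.00 mm
#' thickness proxy) -- arranged on a 3-column (fibers | speck groups |
#' masses), 6-row grid, sizes decreasing with the row index. The exact
#' per-index sizes and coordinates of the commercial insert are not public;
#' the ladders are geometric interpolations between the published endpoints
#' (fiber 3 pinned at 0.61 mm) and every value here can be overridden via a
#' config file ([read_phantom_config()]) by users holding the vendor
#' datasheet.
#'
#' @param wax_block_size_mm `(width, height)` of the wax insert, mm.
#' @param wax_block_offset_mm `(x, y)` of the insert's top-left corner in the
#'   phantom-body frame (origin = body's chest-wall/top corner), mm.
#' @param speck_spacing_mm centre-to-neighbour distance within a speck group.
#' @param fiber_length_mm rendered/template fiber length.
#' @param mass_diameter_mm rendered/template mass disc diameter (the mass
#'   size ladder is a thickness proxy that maps to contrast, not extent).
#'
#' @return a `phantom_spec` list with fields `body_size_mm`, `thickness_mm`,
#'   `wax_block_size_mm`, `wax_block_offset_mm`, the rendering constants
#'   above and `objects`, an ordered list of 18 [object_spec()]s.
#' @export
default_phantom_spec <- function(wax_block_size_mm = c(60, 90),
                                 wax_block_offset_mm = c(17, 110),
                                 speck_spacing_mm = 2.0,
                                 fiber_length_mm = 8.0,
                                 mass_diameter_mm = 3.0) {
  w <- wax_block_size_mm[1]
  h <- wax_block_size_mm[2]
  col_x <- w * c(1, 3, 5) / 6          # fibers | speck groups | masses
  row_y <- h * (seq_len(6) - 0.5) / 6
  objects <- list()
  for (kind_i in seq_along(OBJECT_KINDS)) {
    kind <- OBJECT_KINDS[kind_i]
    sizes <- size_ladder(kind)
    for (i in 1:6) {
      objects[[length(objects) + 1L]] <- object_spec(
        kind = kind, index = i, size_mm = sizes[i],
        center_mm = c(col_x[kind_i], row_y[i]),
        orientation_deg = if (kind == "fiber") c(45, 135)[1 + (i + 1) %% 2],
        speck_spacing_mm = if (kind == "speck_group") speck_spacing_mm,
        n_specks = if (kind == "speck_group") 6L
      )
    }
  }
  spec <- structure(list(
    body_size_mm = c(190, 310),   # (x extent away from chest wall, y extent)
    thickness_mm = 41.0,
    wax_block_size_mm = as.numeric(wax_block_size_mm),
    wax_block_offset_mm = as.numeric(wax_block_offset_mm),
    speck_spacing_mm = speck_spacing_mm,
    fiber_length_mm = fiber_length_mm,
    mass_diameter_mm = mass_diameter_mm,
    objects = objects
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom spec's structural invariants
#'
#' Checks: exactly six objects per kind with indices 1-6 each once, sizes
#' strictly decreasing with index within a kind, all object footprints
#' strictly inside the wax block.
#'
#' @param spec a `phantom_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  kinds <- vapply(spec$objects, `[[`, "", "kind")
  idx <- vapply(spec$objects, `[[`, 1L, "index")
  if (length(spec$objects) != 18L)
    stop("phantom spec must hold exactly 18 objects")
  for (kind in OBJECT_KINDS) {
    sel <- kinds == kind
    if (sum(sel) != 6L || !setequal(idx[sel], 1:6))
      stop("phantom spec needs indices 1-6 exactly once per kind")
    sizes <- vapply(spec$objects[sel], `[[`, 0, "size_mm")[order(idx[sel])]
    if (any(diff(sizes) >= 0))
      stop("object sizes must strictly decrease with index within a kind")
  }
  w <- spec$wax_block_size_mm[1]; h <- spec$wax_block_size_mm[2]
  for (ob in spec$objects) {
    half <- object_halfwidth_mm(ob, spec)
    if (ob$center_mm[1] - half <= 0 || ob$center_mm[1] + half >= w ||
        ob$center_mm[2] - half <= 0 || ob$center_mm[2] + half >= h)
      stop(sprintf("object %s-%d footprint extends outside the wax block",
                   ob$kind, ob$index))
  }
  invisible(spec)
}

# Half-extent (mm) of an object's physical footprint, used for containment
# checks and ROI margins.
object_halfwidth_mm <- function(ob, spec) {
  switch(ob$kind,
    fiber = spec$fiber_length_mm / 2,
    speck_group = ob$speck_spacing_mm + ob$size_mm,
    mass = spec$mass_diameter_mm / 2
  )
}

# Look up one object_spec.
get_object <- function(spec, kind, index) {
  kind <- match.arg(kind, OBJECT_KINDS)
  stopifnot(index %in% 1:6)
  for (ob in spec$objects)
    if (ob$kind == kind && ob$index == index) return(ob)
  stop(sprintf("no object %s-%d in spec", kind, index))
}

#' ROI rectangle of one object in the wax-block pixel frame
#'
#' The wax block is tiled into a 3 x 6 grid of cells, one per object;
#' the cell of `(kind, index)` is that object's region of interest.
#' Geometry is resolution independent: the mm-frame rectangle depends only
#' on the spec, and is converted to pixels with the given spacing.
#'
#' @param spec a `phantom_spec`.
#' @param kind,index object selector.
#' @param pixel_spacing_mm pixel pitch (mm), > 0.
#' @return list with `row0`, `col0` (1-based top-left pixel), `nrow`, `ncol`,
#'   and the mm-frame rectangle `x0_mm`, `y0_mm`, `w_mm`, `h_mm`.
#' @export
object_roi_bounds <- function(spec, kind, index, pixel_spacing_mm) {
  stopifnot(pixel_spacing_mm > 0)
  kind <- match.arg(kind, OBJECT_KINDS)
  stopifnot(index %in% 1:6)
  w <- spec$wax_block_size_mm[1]; h <- spec$wax_block_size_mm[2]
  kind_i <- match(kind, OBJECT_KINDS)
  x0 <- w * (kind_i - 1) / 3
  y0 <- h * (index - 1) / 6
  cw <- w / 3; ch <- h / 6
  list(
    row0 = floor(y0 / pixel_spacing_mm) + 1L,
    col0 = floor(x0 / pixel_spacing_mm) + 1L,
    nrow = max(1L, round(ch / pixel_spacing_mm)),
    ncol = max(1L, round(cw / pixel_spacing_mm)),
    x0_mm = x0, y0_mm = y0, w_mm = cw, h_mm = ch
  )
}

#' Pass criteria for the phantom image quality test
#'
#' Minimum group scores: RANZCR requires fibers >= 4, speck groups >= 3,
#' masses >= 3; ACR requires fibers >= 2, speck groups >= 3, masses >= 2.
#'
#' @param name `"RANZCR"` or `"ACR"`.
#' @return list with `name`, `min_fibers`, `min_specks`, `min_masses`.
#' @export
pass_criteria <- function(name = c("RANZCR", "ACR")) {
  name <- match.arg(name)
  if (name == "RANZCR")
    list(name = "RANZCR", min_fibers = 4, min_specks = 3, min_masses = 3)
  else
    list(name = "ACR", min_fibers = 2, min_specks = 3, min_masses = 2)
}
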