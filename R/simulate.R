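# Synthetic ACR DM phantom renderer: the test harness standing in for
# clinical phantom images. Scene = detector background + PMMA body + wax
# insert + 18 test objects, rendered analytically in the transformed
# (shifted / rotated / overhung) phantom frame, then Poisson-Gaussian
# noise. Every random draw is governed by `seed`.

DOSE_FACTORS <- c(low = 0.4, normal = 1.0, high = 2.5)

#' Simulation configuration
#'
#' @param spec phantom layout shared with the analyzer.
#' @param pixel_spacing_mm detector pixel pitch (mm).
#' @param dose_mode `"low"`, `"normal"` or `"high"` AEC surrogate; maps to a
#'   relative exposure factor (0.4 / 1 / 2.5) that divides the
#'   quantum-noise variance, so low dose means the noisiest image.
#' @param contrast_ladder per-kind `base` contrast (fraction of the wax
#'   level) and per-index `decay` factor: object `i` is rendered with
#'   amplitude `wax_level * base * decay^(i-1)`, giving the monotonically
#'   decreasing visibility ladder of the physical insert.
#' @param noise list: `gain` (quantum-noise variance per intensity unit at
#'   normal dose) and `read_sd` (Gaussian read noise, intensity units).
#' @param shift_mm `(x, y)` displacement of the phantom; y is the lateral
#'   direction (parallel to the chest-wall edge, positive = "right"), x
#'   moves the phantom away from the chest wall.
#' @param rotation_deg in-plane rotation about the wax-block centre
#'   (positive = "right" / clockwise on screen).
#' @param overhang_mm signed chest-wall offset: positive pushes the phantom
#'   past the chest-wall image edge (truncating it), negative is underhang.
#' @param seed RNG seed; fixed seed gives bit-identical images.
#' @param image_extent_mm `(x, y)` physical size of the detector field.
#' @param levels background intensity levels (air, PMMA body, wax insert).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(spec = default_phantom_spec(),
                              pixel_spacing_mm = 0.1,
                              dose_mode = c("normal", "low", "high"),
                              contrast_ladder = list(
                                fiber = list(base = 0.09, decay = 0.75),
                                speck_group = list(base = 0.20, decay = 0.75),
                                mass = list(base = 0.07, decay = 0.75)
                              ),
                              noise = list(gain = 1.0, read_sd = 20),
                              shift_mm = c(0, 0),
                              rotation_deg = 0,
                              overhang_mm = 0,
                              seed = 1L,
                              image_extent_mm = c(230, 370),
                              levels = c(air = 500, body = 2600, wax = 4000)) {
  dose_mode <- match.arg(dose_mode)
  structure(list(
    spec = spec, pixel_spacing_mm = pixel_spacing_mm, dose_mode = dose_mode,
    contrast_ladder = contrast_ladder, noise = noise,
    shift_mm = as.numeric(shift_mm), rotation_deg = rotation_deg,
    overhang_mm = overhang_mm, seed = as.integer(seed),
    image_extent_mm = as.numeric(image_extent_mm), levels = levels
  ), class = "simulation_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Forward transform: phantom-frame mm -> image-frame mm.
# Shift first, then rotation about the (shifted) wax-block centre.
phantom_transform <- function(config) {
  spec <- config$spec
  origin <- c(-config$overhang_mm + config$shift_mm[1],
              (config$image_extent_mm[2] - spec$body_size_mm[2]) / 2 +
                config$shift_mm[2])
  centre <- origin + spec$wax_block_offset_mm + spec$wax_block_size_mm / 2
  th <- config$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(origin = origin, centre = centre, R = R,
       fwd = function(p) {           # p: n x 2 matrix of phantom-frame mm
         p <- matrix(p, ncol = 2)
         sweep(sweep(p, 2, origin - centre, "+") %*% t(R), 2, centre, "+")
       },
       inv = function(q) {           # image-frame mm -> phantom-frame mm
         q <- matrix(q, ncol = 2)
         sweep(sweep(q, 2, centre, "-") %*% R, 2, centre - origin, "+")
       })
}

#' Generate a synthetic phantom image with ground truth
#'
#' Renders the configured scene deterministically for a fixed seed: thin
#' anti-aliased bars for fibers (alternating 45 deg / 135 deg), six
#' Gaussian dots per speck group (FWHM = speck diameter, pentagon + centre
#' arrangement at the nominal spacing), radially smooth discs for masses,
#' with per-index amplitudes from the contrast ladder; then applies the
#' configured shift / rotation / overhang and finally Poisson-Gaussian
#' noise. A positive overhang truncates the scene at the chest-wall (left)
#' image edge.
#'
#' @param config a [simulation_config()].
#' @return list with `image` (a `phantom_image`) and `truth`, a data frame
#'   of per-object true pixel centres, orientations, rendered amplitudes, a
#'   detectability-proxy `visible` flag and an `in_image` flag; `truth`
#'   carries the applied block corner/rotation geometry as attributes.
#' @export
generate_phantom <- function(config) {
  spec <- config$spec
  s <- config$pixel_spacing_mm
  nr <- round(config$image_extent_mm[2] / s)
  nc <- round(config$image_extent_mm[1] / s)
  lv <- config$levels
  tr <- phantom_transform(config)

  set.seed(config$seed)
  img <- matrix(lv[["air"]], nr, nc)

  # pixel-centre coordinates (mm) of the full image
  xs <- (seq_len(nc) - 0.5) * s
  ys <- (seq_len(nr) - 0.5) * s

  soft <- function(d) clamp01(d / s + 0.5)  # d: signed mm inside the edge

  # body + wax rectangles, evaluated in the inverse-transformed frame;
  # px/py are the phantom-frame coordinates of every pixel centre
  th <- config$rotation_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- tr$centre[1]; cy <- tr$centre[2]
  kx <- cx - tr$origin[1] - ct * cx - st * cy
  ky <- cy - tr$origin[2] + st * cx - ct * cy
  px <- outer(st * ys, ct * xs, "+") + kx
  py <- outer(ct * ys, -st * xs, "+") + ky
  img <- img + (lv[["body"]] - lv[["air"]]) *
    (soft(px) * soft(spec$body_size_mm[1] - px) *
     soft(py) * soft(spec$body_size_mm[2] - py))
  b0 <- spec$wax_block_offset_mm
  bs <- spec$wax_block_size_mm
  corners <- tr$fwd(rbind(b0, b0 + c(bs[1], 0), b0 + bs, b0 + c(0, bs[2])))
  r0 <- max(1L, floor(min(corners[, 2]) / s) - 2L)
  r1 <- min(nr, ceiling(max(corners[, 2]) / s) + 2L)
  c0 <- max(1L, floor(min(corners[, 1]) / s) - 2L)
  c1 <- min(nc, ceiling(max(corners[, 1]) / s) + 2L)
  if (r0 <= r1 && c0 <= c1) {
    pxw <- px[r0:r1, c0:c1]; pyw <- py[r0:r1, c0:c1]
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + (lv[["wax"]] - lv[["body"]]) *
      (soft(pxw - b0[1]) * soft(b0[1] + bs[1] - pxw) *
       soft(pyw - b0[2]) * soft(b0[2] + bs[2] - pyw))
    rm(pxw, pyw)
  }
  rm(px, py)

  truth <- data.frame()
  for (ob in spec$objects) {
    lad <- config$contrast_ladder[[ob$kind]]
    amp <- lv[["wax"]] * lad$base * lad$decay^(ob$index - 1)
    centre_block <- ob$center_mm
    centre_phantom <- b0 + centre_block
    centre_img <- as.vector(tr$fwd(centre_phantom))

    half <- object_halfwidth_mm(ob, spec) + 2.5
    r0 <- max(1L, floor((centre_img[2] - half) / s))
    r1 <- min(nr, ceiling((centre_img[2] + half) / s))
    c0 <- max(1L, floor((centre_img[1] - half) / s))
    c1 <- min(nc, ceiling((centre_img[1] + half) / s))
    if (r0 <= r1 && c0 <= c1) {
      lx <- (c0:c1 - 0.5) * s
      ly <- (r0:r1 - 0.5) * s
      LP <- tr$inv(cbind(rep(lx, each = length(ly)), rep(ly, length(lx))))
      dx <- LP[, 1] - centre_phantom[1]
      dy <- LP[, 2] - centre_phantom[2]
      add <- switch(ob$kind,
        fiber = {
          th <- ob$orientation_deg * pi / 180
          u <- c(cos(th), sin(th))
          along <- abs(dx * u[1] + dy * u[2]) - spec$fiber_length_mm / 2
          perp <- abs(-dx * u[2] + dy * u[1]) - ob$size_mm / 2
          amp * clamp01(0.5 - perp / s) * clamp01(0.5 - along / s)
        },
        speck_group = {
          sig <- ob$size_mm / (2 * sqrt(2 * log(2)))  # FWHM = diameter
          ang <- (90 + 72 * 0:4) * pi / 180
          cx <- c(0, ob$speck_spacing_mm * cos(ang))
          cy <- c(0, ob$speck_spacing_mm * sin(ang))
          v <- 0
          for (k in seq_along(cx))
            v <- v + exp(-((dx - cx[k])^2 + (dy - cy[k])^2) / (2 * sig^2))
          amp * v
        },
        mass = {
          r <- sqrt(dx^2 + dy^2)
          edge <- max(0.3, s)
          amp * clamp01((spec$mass_diameter_mm / 2 - r) / edge + 0.5)
        })
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        matrix(add, r1 - r0 + 1, c1 - c0 + 1)
    }

    truth <- rbind(truth, data.frame(
      kind = ob$kind, index = ob$index,
      row_px = centre_img[2] / s + 0.5, col_px = centre_img[1] / s + 0.5,
      orientation_deg = if (ob$kind == "fiber")
        (ob$orientation_deg + config$rotation_deg) %% 180 else NA_real_,
      amplitude = amp,
      in_image = centre_img[1] > 0 && centre_img[1] < config$image_extent_mm[1] &&
                 centre_img[2] > 0 && centre_img[2] < config$image_extent_mm[2]
    ))
  }

  dose <- DOSE_FACTORS[[config$dose_mode]]
  noise_sd_wax <- sqrt(config$noise$gain * lv[["wax"]] / dose +
                       config$noise$read_sd^2)
  truth$visible <- truth$amplitude >= 2 * noise_sd_wax & truth$in_image
  if (config$noise$gain > 0 || config$noise$read_sd > 0) {
    sdmap <- sqrt(config$noise$gain * pmax(img, 0) / dose +
                  config$noise$read_sd^2)
    img <- img + rnorm(length(img), 0, 1) * sdmap
    img[img < 0] <- 0
  }

  corners_phantom <- rbind(b0, b0 + c(bs[1], 0), b0 + bs, b0 + c(0, bs[2]))
  corners_img <- tr$fwd(corners_phantom)
  attr(truth, "block_corners_px") <- cbind(row = corners_img[, 2] / s + 0.5,
                                           col = corners_img[, 1] / s + 0.5)
  attr(truth, "block_centre_px") <- c(row = tr$centre[2] / s + 0.5,
                                      col = tr$centre[1] / s + 0.5)
  attr(truth, "rotation_deg") <- config$rotation_deg
  attr(truth, "noise_sd_wax") <- noise_sd_wax

  list(
    image = phantom_image(
      pixels = img, pixel_spacing_mm = s, photometric = "MONOCHROME2",
      chest_wall_edge = "left", source = "synthetic",
      metadata = list(dose_mode = config$dose_mode, seed = config$seed)
    ),
    truth = truth
  )
}

#' Noise-free copy of a simulation configuration
#'
#' @param config a `simulation_config`.
#' @return the same configuration with all noise sources disabled.
#' @export
noise_free <- function(config) {
  config$noise <- list(gain = 0, read_sd = 0)
  config
}

#' The 12-image phantom positioning suite
#'
#' The standard robustness protocol: lateral movements of 15 and 25 mm to
#' left and right, rotations of about 2.5 and 5 degrees to right and left,
#' and under-/overhanging the chest-wall edge by 15 and 25 mm.
#'
#' @param base a [simulation_config()] supplying everything but the
#'   positioning perturbation.
#' @return named list of 12 configurations, in the protocol order.
#' @export
positioning_suite <- function(base = simulation_config()) {
  mod <- function(label, ...) {
    cfg <- base
    for (nm in names(list(...))) cfg[[nm]] <- list(...)[[nm]]
    cfg$label <- label
    cfg
  }
  configs <- list(
    mod("lateral_left_15mm", shift_mm = c(0, -15)),
    mod("lateral_left_25mm", shift_mm = c(0, -25)),
    mod("lateral_right_15mm", shift_mm = c(0, 15)),
    mod("lateral_right_25mm", shift_mm = c(0, 25)),
    mod("rotation_right_2.5deg", rotation_deg = 2.5),
    mod("rotation_left_2.5deg", rotation_deg = -2.5),
    mod("rotation_right_5deg", rotation_deg = 5),
    mod("rotation_left_5deg", rotation_deg = -5),
    mod("underhang_15mm", overhang_mm = -15),
    mod("underhang_25mm", overhang_mm = -25),
    mod("overhang_15mm", overhang_mm = 15),
    mod("overhang_25mm", overhang_mm = 25)
  )
  names(configs) <- vapply(configs, `[[`, "", "label")
  configs
}
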