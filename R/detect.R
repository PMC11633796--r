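# Object detection: normalized cross-correlation template matching plus
# the three per-kind supplementary validators (2D Gaussian mass fit, speck
# Euclidean-distance check, fiber blob-orientation check).

#' Generate a binary template for a phantom test object
#'
#' Templates encode each object's nominal shape, orientation and physical
#' size: a disc of the nominal mass diameter, an oriented bar of the
#' fiber's diameter, or a dot of the speck's diameter. At the reference
#' 50 um pixel pitch the mass and fiber templates are 80 x 80 px and the
#' individual-speck template 15 x 15 px; at other pitches the window scales
#' by `0.05 / spacing`, rounded to the nearest odd size.
#'
#' @param kind,index object selector.
#' @param spec a `phantom_spec` (supplies sizes and orientations).
#' @param pixel_spacing_mm pixel pitch, > 0.
#' @return a `template`: list with binary matrix `t`, its mean `t_bar`,
#'   `kind`, `index`, `physical_size_mm` and (fibers) `orientation_deg`.
#' @export
make_template <- function(kind, index, spec, pixel_spacing_mm) {
  stopifnot(pixel_spacing_mm > 0)
  kind <- match.arg(kind, OBJECT_KINDS)
  ob <- get_object(spec, kind, index)
  base <- if (kind == "speck_group") 15L else 80L
  if (isTRUE(all.equal(pixel_spacing_mm, 0.05))) {
    n <- base
  } else {
    k <- base * 0.05 / pixel_spacing_mm
    n <- 2L * as.integer(round((k - 1) / 2)) + 1L
    n <- max(n, 3L)
  }
  ctr <- (n + 1) / 2
  x <- (matrix(seq_len(n), n, n, byrow = TRUE) - ctr) * pixel_spacing_mm
  y <- (matrix(seq_len(n), n, n) - ctr) * pixel_spacing_mm
  t <- switch(kind,
    mass = {
      (x^2 + y^2) <= (spec$mass_diameter_mm / 2)^2
    },
    fiber = {
      th <- ob$orientation_deg * pi / 180
      along <- abs(x * cos(th) + y * sin(th))
      perp <- abs(-x * sin(th) + y * cos(th))
      len <- min(spec$fiber_length_mm, 0.9 * n * pixel_spacing_mm)
      (along <= len / 2) & (perp <= max(ob$size_mm, pixel_spacing_mm) / 2)
    },
    speck_group = {
      (x^2 + y^2) <= max(ob$size_mm / 2, 0.6 * pixel_spacing_mm)^2
    })
  t <- matrix(as.numeric(t), n, n)
  if (all(t == 0) || all(t == 1))
    stop(sprintf("degenerate template for %s-%d at %.3f mm spacing",
                 kind, index, pixel_spacing_mm))
  structure(list(
    t = t, t_bar = mean(t), kind = kind, index = ob$index,
    physical_size_mm = ob$size_mm,
    orientation_deg = if (kind == "fiber") ob$orientation_deg else NA_real_
  ), class = "template")
}

#' Windowed zero-mean normalized cross-correlation
#'
#' Slides the template across the sub-image and computes, at every valid
#' offset, the correlation coefficient between the template and the
#' image window:
#' \deqn{\gamma(u,v) = \frac{\sum_{x,y} [f(x,y) - \bar f_{u,v}][t(x-u, y-v) - \bar t]}
#'   {\{\sum_{x,y} [f(x,y)-\bar f_{u,v}]^2 \sum_{x,y} [t(x-u,y-v)-\bar t]^2\}^{0.5}}}
#' where \eqn{\bar f_{u,v}} is the image mean under the window at offset
#' `(u, v)` and \eqn{\bar t} the template mean. \eqn{\gamma = 1} exactly
#' where the window is a positive affine transform of the template;
#' windows of (numerically) zero variance are defined as \eqn{\gamma = 0}.
#' The sliding sums use FFT cross-correlation and integral images.
#'
#' @param template a [make_template()] result, or a plain non-constant
#'   numeric matrix.
#' @param sub_image numeric matrix strictly larger than the template in
#'   both dimensions.
#' @return a `correlation_result`: list with `gamma` (the
#'   `(nr-tr+1) x (nc-tc+1)` surface of valid offsets), `peak_gamma`,
#'   `peak_uv` (1-based (row, col) of the window top-left at the peak),
#'   `peak_center_px` (object-centre estimate) and `f_bar_local`
#'   (windowed image means).
#' @export
normxcorr2 <- function(template, sub_image) {
  t <- if (inherits(template, "template")) template$t else template
  stopifnot(is.matrix(t), is.matrix(sub_image))
  tr <- nrow(t); tc <- ncol(t)
  nr <- nrow(sub_image); nc <- ncol(sub_image)
  if (tr > nr || tc > nc)
    stop("template must be no larger than the sub-image in both dimensions")
  t0 <- t - mean(t)
  st2 <- sum(t0^2)
  if (st2 <= .Machine$double.eps * length(t0))
    stop("constant template: correlation undefined")

  tpad <- matrix(0, nr, nc)
  tpad[seq_len(tr), seq_len(tc)] <- t0
  xc <- Re(fft(fft(sub_image) * Conj(fft(tpad)), inverse = TRUE)) / (nr * nc)
  vr <- nr - tr + 1L; vc <- nc - tc + 1L
  num <- xc[seq_len(vr), seq_len(vc), drop = FALSE]

  # windowed sums via integral images
  ii <- function(m) {
    z <- matrix(0, nr + 1, nc + 1)
    z[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    z
  }
  S <- ii(sub_image)
  S2 <- ii(sub_image^2)
  wsum <- function(z) {
    z[(tr + 1):(nr + 1), (tc + 1):(nc + 1), drop = FALSE] -
      z[(tr + 1):(nr + 1), seq_len(vc), drop = FALSE] -
      z[seq_len(vr), (tc + 1):(nc + 1), drop = FALSE] +
      z[seq_len(vr), seq_len(vc), drop = FALSE]
  }
  n_t <- tr * tc
  sw <- wsum(S)
  s2w <- wsum(S2)
  varsum <- pmax(s2w - sw^2 / n_t, 0)

  # numerical floor: windows whose variance is at roundoff scale are
  # treated as constant (gamma = 0)
  tol <- (1e-5 * max(abs(sub_image), 1))^2 * n_t
  denom <- sqrt(varsum * st2)
  gamma <- ifelse(varsum <= tol, 0, num / denom)
  gamma <- pmin(pmax(gamma, -1), 1)

  pk <- arrayInd(which.max(gamma), dim(gamma))
  structure(list(
    gamma = gamma,
    slope = num / st2,   # least-squares template amplitude at each offset
    peak_gamma = gamma[pk],
    peak_uv = c(row = pk[1], col = pk[2]),
    peak_center_px = c(row = pk[1] + (tr - 1) / 2,
                       col = pk[2] + (tc - 1) / 2),
    f_bar_local = sw / n_t,
    template_dim = c(tr, tc)
  ), class = "correlation_result")
}

#' Euclidean distances from the centre speck to candidate specks
#'
#' @param positions n x 2 matrix of candidate (row, col) positions.
#' @param center length-2 centre-speck position.
#' @return numeric vector of distances (same units as the inputs).
#' @export
speck_distances <- function(positions, center) {
  positions <- matrix(positions, ncol = 2)
  sqrt((positions[, 1] - center[1])^2 + (positions[, 2] - center[2])^2)
}

#' Map a validated-speck count to an object score
#'
#' Four or more specks score 1, two or three score 0.5, fewer than two
#' count as not detected (0). The centre speck is included in the count.
#'
#' @param n number of validated specks in the ROI.
#' @return 0, 0.5 or 1.
#' @export
speck_count_score <- function(n) {
  if (n >= 4) 1 else if (n >= 2) 0.5 else 0
}

#' Orientation of the largest blob of a binary mask
#'
#' Connected-component labelling of the mask, selection of the largest
#' blob, and principal-axis orientation from its second central image
#' moments.
#'
#' @param mask logical or 0/1 matrix.
#' @return list with `orientation_deg` in `[0, 180)`, `area_px`, and the
#'   blob's pixel coordinates; `NULL` when the mask is empty.
#' @export
blob_orientation <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(eb_from_matrix(mask))
  sizes <- tabulate(EBImage::imageData(lab))
  pts <- which(eb_to_matrix(lab) == which.max(sizes), arr.ind = TRUE)
  list(orientation_deg = points_orientation(pts),
       area_px = nrow(pts), points = pts)
}

#' Least-squares fit of an isotropic 2D Gaussian with constant background
#'
#' Fits `A * exp(-((x-x0)^2 + (y-y0)^2) / (2 * sigma0^2)) + Bkg` to a
#' pixel patch by Levenberg-Marquardt least squares, trying each supplied
#' initial guess and keeping the converged fit with the lowest residual.
#'
#' @param z numeric matrix (the patch).
#' @param starts list of named start vectors (`A`, `x0`, `y0`, `sigma0`,
#'   `bkg`); defaults to a small grid derived from the patch.
#' @return a `gaussian_fit`: `A`, `x0`, `y0` (1-based pixel coordinates,
#'   x = col, y = row), `sigma0`, `bkg`, `fwhm_px`
#'   (`2 sqrt(2 ln 2) sigma0`), `converged`, `residual_norm`.
#' @export
fit_gaussian2d <- function(z, starts = NULL) {
  df <- data.frame(
    x = rep(seq_len(ncol(z)), each = nrow(z)),
    y = rep(seq_len(nrow(z)), ncol(z)),
    v = as.vector(z)
  )
  if (is.null(starts)) {
    pk <- arrayInd(which.max(z), dim(z))
    b0 <- median(z)
    starts <- lapply(c(2, 4, 8), function(s0)
      c(A = max(z) - b0, x0 = pk[2], y0 = pk[1], sigma0 = s0, bkg = b0))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma0^2)) + bkg,
        data = df,
        start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$residual_norm) {
      p <- coef(fit)
      best <- list(A = unname(p["A"]), x0 = unname(p["x0"]),
                   y0 = unname(p["y0"]), sigma0 = abs(unname(p["sigma0"])),
                   bkg = unname(p["bkg"]),
                   fwhm_px = 2 * sqrt(2 * log(2)) * abs(unname(p["sigma0"])),
                   converged = TRUE, residual_norm = rn)
    }
  }
  if (is.null(best))
    best <- list(A = NA_real_, x0 = NA_real_, y0 = NA_real_,
                 sigma0 = NA_real_, bkg = NA_real_, fwhm_px = NA_real_,
                 converged = FALSE, residual_norm = NA_real_)
  structure(best, class = "gaussian_fit")
}

# Score from the correlation peak and the validator outcome. A failed
# validator always scores 0; the 0.5 band is the documented interpretation
# for fibers and masses (partial visibility = peak in
# [gamma_partial, gamma_full) with a passing validator).
band_score <- function(peak_gamma, th, validated) {
  if (!validated) return(0)
  if (peak_gamma >= th$gamma_full) 1
  else if (peak_gamma >= th$gamma_partial) 0.5
  else 0
}

object_result <- function(kind, index, score, peak_gamma, validator,
                          stopped = FALSE) {
  structure(list(kind = kind, index = index, score = score,
                 peak_gamma = peak_gamma, validator = validator,
                 stopped = stopped),
            class = "object_result")
}

#' Detect and score a mass ROI
#'
#' Template matching gates the analysis: a correlation peak below
#' `gamma_zero` scores 0 outright. Otherwise an isotropic 2D Gaussian is
#' fitted around the correlation peak from multiple per-size initial
#' guesses; the mass counts as validated when the fitted centroid agrees
#' with the correlation peak (within a spacing-scaled tolerance) and the
#' fitted FWHM lies within the expected physical band. Validated masses
#' score 1 or 0.5 by the correlation bands.
#'
#' @param roi a smoothed ROI (from [smooth_roi()]).
#' @param template the mass [make_template()].
#' @param config a `qc_config`.
#' @param pixel_spacing_mm pixel pitch of the ROI.
#' @return an `object_result` with a `gaussian_fit` in `validator$fit`.
#' @export
analyze_mass <- function(roi, template, config, pixel_spacing_mm) {
  th <- config$thresholds$mass
  cr <- normxcorr2(template, roi$pixels)
  if (cr$peak_gamma < th$gamma_zero)
    return(object_result("mass", roi$index, 0, cr$peak_gamma,
                         list(gated = TRUE)))
  ctr <- cr$peak_center_px
  half <- ceiling(0.75 * nrow(template$t))
  r0 <- max(1, round(ctr["row"]) - half); r1 <- min(nrow(roi$pixels), round(ctr["row"]) + half)
  c0 <- max(1, round(ctr["col"]) - half); c1 <- min(ncol(roi$pixels), round(ctr["col"]) + half)
  patch <- roi$pixels[r0:r1, c0:c1]

  d_px <- config$spec$mass_diameter_mm / pixel_spacing_mm
  b0 <- median(patch)
  pk <- arrayInd(which.max(patch), dim(patch))
  starts <- lapply(d_px * c(0.25, 0.42, 0.6), function(s0)
    c(A = max(patch) - b0, x0 = pk[2], y0 = pk[1], sigma0 = s0, bkg = b0))
  fit <- fit_gaussian2d(patch, starts)

  fwhm_mm <- fit$fwhm_px * pixel_spacing_mm
  centroid_px <- c(row = fit$y0 + r0 - 1, col = fit$x0 + c0 - 1)
  tol_px <- th$centroid_tol_px_50um * 0.05 / pixel_spacing_mm
  dist_px <- sqrt(sum((centroid_px - ctr)^2))
  band <- th$fwhm_band * config$spec$mass_diameter_mm
  validated <- isTRUE(fit$converged) && dist_px <= tol_px &&
    !is.na(fwhm_mm) && fwhm_mm >= band[1] && fwhm_mm <= band[2]
  object_result("mass", roi$index,
                band_score(cr$peak_gamma, th, validated), cr$peak_gamma,
                list(fit = fit, fwhm_mm = fwhm_mm,
                     centroid_px = centroid_px,   # ROI frame (row, col)
                     centroid_dist_px = dist_px, pass = validated))
}

# Greedy non-maximum suppression: strongest-first selection of local
# maxima at least min_dist apart.
find_peaks <- function(gamma, threshold, min_dist, max_n = 12L) {
  idx <- which(gamma >= threshold)
  if (length(idx) == 0) return(matrix(numeric(0), 0, 2))
  ord <- idx[order(gamma[idx], decreasing = TRUE)]
  pts <- arrayInd(ord, dim(gamma))
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nrow(keep) == 0 ||
        min((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) >= min_dist^2) {
      keep <- rbind(keep, p)
      if (nrow(keep) >= max_n) break
    }
  }
  keep
}

#' Detect and score a speck-group ROI
#'
#' Candidate specks are local maxima of the single-speck correlation
#' surface above `peak_threshold`. The candidate nearest the ROI centre is
#' anchored as the centre speck; every other candidate is validated by its
#' Euclidean distance to the anchor against the nominal within-group
#' spacing (+/- `spacing_tol_frac`). The validated count (centre included)
#' maps to the score via [speck_count_score()].
#'
#' @inheritParams analyze_mass
#' @param template the individual-speck [make_template()].
#' @return an `object_result`; `validator` holds candidate positions,
#'   distances and the validated count `n`.
#' @export
analyze_speck_group <- function(roi, template, config, pixel_spacing_mm) {
  th <- config$thresholds$speck_group
  cr <- normxcorr2(template, roi$pixels)
  if (cr$peak_gamma < th$gamma_zero)
    return(object_result("speck_group", roi$index, 0, cr$peak_gamma,
                         list(gated = TRUE, n = 0)))
  ob <- get_object(config$spec, "speck_group", roi$index)
  spacing_px <- ob$speck_spacing_mm / pixel_spacing_mm
  # correlation is amplitude-blind: faint smooth noise bumps can match a
  # small disc as well as a real speck does, so candidate positions must
  # also carry a substantial fraction of the strongest eligible position's
  # fitted template amplitude -- masked out before non-max suppression so
  # a faint bump cannot shadow a real speck
  g <- cr$gamma
  eligible <- g >= th$peak_threshold
  if (any(eligible)) {
    cutoff <- (th$min_rel_amplitude %||% 0.35) * max(cr$slope[eligible])
    g[cr$slope < cutoff] <- 0
  }
  peaks <- find_peaks(g, th$peak_threshold,
                      min_dist = 0.5 * spacing_px, max_n = 24L)
  off <- (cr$template_dim - 1) / 2
  centers <- sweep(peaks, 2, off, "+")
  roi_ctr <- (dim(roi$pixels) + 1) / 2

  n <- 0L
  detail <- list(candidates_px = centers, n_candidates = nrow(centers))
  if (nrow(centers) > 0) {
    d_ctr <- speck_distances(centers, roi_ctr)
    anchor_i <- which.min(d_ctr)
    if (d_ctr[anchor_i] <= spacing_px) {
      anchor <- centers[anchor_i, ]
      others <- centers[-anchor_i, , drop = FALSE]
      d <- speck_distances(others, anchor) * pixel_spacing_mm
      ok <- abs(d - ob$speck_spacing_mm) <=
        th$spacing_tol_frac * ob$speck_spacing_mm
      n <- sum(ok) + 1L
      detail$anchor_px <- anchor
      detail$distances_mm <- d
      detail$accepted <- ok
    }
  }
  detail$n <- n
  object_result("speck_group", roi$index, speck_count_score(n),
                cr$peak_gamma, detail)
}

#' Detect and score a fiber ROI
#'
#' After the correlation gate, the correlation surface is binarized at a
#' fixed fraction of its peak and the largest blob's principal-axis
#' orientation is extracted. The fiber is validated only when that
#' orientation lies within +/- 4 degrees of the nominal 45 degrees (odd
#' indices) or 135 degrees (even indices), compared on the 180-degree
#' circle; validated fibers score 1 or 0.5 by the correlation bands.
#'
#' @inheritParams analyze_mass
#' @param template the fiber [make_template()] at the nominal orientation.
#' @return an `object_result`; `validator` holds the blob orientation,
#'   area and acceptance flag.
#' @export
analyze_fiber <- function(roi, template, config, pixel_spacing_mm) {
  th <- config$thresholds$fiber
  cr <- normxcorr2(template, roi$pixels)
  if (cr$peak_gamma < th$gamma_zero)
    return(object_result("fiber", roi$index, 0, cr$peak_gamma,
                         list(gated = TRUE)))
  blob <- blob_orientation(cr$gamma >= th$binarize_frac * cr$peak_gamma)
  nominal <- template$orientation_deg
  accepted <- !is.null(blob) &&
    angle_diff_180(blob$orientation_deg, nominal) <= th$angle_tol_deg
  object_result("fiber", roi$index,
                band_score(cr$peak_gamma, th, accepted), cr$peak_gamma,
                list(orientation_deg = if (is.null(blob)) NA_real_
                       else blob$orientation_deg,
                     area_px = if (is.null(blob)) 0L else blob$area_px,
                     nominal_deg = nominal, accepted = accepted))
}
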