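# Shared fixtures (generated in code, memoised across test files) and
# independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

sim_noise_free <- function() {
  cached("nf", generate_phantom(noise_free(simulation_config(seed = 1))))
}

sim_normal <- function() {
  cached("normal", generate_phantom(simulation_config(seed = 1)))
}

rois_noise_free <- function() {
  cached("nf_rois", {
    sim <- sim_noise_free()
    extract_rois(sim$image, segment_wax_block(sim$image, default_config()),
                 default_config())
  })
}

# Literal double-loop evaluation of the windowed zero-mean normalized
# cross-correlation: the independent oracle for normxcorr2().
normxcorr2_direct <- function(t, f) {
  tr <- nrow(t); tc <- ncol(t)
  vr <- nrow(f) - tr + 1; vc <- ncol(f) - tc + 1
  t0 <- t - mean(t)
  st2 <- sum(t0^2)
  g <- matrix(0, vr, vc)
  for (u in seq_len(vr)) {
    for (v in seq_len(vc)) {
      w <- f[u:(u + tr - 1), v:(v + tc - 1)]
      w0 <- w - mean(w)
      denom <- sqrt(sum(w0^2) * st2)
      g[u, v] <- if (denom < 1e-9) 0 else sum(w0 * t0) / denom
    }
  }
  g
}

# Flat wax-like ROI with a single anti-aliased bar at the given angle.
bar_roi <- function(angle_deg, amplitude = 400, width_mm = 0.6,
                    length_mm = 8, bg = 4000, spacing = 0.1) {
  m <- matrix(bg, 150, 200)
  x <- (matrix(seq_len(200), 150, 200, byrow = TRUE) - 100.5) * spacing
  y <- (matrix(seq_len(150), 150, 200) - 75.5) * spacing
  th <- angle_deg * pi / 180
  along <- abs(x * cos(th) + y * sin(th))
  perp <- abs(-x * sin(th) + y * cos(th))
  cl <- function(z) pmin(1, pmax(0, z))
  m + amplitude * cl(0.5 - (perp - width_mm / 2) / spacing) *
    cl(0.5 - (along - length_mm / 2) / spacing)
}

# Flat ROI with Gaussian specks at the given (row, col) px offsets from
# the ROI centre.
speck_roi <- function(offsets_px, amplitude = 600, sigma_px = 1.4,
                      bg = 4000, nr = 150, nc = 200) {
  m <- matrix(bg, nr, nc)
  ctr <- (c(nr, nc) + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(offsets_px))) {
    r0 <- ctr[1] + offsets_px[i, 1]
    c0 <- ctr[2] + offsets_px[i, 2]
    m <- m + amplitude * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma_px^2))
  }
  m
}

# Synthetic object_result for scoring-rule tests.
fake_result <- function(kind, index, score) {
  structure(list(kind = kind, index = index, score = score,
                 peak_gamma = NA_real_, validator = list(), stopped = FALSE),
            class = "object_result")
}

fake_group <- function(kind, scores) {
  lapply(seq_along(scores), function(i) fake_result(kind, i, scores[i]))
}
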