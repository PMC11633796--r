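test_that("templates have the published pixel sizes at 50 um pitch", {
  spec <- default_phantom_spec()
  expect_equal(dim(make_template("mass", 1, spec, 0.05)$t), c(80, 80))
  expect_equal(dim(make_template("fiber", 1, spec, 0.05)$t), c(80, 80))
  expect_equal(dim(make_template("speck_group", 1, spec, 0.05)$t), c(15, 15))
  # other pitches scale by 0.05/spacing, rounded to odd
  expect_equal(dim(make_template("mass", 1, spec, 0.1)$t), c(41, 41))
  t7 <- make_template("speck_group", 1, spec, 0.1)$t
  expect_equal(dim(t7), c(7, 7))
  expect_true(all(t7 %in% c(0, 1)))
  expect_gt(sd(t7), 0)
})

test_that("fiber templates carry the nominal orientation", {
  spec <- default_phantom_spec()
  for (i in 1:6) {
    tm <- make_template("fiber", i, spec, 0.05)
    nominal <- if (i %% 2 == 1) 45 else 135
    expect_equal(tm$orientation_deg, nominal)
    pts <- which(tm$t == 1, arr.ind = TRUE)
    measured <- mammoqc:::points_orientation(pts)
    expect_lt(mammoqc:::angle_diff_180(measured, nominal), 1)
  }
})

test_that("correlation peaks at 1 on an exact embedded copy and -1 on its negative", {
  set.seed(21)
  tm <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  img <- matrix(runif(30 * 25), 30, 25)
  img[10:12, 7:9] <- 5 + 2 * tm          # positive affine copy
  cr <- normxcorr2(tm, img)
  expect_equal(cr$peak_gamma, 1, tolerance = 1e-9)
  expect_equal(unname(cr$peak_uv), c(10, 7))

  img2 <- matrix(runif(30 * 25), 30, 25)
  img2[4:6, 12:14] <- 5 - 2 * tm         # anticorrelated copy
  cr2 <- normxcorr2(tm, img2)
  expect_equal(min(cr2$gamma), -1, tolerance = 1e-9)
  expect_equal(unname(arrayInd(which.min(cr2$gamma), dim(cr2$gamma))),
               matrix(c(4L, 12L), 1))
})

test_that("correlation equals the literal double-loop evaluation", {
  set.seed(22)
  for (rep in 1:20) {
    tr <- sample(2:8, 1); tc <- sample(2:8, 1)
    tm <- matrix(rbinom(tr * tc, 1, 0.5), tr, tc)
    if (sd(tm) == 0) tm[1] <- 1 - tm[1]
    nr <- sample((tr + 2):24, 1); nc <- sample((tc + 2):24, 1)
    img <- matrix(runif(nr * nc, 0, 100), nr, nc)
    fast <- normxcorr2(tm, img)$gamma
    slow <- normxcorr2_direct(tm, img)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("correlation is invariant to positive affine intensity transforms", {
  set.seed(23)
  tm <- matrix(rbinom(49, 1, 0.4), 7, 7)
  img <- matrix(runif(40 * 35, 0, 10), 40, 35)
  g1 <- normxcorr2(tm, img)$gamma
  g2 <- normxcorr2(tm, 3.7 * img + 250)$gamma
  expect_lt(max(abs(g1 - g2)), 1e-9)
})

test_that("degenerate correlation inputs raise errors; constant windows give 0", {
  expect_error(normxcorr2(matrix(1, 4, 4), matrix(runif(100), 10, 10)),
               "constant")
  expect_error(normxcorr2(matrix(rbinom(25, 1, 0.5), 5, 5),
                          matrix(1, 3, 3)), "larger")
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  img <- matrix(7, 10, 10)      # all-constant image
  img[5, 5] <- 9
  g <- normxcorr2(tm, img)$gamma
  expect_equal(g[1, 1], 0)      # constant window -> gamma defined as 0
})

test_that("speck distances form a metric and the 3-4-5 example holds", {
  expect_equal(speck_distances(matrix(c(3, 4), 1), c(0, 0)), 5)
  set.seed(24)
  for (rep in 1:50) {
    p <- matrix(runif(6, -10, 10), 3, 2)
    dab <- speck_distances(p[1, , drop = FALSE], p[2, ])
    dba <- speck_distances(p[2, , drop = FALSE], p[1, ])
    dac <- speck_distances(p[1, , drop = FALSE], p[3, ])
    dcb <- speck_distances(p[3, , drop = FALSE], p[2, ])
    expect_equal(dab, dba)
    expect_gte(dac + dcb, dab - 1e-12)
    expect_gte(dab, 0)
  }
})

test_that("validated speck counts map to the published scores", {
  expect_equal(speck_count_score(6), 1)
  expect_equal(speck_count_score(4), 1)
  expect_equal(speck_count_score(3), 0.5)
  expect_equal(speck_count_score(2), 0.5)
  expect_equal(speck_count_score(1), 0)
  expect_equal(speck_count_score(0), 0)
})

test_that("speck analysis counts centre plus in-band neighbours", {
  config <- default_config()
  tm <- make_template("speck_group", 2, config$spec, 0.1)
  # centre + 5 pentagon neighbours at the nominal 2 mm spacing
  ang <- (90 + 72 * 0:4) * pi / 180
  offs <- rbind(c(0, 0), cbind(20 * sin(ang), 20 * cos(ang)))
  roi <- list(pixels = speck_roi(offs), kind = "speck_group", index = 2)
  r <- analyze_speck_group(roi, tm, config, 0.1)
  expect_equal(r$validator$n, 6)
  expect_equal(r$score, 1)

  # centre + one in-band neighbour -> n = 2 -> 0.5
  roi2 <- list(pixels = speck_roi(rbind(c(0, 0), c(0, 20))),
               kind = "speck_group", index = 2)
  r2 <- analyze_speck_group(roi2, tm, config, 0.1)
  expect_equal(r2$validator$n, 2)
  expect_equal(r2$score, 0.5)

  # neighbours far outside the acceptance band are rejected -> n = 1 -> 0
  roi3 <- list(pixels = speck_roi(rbind(c(0, 0), c(0, 45), c(45, 0))),
               kind = "speck_group", index = 2)
  r3 <- analyze_speck_group(roi3, tm, config, 0.1)
  expect_equal(r3$validator$n, 1)
  expect_equal(r3$score, 0)
})

test_that("2D Gaussian fit recovers its own generating model to 1e-3", {
  nr <- 41; nc <- 41
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  z <- 100 * exp(-((x - 23.4)^2 + (y - 19.2)^2) / (2 * 5^2)) + 10
  fit <- fit_gaussian2d(z)
  expect_true(fit$converged)
  expect_equal(fit$A, 100, tolerance = 1e-3)
  expect_equal(fit$x0, 23.4, tolerance = 1e-3)
  expect_equal(fit$y0, 19.2, tolerance = 1e-3)
  expect_equal(fit$sigma0, 5, tolerance = 1e-3)
  expect_equal(fit$bkg, 10, tolerance = 1e-3)
  expect_equal(fit$fwhm_px, 2 * sqrt(2 * log(2)) * fit$sigma0)
})

test_that("mass analysis scores a clean mass 1 and an object-free ROI 0", {
  config <- default_config()
  rois <- rois_noise_free()
  sim <- sim_noise_free()
  tm <- make_template("mass", 1, config$spec, 0.1)
  r <- analyze_mass(smooth_roi(rois[["mass_1"]], 1), tm, config, 0.1)
  expect_equal(r$score, 1)
  expect_true(r$validator$pass)
  # fitted centre vs ground truth: mass 1 sits at its cell centre, and the
  # block was localized pixel-exactly on this noise-free render
  roi_ctr <- (dim(rois[["mass_1"]]$pixels) + 1) / 2
  expect_lt(abs(r$validator$centroid_px[["row"]] - roi_ctr[1]), 1)
  expect_lt(abs(r$validator$centroid_px[["col"]] - roi_ctr[2]), 1)

  set.seed(25)
  noise <- list(pixels = matrix(4000 + rnorm(150 * 200, 0, 60), 150, 200),
                kind = "mass", index = 6)
  r0 <- analyze_mass(smooth_roi(noise, 1), tm, config, 0.1)
  expect_equal(r0$score, 0)
})

test_that("fiber orientation gating accepts within 4 degrees and rejects outside", {
  config <- default_config()
  tm45 <- make_template("fiber", 1, config$spec, 0.1)
  r_good <- analyze_fiber(list(pixels = bar_roi(45), index = 1),
                          tm45, config, 0.1)
  expect_true(r_good$validator$accepted)
  expect_equal(r_good$score, 1)
  expect_lt(mammoqc:::angle_diff_180(r_good$validator$orientation_deg, 45), 4)

  r_52 <- analyze_fiber(list(pixels = bar_roi(52), index = 1),
                        tm45, config, 0.1)
  expect_false(r_52$validator$accepted)   # 52 > 45 + 4
  expect_equal(r_52$score, 0)

  tm135 <- make_template("fiber", 2, config$spec, 0.1)
  r_138 <- analyze_fiber(list(pixels = bar_roi(138), index = 2),
                         tm135, config, 0.1)
  expect_true(r_138$validator$accepted)   # 135 + 3 inside the band
  expect_gt(r_138$score, 0)

  set.seed(26)
  flat <- list(pixels = matrix(4000 + rnorm(150 * 200, 0, 60), 150, 200),
               index = 1)
  expect_equal(analyze_fiber(smooth_roi(flat, 1), tm45, config, 0.1)$score, 0)
})
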