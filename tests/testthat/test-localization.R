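test_that("block corners are recovered within 2 px on an unperturbed phantom", {
  sim <- sim_noise_free()
  region <- segment_wax_block(sim$image, default_config())
  truth_corners <- attr(sim$truth, "block_corners_px")
  expect_lt(max(abs(region$corners_px - truth_corners)), 2)
  expect_equal(region$rotation_deg, 0, tolerance = 0.2)
  expect_lt(region$fit_residual, 0.02)
  expect_false(region$truncated)
})

test_that("rotation is estimated within 0.5 degrees at 5 degrees", {
  sim <- cached("rot5", generate_phantom(
    simulation_config(seed = 2, rotation_deg = 5)))
  region <- segment_wax_block(sim$image, default_config())
  expect_equal(region$rotation_deg, 5, tolerance = 0.5)
  truth_corners <- attr(sim$truth, "block_corners_px")
  expect_lt(max(abs(region$corners_px - truth_corners)), 3)
})

test_that("a 25 mm chest-wall overhang raises a catchable localization failure", {
  sim <- cached("over25", generate_phantom(
    simulation_config(seed = 3, overhang_mm = 25)))
  expect_error(segment_wax_block(sim$image, default_config()),
               class = "mammoqc_localization_failure")
})

test_that("18 ROIs are extracted and track a lateral shift", {
  rois <- rois_noise_free()
  expect_length(rois, 18)
  expect_setequal(names(rois), paste(rep(c("fiber", "speck_group", "mass"),
                                         each = 6), 1:6, sep = "_"))

  shifted <- cached("shift25", generate_phantom(
    noise_free(simulation_config(seed = 1, shift_mm = c(0, 25)))))
  srois <- extract_rois(shifted$image,
                        segment_wax_block(shifted$image, default_config()),
                        default_config())
  # equivariance: ROI content matches the unperturbed phantom
  for (key in c("fiber_1", "speck_group_3", "mass_6"))
    expect_lt(mean(abs(rois[[key]]$pixels - srois[[key]]$pixels)), 5)
  # each ROI contains its object's true centre
  for (ob in default_phantom_spec()$objects) {
    key <- paste(ob$kind, ob$index, sep = "_")
    b <- srois[[key]]$bounds
    tr <- shifted$truth[shifted$truth$kind == ob$kind &
                          shifted$truth$index == ob$index, ]
    region <- attr(srois, "region")
    # map truth centre into the ROI frame via the detected region
    dc <- tr$col_px - region$centre_px[["col"]]
    dr <- tr$row_px - region$centre_px[["row"]]
    th <- -region$rotation_deg * pi / 180
    x_mm <- (dc * cos(th) - dr * sin(th)) * 0.1 + 30   # block frame, mm
    y_mm <- (dc * sin(th) + dr * cos(th)) * 0.1 + 45
    expect_gt(x_mm, b$x0_mm); expect_lt(x_mm, b$x0_mm + b$w_mm)
    expect_gt(y_mm, b$y0_mm); expect_lt(y_mm, b$y0_mm + b$h_mm)
  }
})

test_that("ROI extraction on a rotated phantom matches the unperturbed content", {
  rois <- rois_noise_free()
  rot <- cached("rot5nf", generate_phantom(
    noise_free(simulation_config(seed = 1, rotation_deg = 5))))
  rrois <- extract_rois(rot$image,
                        segment_wax_block(rot$image, default_config()),
                        default_config())
  for (key in c("fiber_2", "speck_group_1", "mass_4"))
    expect_lt(mean(abs(rois[[key]]$pixels - rrois[[key]]$pixels)), 5)
})

test_that("extraction is deterministic and refuses truncated regions", {
  sim <- sim_noise_free()
  config <- default_config()
  region <- segment_wax_block(sim$image, config)
  r1 <- extract_rois(sim$image, region, config)
  r2 <- extract_rois(sim$image, region, config)
  expect_identical(r1, r2)
  region$truncated <- TRUE
  expect_error(extract_rois(sim$image, region, config),
               class = "mammoqc_localization_failure")
})

test_that("Gaussian ROI smoothing preserves mass and sigma 0 is the identity", {
  m <- matrix(rnorm(50 * 60), 50, 60)
  expect_identical(smooth_roi(m, 0), m)
  impulse <- matrix(0, 41, 41); impulse[21, 21] <- 1
  sm <- smooth_roi(impulse, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_error(smooth_roi(m, -1))
})

test_that("smoothing does not reduce validated specks on a noisy ROI", {
  sim <- cached("low11", generate_phantom(
    simulation_config(seed = 11, dose_mode = "low")))
  config <- default_config()
  rois <- extract_rois(sim$image, segment_wax_block(sim$image, config),
                       config)
  for (i in 2:4) {
    roi <- rois[[paste0("speck_group_", i)]]
    tm <- make_template("speck_group", i, config$spec, 0.1)
    n_smooth <- analyze_speck_group(smooth_roi(roi, 1), tm, config,
                                    0.1)$validator$n
    n_raw <- analyze_speck_group(roi, tm, config, 0.1)$validator$n
    expect_gte(n_smooth, n_raw)
  }
})
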