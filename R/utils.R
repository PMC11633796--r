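# Internal numeric helpers shared across modules.

# Bilinear interpolation of img at fractional 1-based (row, col) positions.
# Positions are clamped to the image borders.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00];      v10 <- img[i00 + 1]
  v01 <- img[i00 + nr]; v11 <- img[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Absolute angular difference on the 180-degree circle.
angle_diff_180 <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# Principal-axis orientation (degrees in [0, 180)) of a point set given as
# a 2-column (row, col) matrix, from second central moments; angle measured
# from +x (col) towards +y (row, downward).
points_orientation <- function(pts) {
  x <- pts[, 2] - mean(pts[, 2])
  y <- pts[, 1] - mean(pts[, 1])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
}

# Wrappers keeping EBImage's x-first layout out of the rest of the code:
# our matrices are [row, col].
eb_from_matrix <- function(m) EBImage::Image(t(m))
eb_to_matrix <- function(im) t(EBImage::imageData(im))

# Odd structuring-element size (px) for a physical diameter.
odd_px <- function(size_mm, spacing_mm) {
  k <- max(1L, round(size_mm / spacing_mm))
  if (k %% 2 == 0) k + 1L else k
}
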