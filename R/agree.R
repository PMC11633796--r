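# Agreement statistics between software and observer scores.

#' Intraclass correlation, two-way mixed effects, consistency, single rater
#'
#' ICC(3,1) from the two-way ANOVA decomposition of an n-subjects x
#' k-raters matrix:
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) * MS_error)`,
#' where `MS_rows` is the between-subject mean square and `MS_error` the
#' residual mean square of `score ~ subject + rater`. Consistency-type
#' agreement: a constant offset between raters does not reduce the value.
#'
#' @param m numeric matrix, subjects (images) in rows, raters in columns;
#'   no missing cells, at least 2 x 2.
#' @return the ICC(3,1) value (<= 1).
#' @export
icc_consistency <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m))) stop("ratings matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (stats::var(as.vector(m)) == 0)
    stop("zero total variance: ICC undefined")
  df <- data.frame(
    score = as.vector(m),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(score ~ subject + rater, data = df))[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  msr <- ms[["subject"]]
  mse <- ms[["Residuals"]]
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference between two raters and the mean +/- 1.96 SD limits
#' (sample SD, n-1 denominator). Antisymmetric under swapping `a` and `b`.
#'
#' @param a,b numeric score vectors of equal length >= 2.
#' @return list with `mean_diff`, `lower`, `upper`, `sd_diff` and the
#'   per-subject `differences` and `means` (for plotting).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 2) stop("need at least 2 paired scores")
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, lower = md - 1.96 * s, upper = md + 1.96 * s,
       sd_diff = s, differences = d, means = (a + b) / 2)
}

#' Agreement statistics from a long score table
#'
#' @param scores data frame with columns `image`, `rater`, `kind`, `score`
#'   (one row per image x rater x object kind).
#' @param software_rater rater name treated as the software column for the
#'   Bland-Altman comparison against the mean of the remaining raters;
#'   defaults to `"software"` when present, else the first rater.
#' @return named list per kind, each with `icc` and `bland_altman` (the
#'   software column vs the mean of the other raters), plus `n_images`.
#' @export
agreement_stats <- function(scores, software_rater = NULL) {
  stopifnot(all(c("image", "rater", "kind", "score") %in% names(scores)))
  out <- list()
  for (kind in unique(scores$kind)) {
    sk <- scores[scores$kind == kind, ]
    m <- tapply(sk$score, list(sk$image, sk$rater), mean)
    if (any(is.na(m))) stop("incomplete ratings for kind ", kind)
    sw <- software_rater %||%
      (if ("software" %in% colnames(m)) "software" else colnames(m)[1])
    others <- setdiff(colnames(m), sw)
    out[[kind]] <- list(
      icc = icc_consistency(m),
      bland_altman = bland_altman(m[, sw], rowMeans(m[, others, drop = FALSE])),
      n_images = nrow(m)
    )
  }
  out
}
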