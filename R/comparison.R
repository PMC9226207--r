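# ---- voxel-level comparison of disease patterns ---------------------------

as_weight_volume <- function(x) {
  if (inherits(x, "disease_pattern")) return(pattern_volume(x))
  if (inherits(x, "ssm_pca")) return(pattern_volume(x$pattern))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Pearson correlation between two disease patterns
#'
#' @param dpA,dpB 3D weight volumes, `disease_pattern`s or `ssm_pca` fits on
#'   a shared grid.
#' @param mask logical 3D array (>= 3 voxels).
#' @return Pearson correlation coefficient over mask voxels.
#' @export
pattern_correlation <- function(dpA, dpB, mask) {
  a <- as_weight_volume(dpA)[mask]
  b <- as_weight_volume(dpB)[mask]
  if (length(a) < 3) stop("need at least 3 mask voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' Joint histogram of two disease patterns
#'
#' Bins the paired voxel values of two patterns into an `n_bins x n_bins`
#' count matrix with equal-width bins spanning each pattern's range over the
#' mask. For display, counts are given on a base-10 logarithmic amplitude
#' scale with empty bins masked (NA).
#'
#' @param dp_x,dp_y 3D weight volumes (x is conventionally the metabolic
#'   pattern, y the perfusion-surrogate pattern).
#' @param mask logical 3D array.
#' @param n_bins number of bins per axis (>= 2).
#' @return A `joint_histogram`: list with `x_edges`, `y_edges`, `counts`,
#'   `log10_display`.
#' @export
joint_histogram <- function(dp_x, dp_y, mask, n_bins = 64) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  x <- as_weight_volume(dp_x)[mask]
  y <- as_weight_volume(dp_y)[mask]
  bin_of <- function(v) {
    edges <- seq(min(v), max(v), length.out = n_bins + 1)
    if (edges[1] == edges[n_bins + 1])
      edges <- edges + seq(-1e-9, 1e-9, length.out = n_bins + 1)
    i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    list(edges = edges, i = i)
  }
  bx <- bin_of(x)
  by <- bin_of(y)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(bx$i, levels = seq_len(n_bins)),
               factor(by$i, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  disp <- log10(counts)
  disp[counts == 0] <- NA_real_
  structure(list(x_edges = bx$edges, y_edges = by$edges, counts = counts,
                 log10_display = disp),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("Joint histogram: %d x %d bins, %d voxels, max bin count %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
plot.joint_histogram <- function(x, ...) {
  graphics::image(x = x$x_edges, y = x$y_edges, z = x$log10_display,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "pattern x weight", ylab = "pattern y weight", ...)
  invisible(x)
}

#' Voxelwise linear regression of one pattern on another
#'
#' Ordinary least squares of the dependent pattern's voxel values on the
#' independent pattern's (conventionally, perfusion-surrogate patterns are
#' regressed on the metabolic pattern). Voxels are treated as independent
#' observations; spatial autocorrelation is not corrected.
#'
#' @param dp_y dependent pattern.
#' @param dp_x independent pattern.
#' @param mask logical 3D array.
#' @return A `dp_regression`: list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
voxel_regression <- function(dp_y, dp_x, mask) {
  y <- as_weight_volume(dp_y)[mask]
  x <- as_weight_volume(dp_x)[mask]
  if (length(x) < 3) stop("need at least 3 mask voxels")
  if (stats::sd(x) == 0) stop("independent pattern has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "dp_regression")
}

#' @export
print.dp_regression <- function(x, ...) {
  cat(sprintf("OLS: slope %.3g, intercept %.3g, R^2 = %.3g, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
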