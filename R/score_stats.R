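# ---- subject-score statistics: ROC, ANOVA/Tukey, regression, agreement ----

roc_sweep <- function(scores, labels, positive = "AD") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  list(thresholds = thr, sensitivity = sens, specificity = spec)
}

trapezoid_auc <- function(sens, spec) {
  fpr <- 1 - spec
  o <- order(fpr, sens)
  x <- fpr[o]; y <- sens[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' ROC analysis with Youden threshold and bootstrap AUC confidence interval
#'
#' Builds the ROC curve for patient-vs-control scores with thresholds at
#' midpoints of adjacent distinct scores (plus infinite sentinels), computes
#' the trapezoidal area under the curve, finds the optimal classification
#' threshold by Youden's method (maximal sensitivity + specificity - 1, ties
#' resolved to the lowest threshold), and a 95% confidence interval for the
#' AUC by stratified percentile bootstrap (DeLong intervals available via
#' `ci_method`).
#'
#' @param scores numeric vector of expression scores (typically LOOCV
#'   Z-scores).
#' @param labels vector of class labels.
#' @param positive label of the patient class scoring higher (default "AD").
#' @param ci_method "bootstrap" (stratified percentile, default) or
#'   "delong".
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return An `roc_result`: thresholds, sensitivity, specificity, `auc`,
#'   `auc_ci`, `youden_threshold`, `youden_j`.
#' @export
roc_youden <- function(scores, labels, positive = "AD",
                       ci_method = c("bootstrap", "delong"),
                       n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present for ROC analysis")
  sw <- roc_sweep(scores, labels, positive)
  auc <- trapezoid_auc(sw$sensitivity, sw$specificity)
  j <- sw$sensitivity + sw$specificity - 1
  jmax <- max(j)
  youden_thr <- min(sw$thresholds[j >= jmax - 1e-12])
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  if (ci_method == "bootstrap") {
    aucs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      pb <- sample(pos, replace = TRUE)
      nb <- sample(neg, replace = TRUE)
      mw_auc(pb, nb)
    }, numeric(1)))
    ci <- unname(stats::quantile(aucs, c(0.025, 0.975), type = 7))
  } else {
    # DeLong structural components
    v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)),
                  numeric(1))
    v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)),
                  numeric(1))
    se <- sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  }
  structure(list(thresholds = sw$thresholds, sensitivity = sw$sensitivity,
                 specificity = sw$specificity, auc = auc,
                 auc_ci = ci, youden_threshold = youden_thr,
                 youden_j = jmax, ci_method = ci_method),
            class = "roc_result")
}

# Mann-Whitney AUC: concordant pairs plus half ties.
mw_auc <- function(pos, neg) {
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.2f-%.2f, %s), Youden threshold %.3g (J = %.2f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method,
              x$youden_threshold, x$youden_j))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' One-way ANOVA of scores across groups with Tukey correction
#'
#' Fixed-effects one-way ANOVA of expression scores across subject groups,
#' followed by Tukey honest-significant-difference pairwise comparisons via
#' the studentized range distribution. Pairwise rows report the mean
#' difference, its standard error, the Tukey-adjusted p and the unadjusted
#' pairwise p.
#'
#' @param scores numeric vector.
#' @param groups vector of group labels (>= 2 levels, >= 2 members each).
#' @return An `anova_tukey`: `f_stat`, `df`, `p_value`, `pairwise` data
#'   frame.
#' @export
anova_tukey <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs at least 2 members; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (all(tapply(scores, groups, stats::var) == 0))
    stop("zero within-group variance in every group: F is undefined")
  fit <- stats::aov(scores ~ groups)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  mse <- sm["Residuals", "Mean Sq"]
  dfr <- sm["Residuals", "Df"]
  # TukeyHSD rows follow combn(levels, 2), named "B-A" with diff = mean(B)-mean(A)
  pairs <- utils::combn(levels(groups), 2)
  stopifnot(ncol(pairs) == nrow(tk))
  se <- p_unadj <- numeric(nrow(tk))
  for (i in seq_len(nrow(tk))) {
    na <- sizes[pairs[2, i]]; nb <- sizes[pairs[1, i]]
    se[i] <- sqrt(mse * (1 / na + 1 / nb))
    p_unadj[i] <- 2 * stats::pt(-abs(tk[i, "diff"] / se[i]), dfr)
  }
  structure(list(f_stat = sm["groups", "F value"],
                 df = c(sm["groups", "Df"], dfr),
                 p_value = sm["groups", "Pr(>F)"],
                 pairwise = data.frame(
                   groupA = pairs[2, ],
                   groupB = pairs[1, ],
                   mean_diff = tk[, "diff"], se = se,
                   p_adjusted = tk[, "p adj"], p_unadjusted = p_unadj,
                   row.names = NULL)),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df[1], x$df[2], x$f_stat, x$p_value))
  pw <- x$pairwise
  pw$mean_diff <- sprintf("%.2f +/- %.2f", pw$mean_diff, pw$se)
  print(pw[, c("groupA", "groupB", "mean_diff", "p_adjusted")],
        row.names = FALSE)
  invisible(x)
}

#' Linear regression between two score sets
#'
#' Ordinary least squares of one method's subject scores on another's
#' (conventionally, perfusion-surrogate scores on metabolic scores), with
#' the Pearson correlation.
#'
#' @param y_scores dependent scores.
#' @param x_scores independent scores (same subjects, same order).
#' @return A `dp_regression` with an additional `pearson_r` element.
#' @export
score_regression <- function(y_scores, x_scores) {
  if (length(y_scores) != length(x_scores))
    stop("score vectors must be paired (equal length)")
  if (length(x_scores) < 3) stop("need at least 3 paired scores")
  if (stats::sd(x_scores) == 0) stop("independent scores are constant")
  fit <- stats::lm(y_scores ~ x_scores)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 pearson_r = stats::cor(x_scores, y_scores),
                 n = length(x_scores)),
            class = "dp_regression")
}

#' Bland-Altman agreement between two score sets
#'
#' Paired-difference analysis: mean difference (bias), limits of agreement
#' at mean +/- 1.96 x SD of the differences, the percentage of pairs inside
#' the limits, and a bias regression of the difference on the pair mean
#' (or, via `regress_on = "x"`, on the reference scores).
#'
#' @param y_scores,x_scores paired score vectors (length >= 3).
#' @param regress_on regressor for the bias fit: pair `"mean"` (default,
#'   standard practice) or the reference scores `"x"`.
#' @return A `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `bias_slope`, `bias_intercept`, `pct_within_loa`, `n`.
#' @export
bland_altman <- function(y_scores, x_scores, regress_on = c("mean", "x")) {
  regress_on <- match.arg(regress_on)
  if (length(y_scores) != length(x_scores))
    stop("score vectors must be paired (equal length)")
  if (length(x_scores) < 3) stop("need at least 3 pairs")
  d <- y_scores - x_scores
  m <- (y_scores + x_scores) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1.96, 1.96) * sdd
  reg_x <- if (regress_on == "mean") m else x_scores
  if (stats::sd(reg_x) == 0) {
    slope <- 0; intercept <- md
  } else {
    cf <- stats::coef(stats::lm(d ~ reg_x))
    slope <- unname(cf[2]); intercept <- unname(cf[1])
  }
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_low = loa[1], loa_high = loa[2],
                 bias_slope = slope, bias_intercept = intercept,
                 pct_within_loa = 100 * mean(d >= loa[1] & d <= loa[2]),
                 regress_on = regress_on, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g], %.1f%% within LoA\n",
              x$mean_diff, x$loa_low, x$loa_high, x$pct_within_loa))
  cat(sprintf("  bias regression on %s: slope %.3g, intercept %.3g\n",
              x$regress_on, x$bias_slope, x$bias_intercept))
  invisible(x)
}
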