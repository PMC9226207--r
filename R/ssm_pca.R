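# ---- scaled subprofile model / PCA disease patterns -----------------------

#' Build the centred voxels-by-subjects data matrix
#'
#' Restricts each subject image to the mask, optionally log-transforms,
#' centres each subject column by its own mean, computes the mean profile of
#' the healthy-control columns, and subtracts that profile from every
#' column. The per-subject offsets and the HC mean profile are stored so
#' that prospective subjects can be preprocessed identically.
#'
#' @param cohort a [pet_cohort()] (typically the AD + HC training subjects).
#' @param mask logical 3D array (defaults to the cohort mask).
#' @param log_transform apply `log()` before centering (classical scaled
#'   subprofile modelling; off by default for quantitative images).
#' @return An `ssm_data_matrix`: list with `values` (voxels x subjects,
#'   centred), `subject_id`, `group`, `mask`, `offsets`, `hc_profile`,
#'   `log_transform`.
#' @export
build_data_matrix <- function(cohort, mask = cohort$mask,
                              log_transform = FALSE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (!any(cohort$group == "HC"))
    stop("no HC subjects: cannot form the healthy-control mean profile")
  idx <- which(mask)
  X <- vapply(cohort$images, function(img) img[idx],
              numeric(length(idx)))
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)
    stop("non-finite values inside the mask at voxel index(es): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  }
  if (log_transform) {
    if (any(X <= 0))
      stop("log transform requires strictly positive masked values")
    X <- log(X)
  }
  offsets <- colMeans(X)
  X <- sweep(X, 2, offsets)
  hc_profile <- rowMeans(X[, cohort$group == "HC", drop = FALSE])
  X <- X - hc_profile
  structure(list(values = X, subject_id = cohort$subject_id,
                 group = cohort$group, mask = mask,
                 dim = dim(mask), voxel_size = cohort$voxel_size,
                 offsets = offsets, hc_profile = hc_profile,
                 log_transform = log_transform),
            class = "ssm_data_matrix")
}

# PCA of a voxels x subjects matrix via the subjects x subjects covariance
# (efficient for voxels >> subjects). Component signs are fixed so the
# largest-|loading| voxel of each component is positive.
pca_small <- function(X) {
  n <- ncol(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  keep <- eg$values > max(tol, 0)
  if (!any(keep))
    stop("degenerate decomposition: the data matrix has no variance ",
         "(identical images?)")
  lam <- eg$values[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  U <- X %*% V %*% diag(1 / sqrt(lam), nrow = length(lam))
  flip <- vapply(seq_len(ncol(U)),
                 function(j) sign(U[which.max(abs(U[, j])), j]),
                 numeric(1))
  U <- sweep(U, 2, flip, `*`)
  scores <- crossprod(X, U)          # subjects x PCs
  list(loadings = U, scores = scores,
       variance_fraction = lam / sum(eg$values))
}

# Ridge-penalized logistic regression (intercept unpenalized), used only
# when the unpenalized fit separates; AIC is computed from the unpenalized
# log-likelihood at the returned coefficients.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 200) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wd <- mu * (1 - mu)
    H <- crossprod(X1, X1 * Wd) + pen
    g <- crossprod(X1, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(beta)
}

logistic_loglik <- function(beta, X, y) {
  eta <- drop(cbind(1, X) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# One logistic fit on the given PC-score columns; returns coefficients and
# AIC (unpenalized log-likelihood even when the ridge fallback is used).
fit_logistic_safe <- function(S, y, ridge_lambda = 1e-3) {
  df <- data.frame(y = y, S)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || !fit$converged) {
    beta <- ridge_logistic(as.matrix(S), y, lambda = ridge_lambda)
    ll <- logistic_loglik(beta, as.matrix(S), y)
    list(beta = beta, aic = -2 * ll + 2 * length(beta), separated = TRUE)
  } else {
    list(beta = unname(stats::coef(fit)), aic = stats::AIC(fit),
         separated = FALSE)
  }
}

# Stepwise forward selection over candidate PC columns by strictly
# decreasing AIC; ties broken by lower PC index (first candidate wins).
stepwise_logistic_aic <- function(scores, y, ridge_lambda = 1e-3) {
  k <- ncol(scores)
  null_dev <- -2 * sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  current <- integer(0)
  current_aic <- null_dev + 2        # intercept-only AIC
  current_fit <- NULL
  any_separated <- FALSE
  repeat {
    cand <- setdiff(seq_len(k), current)
    if (!length(cand)) break
    best <- NULL
    for (j in cand) {
      set <- c(current, j)
      f <- fit_logistic_safe(scores[, set, drop = FALSE], y, ridge_lambda)
      if (is.null(best) || f$aic < best$aic - 1e-12)
        best <- c(f, list(set = set))
    }
    if (best$aic < current_aic - 1e-12) {
      current <- best$set
      current_aic <- best$aic
      current_fit <- best
      any_separated <- any_separated || best$separated
    } else break
  }
  if (!length(current))
    stop("stepwise selection is empty: no principal component lowered the AIC")
  list(included = current, beta = current_fit$beta, aic = current_aic,
       separated = any_separated)
}

#' Derive a disease pattern from a centred data matrix
#'
#' Runs PCA on the centred voxels-by-subjects matrix (via the
#' subjects-by-subjects covariance), selects the minimal prefix of
#' variance-ordered components whose cumulative explained variance reaches
#' `variance_target`, performs stepwise-forward logistic regression of group
#' (patient vs control) on the selected components' subject scores with
#' strictly-decreasing AIC acceptance, and combines the retained components,
#' weighted by their logistic coefficients, into a unit-norm voxel-weight
#' pattern whose sign is fixed so patients express it positively.
#'
#' @param dm an [build_data_matrix()] result.
#' @param variance_target cumulative variance fraction for the candidate PC
#'   pool (default 0.5).
#' @param ridge_lambda ridge penalty used only if the logistic fit separates.
#' @return A `disease_pattern`: voxel weights plus the PCs, coefficients and
#'   variance bookkeeping that produced it.
#' @export
derive_pattern <- function(dm, variance_target = 0.5, ridge_lambda = 1e-3) {
  stopifnot(inherits(dm, "ssm_data_matrix"))
  if (!all(dm$group %in% c("AD", "HC")))
    stop("pattern derivation expects AD and HC subjects only")
  if (sum(dm$group == "AD") < 2 || sum(dm$group == "HC") < 2)
    stop("need at least 2 subjects per class")
  pc <- pca_small(dm$values)
  cum <- cumsum(pc$variance_fraction)
  k <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  y <- as.integer(dm$group == "AD")
  sel <- stepwise_logistic_aic(pc$scores[, seq_len(k), drop = FALSE], y,
                               ridge_lambda)
  w <- pc$loadings[, sel$included, drop = FALSE] %*% sel$beta[-1]
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("null pattern: logistic coefficients are all zero")
  w <- drop(w) / nrm
  raw <- drop(crossprod(dm$values, w))
  if (mean(raw[dm$group == "AD"]) < mean(raw[dm$group == "HC"])) {
    w <- -w
    raw <- -raw
  }
  structure(list(weights = w, mask = dm$mask, dim = dm$dim,
                 voxel_size = dm$voxel_size,
                 included_pcs = sort(sel$included),
                 logistic_coefficients = stats::setNames(
                   sel$beta, c("(Intercept)", paste0("PC", sel$included))),
                 candidate_pcs = seq_len(k),
                 variance_fraction = pc$variance_fraction,
                 dp_variance_explained = 100 * sum(pc$variance_fraction[sel$included]),
                 separation_handled = sel$separated,
                 hc_profile = dm$hc_profile,
                 log_transform = dm$log_transform,
                 training_ids = dm$subject_id, training_groups = dm$group,
                 insample_raw = raw,
                 pc_loadings = pc$loadings[, seq_len(k), drop = FALSE],
                 pc_scores = pc$scores[, seq_len(k), drop = FALSE]),
            class = "disease_pattern")
}

#' @export
print.disease_pattern <- function(x, ...) {
  cat(sprintf("Disease pattern: %d mask voxels; PCs in DP: %s; ",
              length(x$weights),
              paste(x$included_pcs, collapse = ", ")),
      sprintf("variance explained by DP %.1f%%\n", x$dp_variance_explained))
  invisible(x)
}

#' Pattern weights as a 3D volume
#'
#' @param pattern a `disease_pattern`.
#' @return 3D array of voxel weights, zero outside the mask.
#' @export
pattern_volume <- function(pattern) {
  stopifnot(inherits(pattern, "disease_pattern"))
  a <- array(0, dim = pattern$dim)
  a[pattern$mask] <- pattern$weights
  attr(a, "voxel_size") <- pattern$voxel_size
  a
}

#' Score a subject image against a disease pattern
#'
#' The image is masked, centred by its own mask mean, the training HC mean
#' profile is subtracted, and the inner product with the pattern's voxel
#' weights is returned.
#'
#' @param image 3D array on the training grid.
#' @param pattern a `disease_pattern`.
#' @return Raw pattern-expression score (scalar).
#' @export
score_subject <- function(image, pattern) {
  stopifnot(inherits(pattern, "disease_pattern"))
  if (!identical(dim(image), pattern$dim))
    stop("image grid does not match the pattern's training grid")
  v <- image[pattern$mask]
  if (pattern$log_transform) {
    if (any(v <= 0)) stop("log transform requires positive masked values")
    v <- log(v)
  }
  v <- v - mean(v) - pattern$hc_profile
  sum(v * pattern$weights)
}

#' Leave-one-out cross-validated pattern scores
#'
#' For each training subject, a new pattern is derived from the remaining
#' subjects and the left-out subject is scored against it. Fold patterns are
#' compared with the full-cohort pattern by cosine similarity as a stability
#' report.
#'
#' @param cohort a [pet_cohort()] restricted to AD and HC subjects.
#' @param mask logical 3D array.
#' @param variance_target cumulative variance fraction (see
#'   [derive_pattern()]).
#' @param full_pattern optional full-cohort `disease_pattern` for the
#'   stability report (derived internally if omitted).
#' @param log_transform see [build_data_matrix()].
#' @return List with `scores` (data frame: subject_id, group, raw_score) and
#'   `stability` (data frame: subject_id, cosine of fold pattern vs full
#'   pattern).
#' @export
loocv_scores <- function(cohort, mask = cohort$mask, variance_target = 0.5,
                         full_pattern = NULL, log_transform = FALSE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  n <- length(cohort$images)
  if (is.null(full_pattern))
    full_pattern <- derive_pattern(build_data_matrix(cohort, mask,
                                                     log_transform),
                                   variance_target)
  raw <- cosine <- numeric(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    gk <- cohort$group[keep]
    if (sum(gk == "AD") < 2 || sum(gk == "HC") < 2)
      stop("leave-one-out fold retains fewer than 2 subjects of a class")
    sub <- pet_cohort(cohort$images[keep], cohort$subject_id[keep], gk,
                      mask, cohort$voxel_size)
    pat_i <- derive_pattern(build_data_matrix(sub, mask, log_transform),
                            variance_target)
    raw[i] <- score_subject(cohort$images[[i]], pat_i)
    cosine[i] <- sum(pat_i$weights * full_pattern$weights)
  }
  list(scores = data.frame(subject_id = cohort$subject_id,
                           group = cohort$group, raw_score = raw),
       stability = data.frame(subject_id = cohort$subject_id,
                              cosine = cosine))
}

#' Z-standardize pattern-expression scores
#'
#' Standardizes raw scores by the mean and standard deviation of the
#' healthy-control leave-one-out scores, so that the HC LOOCV scores have
#' mean 0 and SD 1 by construction.
#'
#' @param raw_scores numeric vector of raw scores.
#' @param hc_loocv_scores numeric vector of HC leave-one-out raw scores
#'   (length >= 2, nonzero SD).
#' @return Numeric vector of Z-scores.
#' @export
zscore_standardize <- function(raw_scores, hc_loocv_scores) {
  if (length(hc_loocv_scores) < 2)
    stop("need at least 2 HC leave-one-out scores to standardize")
  s <- stats::sd(hc_loocv_scores)
  if (s == 0) stop("HC leave-one-out scores have zero standard deviation")
  (raw_scores - mean(hc_loocv_scores)) / s
}

#' Regional summary of a disease pattern
#'
#' Mean and standard deviation of the pattern's voxel weights per atlas
#' region and per combined lobe, with volumes in cubic centimetres.
#' Regions with no voxels inside the mask are reported with zero volume and
#' missing statistics rather than dropped.
#'
#' @param pattern a `disease_pattern`.
#' @param atlas an [atlas_definition()] on the pattern grid.
#' @return Data frame with columns `level` ("region" or "lobe"), `name`,
#'   `lobe`, `n_voxels`, `volume_cm3`, `mean`, `sd`.
#' @export
regional_summary <- function(pattern, atlas) {
  stopifnot(inherits(pattern, "disease_pattern"), inherits(atlas, "atlas_def"))
  if (!identical(dim(atlas$labels), pattern$dim))
    stop("atlas grid does not match pattern grid")
  vol <- pattern_volume(pattern)
  vox_cm3 <- prod(atlas$voxel_size) / 1000
  lab_in <- atlas$labels
  lab_in[!pattern$mask] <- 0L
  row_for <- function(level, name, lobe, vals) {
    data.frame(level = level, name = name, lobe = lobe,
               n_voxels = length(vals),
               volume_cm3 = length(vals) * vox_cm3,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else
                 if (length(vals) == 1) 0 else NA_real_)
  }
  rows <- list()
  for (lab in names(atlas$region_names)) {
    nm <- atlas$region_names[[lab]]
    vals <- vol[lab_in == as.integer(lab)]
    rows[[length(rows) + 1L]] <- row_for("region", nm, atlas$lobe_map[[nm]],
                                         vals)
  }
  for (lb in unique(unname(atlas$lobe_map))) {
    members <- names(atlas$lobe_map)[atlas$lobe_map == lb]
    labs <- names(atlas$region_names)[atlas$region_names %in% members]
    vals <- vol[lab_in %in% as.integer(labs)]
    rows[[length(rows) + 1L]] <- row_for("lobe", lb, lb, vals)
  }
  do.call(rbind, rows)
}

# ---- the model-fitting front end ------------------------------------------

#' Fit a scaled-subprofile-model disease pattern
#'
#' The main fitting function of the package. Takes a cohort of spatially
#' aligned images with group labels, derives the disease-specific covariance
#' pattern from the AD and HC subjects (PCA on the doubly centred data
#' matrix, >= `variance_target` cumulative-variance component pool,
#' stepwise-AIC logistic combination), computes leave-one-out
#' cross-validated scores for the training subjects and prospective scores
#' for all other subjects, and Z-standardizes every score by the mean and SD
#' of the HC leave-one-out scores.
#'
#' @param cohort a [pet_cohort()]; AD and HC subjects form the training set,
#'   any MCI+/MCI- subjects are scored prospectively.
#' @param mask logical 3D array (defaults to the cohort mask).
#' @param variance_target cumulative variance fraction defining the
#'   candidate component pool (default 0.5).
#' @param log_transform apply the classical log transform before centering.
#' @param loocv compute leave-one-out scores (required for Z-standardized
#'   scores; default TRUE).
#' @return An object of class `ssm_pca`: list with `pattern` (the
#'   `disease_pattern`), `scores` (data frame: subject_id, group, raw_score,
#'   z_score, loocv), `stability`, `hc_score_mean`, `hc_score_sd`, `call`.
#' @seealso [predict.ssm_pca()], [regional_summary()], [pattern_volume()]
#' @examples
#' ph <- make_phantom_atlas(c(12, 12, 12), 5, seed = 2)
#' tm <- make_pattern_template(ph$atlas, c(parietal = -1, temporal = -0.5),
#'                             ph$mask, smoothing_fwhm = 10)
#' bl <- make_phantom_baseline(ph$atlas, ph$mask, seed = 2)
#' cfg <- sim_config(n_AD = 6, n_HC = 6, n_MCIplus = 0, n_MCIminus = 0,
#'                   noise_sd = 0.01, seed = 3)
#' sim <- simulate_static_cohort(tm, bl, cfg, ph$mask)
#' fit <- ssm_pca(sim$cohort)
#' summary(fit)
#' @export
ssm_pca <- function(cohort, mask = cohort$mask, variance_target = 0.5,
                    log_transform = FALSE, loocv = TRUE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  train <- which(cohort$group %in% c("AD", "HC"))
  if (sum(cohort$group == "AD") < 2 || sum(cohort$group == "HC") < 2)
    stop("need at least 2 AD and 2 HC subjects to derive a pattern")
  trn <- pet_cohort(cohort$images[train], cohort$subject_id[train],
                    cohort$group[train], mask, cohort$voxel_size)
  dm <- build_data_matrix(trn, mask, log_transform)
  pattern <- derive_pattern(dm, variance_target)
  raw <- vapply(cohort$images, score_subject, numeric(1), pattern = pattern)
  is_loocv <- rep(FALSE, length(raw))
  stability <- NULL
  hc_mean <- hc_sd <- NA_real_
  z <- rep(NA_real_, length(raw))
  if (loocv) {
    lo <- loocv_scores(trn, mask, variance_target, full_pattern = pattern,
                       log_transform = log_transform)
    raw[train] <- lo$scores$raw_score
    is_loocv[train] <- TRUE
    stability <- lo$stability
    hc_raw <- lo$scores$raw_score[lo$scores$group == "HC"]
    hc_mean <- mean(hc_raw)
    hc_sd <- stats::sd(hc_raw)
    z <- zscore_standardize(raw, hc_raw)
    pattern$training_hc_score_mean <- hc_mean
    pattern$training_hc_score_sd <- hc_sd
  }
  structure(list(pattern = pattern,
                 scores = data.frame(subject_id = cohort$subject_id,
                                     group = cohort$group,
                                     raw_score = raw, z_score = z,
                                     loocv = is_loocv),
                 stability = stability,
                 hc_score_mean = hc_mean, hc_score_sd = hc_sd,
                 variance_target = variance_target,
                 log_transform = log_transform,
                 call = match.call()),
            class = "ssm_pca")
}

#' @export
print.ssm_pca <- function(x, ...) {
  cat("Scaled subprofile model / PCA disease pattern\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  print(x$pattern)
  tab <- table(x$scores$group)
  cat(sprintf("Scored %d subjects (%s)\n", nrow(x$scores),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.ssm_pca <- function(object, ...) {
  sc <- object$scores
  gs <- do.call(rbind, lapply(split(sc$z_score, sc$group), function(v) {
    data.frame(n = length(v), mean_z = mean(v), sd_z = stats::sd(v))
  }))
  out <- list(pattern = object$pattern,
              group_scores = gs,
              stability = if (!is.null(object$stability))
                summary(object$stability$cosine),
              hc_score_mean = object$hc_score_mean,
              hc_score_sd = object$hc_score_sd)
  class(out) <- "summary.ssm_pca"
  out
}

#' @export
print.summary.ssm_pca <- function(x, ...) {
  print(x$pattern)
  cat(sprintf("Included PC coefficients: %s\n",
              paste(sprintf("%s = %.3g",
                            names(x$pattern$logistic_coefficients),
                            x$pattern$logistic_coefficients),
                    collapse = ", ")))
  cat("Z-scores by group:\n")
  print(round(x$group_scores, 3))
  if (!is.null(x$stability)) {
    cat("LOOCV fold-pattern cosine with full pattern:\n")
    print(x$stability)
  }
  invisible(x)
}

#' @export
coef.ssm_pca <- function(object, ...) object$pattern$logistic_coefficients

#' @export
fitted.ssm_pca <- function(object, ...) object$scores$z_score

#' Score new images against a fitted pattern
#'
#' @param object an `ssm_pca` fit.
#' @param newdata a 3D array, a list of 3D arrays, or a [pet_cohort()] on
#'   the training grid; if omitted, the training-cohort scores are returned.
#' @param ... unused.
#' @return Data frame with `raw_score` and `z_score` per image.
#' @export
predict.ssm_pca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  imgs <- if (inherits(newdata, "pet_cohort")) newdata$images
  else if (is.list(newdata)) newdata else list(newdata)
  raw <- vapply(imgs, score_subject, numeric(1), pattern = object$pattern)
  data.frame(raw_score = raw,
             z_score = if (is.finite(object$hc_score_sd))
               (raw - object$hc_score_mean) / object$hc_score_sd
             else NA_real_)
}

#' Plot a fitted disease pattern
#'
#' Displays axial slices of the pattern's voxel weights (blue negative, red
#' positive) using base graphics.
#'
#' @param x an `ssm_pca` fit or a `disease_pattern`.
#' @param slices axial slice indices (default: three central slices).
#' @param ... passed to [graphics::image()].
#' @export
plot.ssm_pca <- function(x, slices = NULL, ...) {
  plot(x$pattern, slices = slices, ...)
}

#' @export
plot.disease_pattern <- function(x, slices = NULL, ...) {
  vol <- pattern_volume(x)
  nz <- dim(vol)[3]
  if (is.null(slices))
    slices <- unique(pmax(1, pmin(nz, round(nz * c(0.35, 0.5, 0.65)))))
  m <- max(abs(vol))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(65)
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (s in slices)
    graphics::image(vol[, , s], zlim = c(-m, m), col = pal, axes = FALSE,
                    main = paste("slice", s), ...)
  invisible(x)
}
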