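# ---- reference-tissue kinetics: SRTM/SRTM2, ePIB, SUVR --------------------

# Convolution C_R (x) exp(-theta t) on the 1 s grid, exact for a
# piecewise-linear C_R, via the exponential's recursive update. The integral
# is returned in value*minutes so that products with 1/min rate constants
# are dimensionally consistent.
exp_conv <- function(ref_values, theta_per_min) {
  th <- theta_per_min / 60         # per second
  n <- length(ref_values)
  if (th <= 0) stop("theta must be positive")
  E <- exp(-th)
  a <- ref_values[-n]
  b <- ref_values[-1]
  inc <- a * (1 - E) / th + (b - a) * (th - (1 - E)) / th^2
  c(0, stats::filter(inc, E, method = "recursive", init = 0)) / 60
}

#' Time-average a 1 s-grid signal over each frame interval
#'
#' Averages a finely sampled signal (values at t = 0, 1, 2, ... seconds)
#' over every frame of a schedule via the cumulative trapezoidal integral.
#'
#' @param fine_values numeric vector sampled at 1 s starting at t = 0.
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame averages.
#' @export
frame_average <- function(fine_values, schedule) {
  n <- length(fine_values)
  cumint <- c(0, cumsum((fine_values[-1] + fine_values[-n]) / 2))
  tgrid <- seq_len(n) - 1
  ci <- function(t) stats::approx(tgrid, cumint, xout = t, rule = 2)$y
  (ci(schedule$end_s) - ci(schedule$start_s)) / (schedule$end_s - schedule$start_s)
}

#' Simplified reference tissue model forward solution
#'
#' Computes the frame-averaged tissue time-activity curve
#' `C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * [C_R (x) exp(-k2a t)](t)`
#' with `k2a = k2 / (1 + BPND)`. The convolution is evaluated on the 1 s
#' grid of the reference curve; frame values are time-averages over each
#' frame interval.
#'
#' @param ref a `reference_curve` (see [simulate_reference_curve()]).
#' @param schedule a [frame_schedule()] within the curve duration.
#' @param R1 relative delivery (unitless).
#' @param k2 tissue efflux rate, 1/min.
#' @param bpnd non-displaceable binding potential (unitless).
#' @return Numeric vector of frame-averaged activities.
#' @export
srtm_forward <- function(ref, schedule, R1, k2, bpnd = 0) {
  stopifnot(inherits(ref, "reference_curve"), inherits(schedule, "frame_schedule"))
  if (max(schedule$end_s) > max(ref$t))
    stop("schedule extends beyond the reference curve")
  k2a <- k2 / (1 + bpnd)
  if (k2a <= 0) stop("apparent efflux rate k2a must be positive")
  fine <- R1 * ref$values + (k2 - R1 * k2a) * exp_conv(ref$values, k2a)
  frame_average(fine, schedule)
}

#' Basis grid of apparent-efflux decay constants
#'
#' Logarithmically spaced constants over `[k2a_min, k2a_max]` (1/min), with
#' precomputed frame-averaged basis curves `C_R (x) exp(-theta t)`.
#'
#' @param ref a `reference_curve`.
#' @param schedule a [frame_schedule()].
#' @param k2a_min,k2a_max grid bounds, 1/min.
#' @param n_basis number of basis functions.
#' @return List with `thetas` (1/min), `basis` (frames x n_basis matrix),
#'   and `ref_frames` (frame-averaged reference curve).
#' @export
basis_grid <- function(ref, schedule, k2a_min = 0.01, k2a_max = 0.3,
                       n_basis = 80) {
  stopifnot(k2a_min > 0, k2a_max > k2a_min, n_basis >= 2)
  thetas <- exp(seq(log(k2a_min), log(k2a_max), length.out = n_basis))
  basis <- vapply(thetas,
                  function(th) frame_average(exp_conv(ref$values, th), schedule),
                  numeric(nrow(schedule)))
  list(thetas = thetas, basis = basis,
       ref_frames = frame_average(ref$values, schedule))
}

#' Fit the three-parameter SRTM to a single time-activity curve
#'
#' For each decay constant theta on the grid, solves the frame-duration
#' weighted linear least squares
#' `C_T = R1 * C_R + phi * [C_R (x) exp(-theta t)]` and keeps the theta with
#' the smallest residual sum of squares; then `k2 = phi + R1 * theta`,
#' `BPND = k2 / theta - 1`, `k2' = k2 / R1`.
#'
#' @param tac numeric vector of frame activities.
#' @param ref a `reference_curve`.
#' @param schedule a [frame_schedule()].
#' @param grid a [basis_grid()] (defaults to 80 log-spaced constants over
#'   `[0.005, 0.6]` 1/min, the parametric-map grid widened by x0.5 / x2).
#' @return List with `R1`, `k2`, `k2a`, `bpnd`, `k2_prime`, `rss`, `valid`.
#' @export
fit_srtm <- function(tac, ref, schedule, grid = NULL) {
  if (is.null(grid))
    grid <- basis_grid(ref, schedule, 0.005, 0.6, 80)
  if (!all(is.finite(tac))) stop("tac contains non-finite values")
  if (all(tac == 0))
    return(list(R1 = NA_real_, k2 = NA_real_, k2a = NA_real_,
                bpnd = NA_real_, k2_prime = NA_real_, rss = NA_real_,
                valid = FALSE))
  w <- frame_durations(schedule)
  sw <- sqrt(w)
  yw <- tac * sw
  crw <- grid$ref_frames * sw
  best <- list(rss = Inf)
  for (j in seq_along(grid$thetas)) {
    bw <- grid$basis[, j] * sw
    X <- cbind(crw, bw)
    cf <- tryCatch(qr.solve(X, yw), error = function(e) NULL)
    if (is.null(cf)) next
    rss <- sum((yw - X %*% cf)^2)
    if (rss < best$rss)
      best <- list(rss = rss, theta = grid$thetas[j], R1 = cf[1], phi = cf[2])
  }
  if (!is.finite(best$rss)) stop("SRTM fit failed on all basis functions")
  k2 <- best$phi + best$R1 * best$theta
  list(R1 = unname(best$R1), k2 = unname(k2), k2a = best$theta,
       bpnd = unname(k2 / best$theta - 1),
       k2_prime = unname(k2 / best$R1), rss = best$rss, valid = TRUE)
}

# Reconstruct a 1 s-grid curve from frame-averaged values: linear
# interpolation through (0, 0) and frame midpoints, then a few multiplicative
# corrections so that the fine curve's frame averages match the input.
ref_fine_from_frames <- function(tac, schedule, n_iter = 6) {
  dur <- max(schedule$end_s)
  sch_mid <- frame_midpoints(schedule)
  fine <- stats::approx(c(0, sch_mid, dur), c(0, tac, tac[length(tac)]),
                        xout = seq(0, dur, 1), rule = 2)$y
  for (it in seq_len(n_iter)) {
    cur <- frame_average(fine, schedule)
    fac <- ifelse(abs(cur) > 1e-12, tac / cur, 1)
    ffac <- stats::approx(c(0, sch_mid, dur), c(fac[1], fac, fac[length(fac)]),
                          xout = seq(0, dur, 1), rule = 2)$y
    fine <- fine * ffac
  }
  structure(list(t = seq(0, dur, 1), values = fine, params = list()),
            class = "reference_curve")
}

#' Voxelwise SRTM2 R1 parametric mapping
#'
#' Implements the two-stage parametric-map recipe: (1) the reference
#' time-activity curve is the mean over reference-mask voxels; (2) a
#' three-parameter SRTM fit per masked voxel estimates binding potential;
#' (3) the reference efflux rate `k2'` is fixed at the median of `k2 / R1`
#' over voxels with `BPND` above `bp_threshold`; (4) a two-parameter SRTM2
#' refit per voxel, `C_T = R1 * [C_R + (k2' - k2a) * (C_R (x) exp(-k2a t))]`,
#' with `k2a` restricted to `n_basis` log-spaced values in
#' `[k2a_min, k2a_max]`, yields the final R1 map.
#'
#' @param dyn a [dynamic_image()].
#' @param mask logical 3D array of voxels to fit.
#' @param ref_mask logical 3D array of reference (cerebellar grey) voxels.
#' @param bp_threshold binding-potential threshold for the `k2'` median.
#' @param k2a_min,k2a_max apparent-efflux grid bounds, 1/min.
#' @param n_basis number of basis functions.
#' @return A `parametric_map`: list with 3D arrays `R1`, `k2a`, `bpnd`
#'   (defined on `fit_mask`), `fit_mask`, scalar `k2_prime_fixed`, and
#'   `settings`.
#' @export
fit_srtm2_voxelwise <- function(dyn, mask, ref_mask, bp_threshold = 0.05,
                                k2a_min = 0.01, k2a_max = 0.3, n_basis = 80) {
  stopifnot(inherits(dyn, "dynamic_image"))
  if (!any(ref_mask)) stop("reference mask is empty")
  if (!any(mask)) stop("fit mask is empty")
  sch <- dyn$schedule
  nf <- nrow(sch)
  flat <- matrix(dyn$data, ncol = nf)
  Y <- t(flat[which(mask), , drop = FALSE])          # frames x voxels
  ref_tac <- colMeans(flat[which(ref_mask), , drop = FALSE])
  ref <- ref_fine_from_frames(ref_tac, sch)

  w <- frame_durations(sch)
  sw <- sqrt(w)
  Yw <- Y * sw

  # stage 1: SRTM per voxel on a widened grid
  g1 <- basis_grid(ref, sch, k2a_min / 2, k2a_max * 2, n_basis)
  crw <- g1$ref_frames * sw
  nv <- ncol(Y)
  yy <- colSums(Yw^2)
  srtm_ls <- function(bw) {
    # closed-form 2x2 weighted normal equations, shared design across voxels
    a11 <- sum(crw^2); a12 <- sum(crw * bw); a22 <- sum(bw^2)
    det <- a11 * a22 - a12^2
    if (det <= .Machine$double.eps * a11 * a22) return(NULL)
    b1 <- crossprod(crw, Yw)[1, ]
    b2 <- crossprod(bw, Yw)[1, ]
    R1j <- (a22 * b1 - a12 * b2) / det
    phij <- (a11 * b2 - a12 * b1) / det
    list(R1 = R1j, phi = phij, rss = yy - (R1j * b1 + phij * b2))
  }
  rss_mat <- matrix(Inf, n_basis, nv)
  R1_mat <- phi_mat <- matrix(NA_real_, n_basis, nv)
  for (j in seq_along(g1$thetas)) {
    ls <- srtm_ls(g1$basis[, j] * sw)
    if (is.null(ls)) next
    rss_mat[j, ] <- ls$rss
    R1_mat[j, ] <- ls$R1
    phi_mat[j, ] <- ls$phi
  }
  jbest <- max.col(-t(rss_mat), ties.method = "first")
  pick <- cbind(jbest, seq_len(nv))
  best_th <- g1$thetas[jbest]
  best_R1 <- R1_mat[pick]
  best_phi <- phi_mat[pick]
  # sub-grid refinement: log-parabolic interpolation of RSS(theta) at the
  # grid minimum, then one exact refit at the refined theta per voxel
  h <- diff(log(g1$thetas[1:2]))
  interior <- jbest > 1 & jbest < n_basis
  if (any(interior)) {
    jm <- jbest[interior]
    r0 <- rss_mat[cbind(jm, which(interior))]
    rm <- rss_mat[cbind(jm - 1L, which(interior))]
    rp <- rss_mat[cbind(jm + 1L, which(interior))]
    curv <- rp - 2 * r0 + rm
    delta <- ifelse(is.finite(curv) & curv > 0,
                    pmin(0.5, pmax(-0.5, 0.5 * (rm - rp) / curv)), 0)
    th_ref <- exp(log(g1$thetas[jm]) + delta * h)
    for (u in unique(th_ref[delta != 0])) {
      vsel <- which(interior)[th_ref == u]
      bw <- frame_average(exp_conv(ref$values, u), sch) * sw
      ls <- srtm_ls(bw)
      if (is.null(ls)) next
      better <- ls$rss[vsel] < rss_mat[cbind(jbest[vsel], vsel)]
      vsel <- vsel[better]
      if (!length(vsel)) next
      best_th[vsel] <- u
      best_R1[vsel] <- ls$R1[vsel]
      best_phi[vsel] <- ls$phi[vsel]
    }
  }
  k2_1 <- best_phi + best_R1 * best_th
  bp_1 <- k2_1 / best_th - 1
  sel <- is.finite(bp_1) & bp_1 > bp_threshold & is.finite(best_R1) &
    best_R1 > 0
  if (!any(sel))
    stop(sprintf("no voxel has BPND above the threshold %.3g; cannot fix k2'",
                 bp_threshold))
  k2p <- stats::median(k2_1[sel] / best_R1[sel])

  # stage 2: SRTM2 with k2' fixed, one linear parameter per voxel
  g2 <- basis_grid(ref, sch, k2a_min, k2a_max, n_basis)
  best_rss2 <- rep(Inf, nv)
  best_R12 <- best_th2 <- rep(NA_real_, nv)
  for (j in seq_along(g2$thetas)) {
    xw <- (g2$ref_frames + (k2p - g2$thetas[j]) * g2$basis[, j]) * sw
    xx <- sum(xw^2)
    if (xx <= 0) next
    xy <- crossprod(xw, Yw)[1, ]
    R1j <- xy / xx
    rss <- yy - R1j * xy
    upd <- rss < best_rss2
    best_rss2[upd] <- rss[upd]
    best_R12[upd] <- R1j[upd]
    best_th2[upd] <- g2$thetas[j]
  }
  to_vol <- function(v) {
    a <- array(NA_real_, dim = dim(mask)); a[mask] <- v; a
  }
  structure(list(R1 = to_vol(best_R12), k2a = to_vol(best_th2),
                 bpnd = to_vol(best_R12 * k2p / best_th2 - 1),
                 fit_mask = mask, k2_prime_fixed = k2p,
                 settings = list(bp_threshold = bp_threshold,
                                 k2a_min = k2a_min, k2a_max = k2a_max,
                                 n_basis = n_basis)),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("SRTM2 parametric map: %d voxels, k2' fixed at %.4g 1/min\n",
              sum(x$fit_mask), x$k2_prime_fixed))
  cat(sprintf("  R1 median %.3g [%.3g, %.3g]\n",
              stats::median(x$R1[x$fit_mask]),
              min(x$R1[x$fit_mask]), max(x$R1[x$fit_mask])))
  invisible(x)
}

#' Early-frame SUVR window presets
#'
#' @param name one of `"20-130s"` (default in the parametric pipeline),
#'   `"20-120s"`, `"1-8min"`.
#' @return numeric length-2, window in seconds.
#' @export
epib_window <- function(name = c("20-130s", "20-120s", "1-8min")) {
  switch(match.arg(name),
         "20-130s" = c(20, 130),
         "20-120s" = c(20, 120),
         "1-8min" = c(60, 480))
}

#' Early-frame pseudo-perfusion SUVR image (ePIB)
#'
#' Duration-weighted average of the frames overlapping a time window, with
#' each frame weighted by its overlap duration with the (closed) window,
#' normalized by the same quantity averaged over the reference mask.
#'
#' @param dyn a [dynamic_image()].
#' @param window numeric length-2 `(t0_s, t1_s)` or a preset name for
#'   [epib_window()].
#' @param ref_mask logical 3D reference mask.
#' @return 3D SUVR array.
#' @export
compute_epib <- function(dyn, window = "20-130s", ref_mask) {
  stopifnot(inherits(dyn, "dynamic_image"))
  if (is.character(window)) window <- epib_window(window)
  stopifnot(length(window) == 2, window[2] > window[1])
  sch <- dyn$schedule
  wts <- pmax(0, pmin(sch$end_s, window[2]) - pmax(sch$start_s, window[1]))
  if (sum(wts) == 0)
    stop("window has zero overlap with the frame schedule")
  nf <- nrow(sch)
  flat <- matrix(dyn$data, ncol = nf)
  wavg <- as.numeric(flat %*% wts) / sum(wts)
  ref_val <- mean(wavg[which(ref_mask)])
  if (!is.finite(ref_val) || ref_val <= 0)
    stop("reference-region ePIB denominator is not positive")
  array(wavg / ref_val, dim = dim(dyn$data)[1:3])
}

#' Standardized uptake value ratio image
#'
#' Voxelwise division of a static image by its mean over the reference mask
#' (cerebellar grey matter in the standard pipeline).
#'
#' @param static 3D array.
#' @param ref_mask logical 3D reference mask.
#' @return 3D SUVR array.
#' @export
compute_suvr <- function(static, ref_mask) {
  if (!identical(dim(static), dim(ref_mask))) stop("grid mismatch")
  ref_val <- mean(static[ref_mask])
  if (!is.finite(ref_val) || ref_val <= 0)
    stop("reference-region mean must be positive")
  static / ref_val
}
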