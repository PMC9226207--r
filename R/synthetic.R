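# ---- phantom cohorts with known ground truth ------------------------------

# Evaluate code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

conv1d_zero <- function(v, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(v)
  vp <- c(rep(0, r), v, rep(0, r))
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + length(v))]
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a volume with a separable Gaussian kernel specified in mm full
#' width at half maximum, with zero padding at the edges.
#'
#' @param arr 3D array.
#' @param fwhm_mm scalar FWHM in mm (0 = no smoothing).
#' @param voxel_size numeric length-3 voxel size in mm.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_size = c(2, 2, 2)) {
  stopifnot(length(dim(arr)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(arr)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size   # sigma in voxels
  kern <- lapply(sig, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k / sum(k)
  })
  a <- apply(arr, c(2, 3), conv1d_zero, kern[[1]])
  a <- aperm(apply(a, c(1, 3), conv1d_zero, kern[[2]]), c(2, 1, 3))
  aperm(apply(a, c(1, 2), conv1d_zero, kern[[3]]), c(2, 3, 1))
}

#' Generate a phantom atlas on an ellipsoidal mask
#'
#' Partitions an ellipsoidal "brain" mask into contiguous regions by a
#' Voronoi tessellation of randomly placed seed points. The most inferior
#' region is flagged as the cerebellar grey-matter reference region; the
#' remaining regions are assigned cyclically to the frontal, parietal,
#' temporal, and occipital lobes.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param n_regions number of regions (>= 2: one reference + >= 1 cortical).
#' @param seed RNG seed (region placement is deterministic given the seed).
#' @param voxel_size voxel size in mm.
#' @return List with elements `atlas` (an [atlas_definition()]) and `mask`
#'   (logical 3D array).
#' @export
make_phantom_atlas <- function(grid_shape, n_regions = 6, seed = 1,
                               voxel_size = c(8, 8, 8)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (n_regions < 2)
    stop("n_regions must be >= 2 (one reference region plus cortex)")
  ctr <- (grid_shape + 1) / 2
  semi <- 0.45 * grid_shape
  ix <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  inside <- ((ix$x - ctr[1]) / semi[1])^2 + ((ix$y - ctr[2]) / semi[2])^2 +
    ((ix$z - ctr[3]) / semi[3])^2 <= 1
  mask <- array(inside, dim = grid_shape)
  nmask <- sum(mask)
  if (nmask < 8L * n_regions)
    stop(sprintf("grid too small: %d mask voxels for %d regions",
                 nmask, n_regions))
  vox <- as.matrix(ix[inside, ])
  seeds <- with_seed(seed, vox[sample.int(nmask, n_regions), , drop = FALSE])
  # assign every mask voxel to its nearest seed (mm distance)
  d2 <- sapply(seq_len(n_regions), function(i) {
    dd <- sweep(vox, 2, seeds[i, ]) * rep(voxel_size, each = nrow(vox))
    rowSums(dd^2)
  })
  assign_lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = grid_shape)
  labels[mask] <- assign_lab
  # reference = region whose seed lies most inferior (lowest z, ties by y)
  ord <- order(seeds[, 3], seeds[, 2], seeds[, 1])
  ref_lab <- ord[1]
  reg_names <- character(n_regions)
  reg_names[ref_lab] <- "cerebellum_gm"
  cort <- setdiff(seq_len(n_regions), ref_lab)
  reg_names[cort] <- sprintf("region_%02d", seq_along(cort))
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  lobe_map <- stats::setNames(
    c("cerebellum", lobes[(seq_along(cort) - 1L) %% length(lobes) + 1L]),
    c("cerebellum_gm", reg_names[cort]))
  atlas <- atlas_definition(labels,
                            stats::setNames(reg_names, as.character(seq_len(n_regions))),
                            lobe_map, voxel_size = voxel_size)
  list(atlas = atlas, mask = mask)
}

#' Build a disease-topography template
#'
#' Creates a ground-truth pattern template as a piecewise-constant-per-region
#' map of lobe effects, Gaussian-smoothed, masked, and normalized to unit
#' Euclidean norm over the mask. By convention affected lobes carry negative
#' weights (relative reduction).
#'
#' @param atlas an [atlas_definition()].
#' @param effects_by_lobe named numeric vector of relative effects keyed by
#'   lobe name (e.g. `c(parietal = -1, temporal = -0.7)`).
#' @param mask logical 3D array.
#' @param smoothing_fwhm mm FWHM applied before masking/normalization.
#' @return 3D array: unit-norm template, zero outside the mask.
#' @export
make_pattern_template <- function(atlas, effects_by_lobe, mask,
                                  smoothing_fwhm = 12) {
  stopifnot(inherits(atlas, "atlas_def"))
  unknown <- setdiff(names(effects_by_lobe), unique(atlas$lobe_map))
  if (length(unknown))
    stop("unknown lobe name(s): ", paste(unknown, collapse = ", "))
  if (all(effects_by_lobe == 0))
    stop("all lobe effects are zero: null template cannot be normalized")
  # per-region effect through the region -> lobe map
  region_effect <- vapply(names(atlas$region_names), function(lab) {
    lobe <- atlas$lobe_map[[atlas$region_names[[lab]]]]
    if (lobe %in% names(effects_by_lobe)) effects_by_lobe[[lobe]] else 0
  }, numeric(1))
  tmpl <- array(0, dim = dim(atlas$labels))
  for (lab in names(region_effect)) {
    if (region_effect[[lab]] != 0)
      tmpl[atlas$labels == as.integer(lab)] <- region_effect[[lab]]
  }
  tmpl <- gaussian_smooth(tmpl, smoothing_fwhm, atlas$voxel_size)
  tmpl <- apply_mask(tmpl, mask)
  nrm <- sqrt(sum(tmpl[mask]^2))
  if (nrm == 0) stop("template vanished after smoothing and masking")
  tmpl / nrm
}

#' Piecewise-constant positive baseline image for phantom cohorts
#'
#' @param atlas an [atlas_definition()].
#' @param mask logical 3D array.
#' @param range region mean range (uniform draw per region).
#' @param seed RNG seed.
#' @return 3D array, strictly positive inside the mask, zero outside.
#' @export
make_phantom_baseline <- function(atlas, mask, range = c(0.8, 1.2), seed = 1) {
  labs <- as.integer(names(atlas$region_names))
  means <- with_seed(seed, stats::runif(length(labs), range[1], range[2]))
  base <- array(0, dim = dim(atlas$labels))
  for (i in seq_along(labs)) base[atlas$labels == labs[i]] <- means[i]
  apply_mask(base, mask)
}

#' Simulation configuration for static phantom cohorts
#'
#' Defaults emulate the reference study conditions: 15 AD, 16 HC, 11 MCI+,
#' 10 MCI- subjects; group pattern-expression means ordered
#' HC = 0 < MCI- = 0.3 < MCI+ = 1 < AD = 2 (unitless multiples of the
#' unit-norm template); between-subject expression SD 0.5; 10% lognormal
#' global scaling variability; additive Gaussian noise of SD 0.05 image
#' units (on a baseline of order 1), smoothed at 12 mm FWHM.
#'
#' @param n_AD,n_HC,n_MCIplus,n_MCIminus subject counts per group.
#' @param expression_mean named numeric: mean template expression per group.
#' @param expression_sd between-subject expression SD (unitless).
#' @param global_scale_sd SD of log global scale factor (unitless).
#' @param noise_sd additive noise SD before smoothing (image units).
#' @param smoothing_fwhm mm FWHM applied to the noise field.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_AD = 15, n_HC = 16, n_MCIplus = 11, n_MCIminus = 10,
                       expression_mean = c("AD" = 2, "MCI+" = 1,
                                           "MCI-" = 0.3, "HC" = 0),
                       expression_sd = 0.5, global_scale_sd = 0.1,
                       noise_sd = 0.05, smoothing_fwhm = 12, seed = 1) {
  counts <- c(n_AD, n_HC, n_MCIplus, n_MCIminus)
  if (any(counts < 0)) stop("subject counts must be >= 0")
  if (expression_sd < 0 || global_scale_sd < 0 || noise_sd < 0)
    stop("standard deviations must be >= 0")
  need <- c("AD", "MCI+", "MCI-", "HC")
  if (!all(need %in% names(expression_mean)))
    stop("expression_mean must be named for all of ",
         paste(need, collapse = ", "))
  structure(list(n_AD = n_AD, n_HC = n_HC, n_MCIplus = n_MCIplus,
                 n_MCIminus = n_MCIminus,
                 expression_mean = expression_mean[need],
                 expression_sd = expression_sd,
                 global_scale_sd = global_scale_sd, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm, seed = seed),
            class = "sim_config")
}

#' Simulate a static phantom cohort with an embedded disease topography
#'
#' Each subject image is
#' `g_s * baseline * (1 + z_s * template) + noise`, where `g_s` is a
#' lognormal global scale factor, `z_s` a Gaussian per-subject template
#' expression with group-specific mean, and the noise field is iid Gaussian
#' subsequently smoothed. The generator returns the ground-truth expressions
#' for recovery testing.
#'
#' @param template unit-norm 3D template (see [make_pattern_template()]).
#' @param baseline 3D baseline image, strictly positive inside the mask.
#' @param cfg a [sim_config()].
#' @param mask logical 3D array.
#' @param voxel_size voxel size in mm.
#' @return List with `cohort` (a [pet_cohort()]) and `truth` (data frame
#'   with `subject_id`, `group`, `z` (expression), `g` (global scale)).
#' @export
simulate_static_cohort <- function(template, baseline, cfg, mask,
                                   voxel_size = c(8, 8, 8)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(baseline[mask] <= 0))
    stop("baseline must be strictly positive inside the mask")
  groups <- rep(c("AD", "MCI+", "MCI-", "HC"),
                c(cfg$n_AD, cfg$n_MCIplus, cfg$n_MCIminus, cfg$n_HC))
  n <- length(groups)
  if (n == 0) stop("no subjects configured")
  ids <- sprintf("%s_%02d", gsub("[+]", "p", gsub("[-]", "m", groups)),
                 stats::ave(seq_len(n), groups, FUN = seq_along))
  with_seed(cfg$seed, {
    z <- stats::rnorm(n, cfg$expression_mean[groups], cfg$expression_sd)
    g <- exp(stats::rnorm(n, 0, cfg$global_scale_sd))
    images <- vector("list", n)
    for (s in seq_len(n)) {
      expr <- 1 + z[s] * template
      if (any(expr[mask] <= 0))
        stop(sprintf(paste0("expression z = %.3g drives 1 + z*template ",
                            "nonpositive: non-physical negative image"), z[s]))
      img <- g[s] * baseline * expr
      if (cfg$noise_sd > 0) {
        eps <- array(stats::rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
        img <- img + gaussian_smooth(eps, cfg$smoothing_fwhm, voxel_size)
      }
      images[[s]] <- apply_mask(img, mask)
    }
    list(cohort = pet_cohort(images, ids, groups, mask, voxel_size),
         truth = data.frame(subject_id = ids, group = groups, z = z, g = g))
  })
}

#' Simulate a gamma-variate reference-tissue curve
#'
#' `C_R(t) = A * (t/tau)^alpha * exp(-t/tau)`, sampled on a 1-second grid.
#' The curve is zero at t = 0 and peaks at `t = alpha * tau`.
#'
#' @param duration_s total duration, seconds.
#' @param A amplitude (activity units, arbitrary).
#' @param alpha shape parameter (> 0).
#' @param tau time constant, seconds (> 0).
#' @return A `reference_curve`: list with `t` (0..duration, 1 s), `values`,
#'   and `params`.
#' @export
simulate_reference_curve <- function(duration_s = 3300, A = 1, alpha = 2,
                                     tau = 60) {
  if (duration_s <= 0) stop("duration must be positive")
  if (A <= 0 || alpha <= 0 || tau <= 0)
    stop("A, alpha and tau must be positive")
  t <- seq(0, duration_s, by = 1)
  v <- A * (t / tau)^alpha * exp(-t / tau)
  v[1] <- 0
  structure(list(t = t, values = v,
                 params = list(A = A, alpha = alpha, tau = tau)),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("Reference curve: %d s, peak %.3g at t = %d s\n",
              max(x$t), max(x$values), x$t[which.max(x$values)]))
  invisible(x)
}

#' Simulate a dynamic phantom cohort from the reference-tissue forward model
#'
#' Each region's noiseless time-activity curve is the frame-averaged
#' simplified-reference-tissue-model solution for that region's kinetic
#' parameters, driven by a shared reference curve; iid Gaussian noise is
#' added per voxel and frame. The reference region must have R1 = 1 and
#' BPND = 0 (it is its own reference).
#'
#' @param atlas an [atlas_definition()] whose cerebellum lobe is the
#'   reference region.
#' @param mask logical 3D array.
#' @param kinetics_by_region data frame with columns `region`, `R1`, `k2`
#'   (1/min), `BPND`, one row per atlas region.
#' @param ref_curve a [simulate_reference_curve()] result.
#' @param schedule a [frame_schedule()]; must lie within the curve duration.
#' @param noise_sd frame noise SD (activity units).
#' @param n_subjects number of replicate subjects.
#' @param seed RNG seed.
#' @return List with `images` (list of [dynamic_image()]), `truth_r1`
#'   (3D array), `k2_prime` (reference efflux, 1/min), and
#'   `kinetics` (the input table with derived `k2a`).
#' @export
simulate_dynamic_cohort <- function(atlas, mask, kinetics_by_region, ref_curve,
                                    schedule, noise_sd = 0, n_subjects = 1,
                                    seed = 1) {
  stopifnot(inherits(atlas, "atlas_def"), inherits(schedule, "frame_schedule"),
            inherits(ref_curve, "reference_curve"))
  if (max(schedule$end_s) > max(ref_curve$t))
    stop("frame schedule extends beyond the reference curve duration")
  kb <- kinetics_by_region
  need <- c("region", "R1", "k2", "BPND")
  if (!all(need %in% names(kb))) stop("kinetics table needs columns ",
                                      paste(need, collapse = ", "))
  regs <- unname(atlas$region_names)
  if (!all(regs %in% kb$region))
    stop("kinetics missing for region(s): ",
         paste(setdiff(regs, kb$region), collapse = ", "))
  ref_regs <- names(atlas$lobe_map)[atlas$lobe_map == "cerebellum"]
  kref <- kb[kb$region %in% ref_regs, , drop = FALSE]
  if (any(kref$R1 != 1) || any(kref$BPND != 0))
    stop("reference (cerebellum) region must have R1 = 1 and BPND = 0")
  k2_prime <- kref$k2[1] / kref$R1[1]
  kb$k2a <- kb$k2 / (1 + kb$BPND)

  nf <- nrow(schedule)
  tac <- matrix(0, nf, nrow(kb))
  for (i in seq_len(nrow(kb)))
    tac[, i] <- srtm_forward(ref_curve, schedule,
                             R1 = kb$R1[i], k2 = kb$k2[i], bpnd = kb$BPND[i])
  lab_of <- stats::setNames(seq_len(nrow(kb)),
                            kb$region)   # region name -> tac column
  # per-voxel region index inside mask
  vox_lab <- atlas$labels[mask]
  vox_reg <- match(unname(atlas$region_names[as.character(vox_lab)]), kb$region)
  truth_r1 <- array(NA_real_, dim = dim(mask))
  truth_r1[mask] <- kb$R1[vox_reg]

  dims <- c(dim(mask), nf)
  images <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    arr <- array(0, dim = dims)
    flat <- matrix(0, prod(dim(mask)), nf)
    flat[which(mask), ] <- t(tac[, vox_reg, drop = FALSE])
    if (noise_sd > 0)
      flat[which(mask), ] <- flat[which(mask), ] +
        stats::rnorm(sum(mask) * nf, 0, noise_sd)
    arr[] <- flat
    dynamic_image(arr, schedule)
  }))
  list(images = images, truth_r1 = truth_r1, k2_prime = k2_prime,
       kinetics = kb)
}
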