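test_that("data matrix performs subject centering then HC-mean subtraction", {
  # 5-voxel toy, hand-rolled two-step centering oracle
  m <- array(TRUE, dim = c(5, 1, 1))
  raw <- list(c(1, 2, 3, 4, 5), c(2, 2, 2, 2, 7), c(0, 1, 0, 1, 3),
              c(5, 4, 3, 2, 1))
  imgs <- lapply(raw, function(v) array(v, dim = c(5, 1, 1)))
  coh <- pet_cohort(imgs, paste0("s", 1:4), c("AD", "AD", "HC", "HC"), m,
                    c(1, 1, 1))
  dm <- build_data_matrix(coh)
  X0 <- vapply(raw, function(v) v - mean(v), numeric(5))    # subject-centred
  hc <- rowMeans(X0[, 3:4])
  expect_equal(unname(dm$values), unname(X0 - hc), tolerance = 1e-12)
  expect_equal(unname(dm$hc_profile), unname(hc))
  # per-subject centering leaves column means 0 before HC subtraction
  expect_equal(colMeans(X0), rep(0, 4), tolerance = 1e-12)
  expect_equal(mean(dm$hc_profile), 0, tolerance = 1e-12)

  # identical images -> zero matrix
  same <- pet_cohort(rep(imgs[1], 4), paste0("s", 1:4),
                     c("AD", "AD", "HC", "HC"), m, c(1, 1, 1))
  expect_equal(max(abs(build_data_matrix(same)$values)), 0)

  # guards
  no_hc <- pet_cohort(imgs, paste0("s", 1:4), rep("AD", 4), m, c(1, 1, 1))
  expect_error(build_data_matrix(no_hc), "no HC")
  bad <- imgs; bad[[1]][2] <- NaN
  cohb <- pet_cohort(bad, paste0("s", 1:4), c("AD", "AD", "HC", "HC"), m,
                     c(1, 1, 1))
  expect_error(build_data_matrix(cohb), "voxel")
})

test_that("subjects-space PCA agrees with a direct decomposition on toys", {
  set.seed(10)
  for (rep in 1:5) {
    nv <- sample(10:50, 1); ns <- sample(4:8, 1)
    X <- matrix(rnorm(nv * ns), nv, ns)
    X <- sweep(X, 2, colMeans(X))
    pc <- rcbfdp:::pca_small(X)
    sv <- svd(X)
    k <- ncol(pc$loadings)
    expect_equal(pc$variance_fraction[1:k],
                 (sv$d^2 / sum(sv$d^2))[1:k], tolerance = 1e-8)
    # loadings match up to sign; scores follow the same sign convention
    for (j in 1:min(3, k)) {
      s <- sign(sum(pc$loadings[, j] * sv$u[, j]))
      expect_equal(pc$loadings[, j], s * sv$u[, j], tolerance = 1e-8)
      expect_equal(unname(pc$scores[, j]), s * sv$d[j] * sv$v[, j],
                   tolerance = 1e-8)
    }
    # orthonormal loadings
    expect_equal(crossprod(pc$loadings), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("variance-prefix pool is minimal and pattern bookkeeping coheres", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 8, n_HC = 8, noise_sd = 0.05,
                                seed = 2)
  dm <- build_data_matrix(sc$cohort)
  pat <- derive_pattern(dm, variance_target = 0.5)
  vf <- pat$variance_fraction
  k <- length(pat$candidate_pcs)
  expect_gte(sum(vf[1:k]), 0.5)
  if (k > 1) expect_lt(sum(vf[1:(k - 1)]), 0.5)   # minimal prefix
  expect_true(all(pat$included_pcs %in% pat$candidate_pcs))
  expect_equal(pat$dp_variance_explained, 100 * sum(vf[pat$included_pcs]))
  expect_equal(sum(pat$weights^2), 1, tolerance = 1e-10)
  # sign convention: AD in-sample scores exceed HC
  expect_gt(mean(pat$insample_raw[pat$training_groups == "AD"]),
            mean(pat$insample_raw[pat$training_groups == "HC"]))
  # in-sample raw scores equal prospective scoring of the training images
  rescored <- vapply(sc$cohort$images, score_subject, numeric(1),
                     pattern = pat)
  expect_equal(rescored, pat$insample_raw, tolerance = 1e-8)
})

test_that("a single separating component forces a proportional pattern", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  # one strong embedded direction, no nuisance variance
  cfg <- sim_config(n_AD = 6, n_HC = 6, n_MCIplus = 0, n_MCIminus = 0,
                    expression_sd = 0.3, global_scale_sd = 0,
                    noise_sd = 1e-4, seed = 3)
  sim <- simulate_static_cohort(ph$template, ph$baseline, cfg, ph$mask)
  dm <- build_data_matrix(sim$cohort)
  pat <- derive_pattern(dm)
  if (identical(pat$included_pcs, 1L)) {
    expect_equal(abs(sum(pat$weights * pat$pc_loadings[, 1])), 1,
                 tolerance = 1e-8)
  }
  expect_gt(abs(cosine(pat$weights,
                       (ph$baseline * ph$template)[ph$mask] -
                         mean((ph$baseline * ph$template)[ph$mask]))), 0.9)
})

test_that("stepwise-AIC forward selection matches exhaustive search on toys", {
  set.seed(77)
  n_match <- 0
  for (rep in 1:20) {
    n <- 24
    y <- rep(c(1L, 0L), each = n / 2)
    S <- cbind(rnorm(n, mean = y * runif(1, 1, 2)), rnorm(n))
    if (runif(1) < 0.5) S <- S[, 2:1]
    sel <- tryCatch(rcbfdp:::stepwise_logistic_aic(S, y),
                    error = function(e) list(included = integer(0)))
    aic_of <- function(set) {
      if (!length(set)) {
        p <- mean(y)
        return(-2 * sum(y * log(p) + (1 - y) * log(1 - p)) + 2)
      }
      rcbfdp:::fit_logistic_safe(S[, set, drop = FALSE], y)$aic
    }
    subsets <- list(integer(0), 1L, 2L, c(1L, 2L))
    aics <- vapply(subsets, aic_of, numeric(1))
    best <- subsets[[which.min(aics)]]
    # with 2 candidates, forward selection with strict-decrease acceptance
    # reaches the exhaustive AIC optimum
    expect_lte(aic_of(sel$included), min(aics) + 1e-8)
    if (identical(sort(sel$included), sort(best))) n_match <- n_match + 1
  }
  expect_equal(n_match, 20)
})

test_that("scoring identities: zero at HC mean, shift invariance, linearity", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 6, n_HC = 6, seed = 4)
  fit <- ssm_pca(sc$cohort, loocv = FALSE)
  pat <- fit$pattern
  base_img <- sc$cohort$images[[1]]

  # image consistent with the training HC mean profile scores ~ 0
  hc_img <- array(0, dim = pat$dim)
  hc_img[pat$mask] <- pat$hc_profile + 5          # arbitrary offset
  expect_lt(abs(score_subject(hc_img, pat)), 1e-8)

  # global additive shift leaves the raw score unchanged
  expect_equal(score_subject(base_img + 3.2, pat),
               score_subject(base_img, pat), tolerance = 1e-8)

  # adding t * DP raises the score by exactly t
  w_vol <- pattern_volume(pat)
  for (t in c(-1.5, 0.3, 2)) {
    expect_equal(score_subject(base_img + t * w_vol, pat),
                 score_subject(base_img, pat) + t, tolerance = 1e-8)
  }
  expect_error(score_subject(array(0, dim = c(3, 3, 3)), pat), "grid")
})

test_that("LOOCV is order-invariant, consistent for duplicates, and guarded", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 5, n_HC = 5, noise_sd = 0.02,
                                seed = 6)
  lo <- loocv_scores(sc$cohort)
  # permuting subject order permutes rows only
  perm <- c(3, 1, 4, 2, 5, 9, 7, 10, 8, 6)
  coh2 <- pet_cohort(sc$cohort$images[perm], sc$cohort$subject_id[perm],
                     sc$cohort$group[perm], sc$cohort$mask,
                     sc$cohort$voxel_size)
  lo2 <- loocv_scores(coh2)
  m <- match(lo$scores$subject_id, lo2$scores$subject_id)
  expect_equal(lo2$scores$raw_score[m], lo$scores$raw_score, tolerance = 1e-8)

  # duplicated subject: LOOCV score approximates its twin's fold score
  imgs <- c(sc$cohort$images, sc$cohort$images[1])
  cohd <- pet_cohort(imgs, c(sc$cohort$subject_id, "dup"),
                     c(sc$cohort$group, sc$cohort$group[1]), sc$cohort$mask,
                     sc$cohort$voxel_size)
  lod <- loocv_scores(cohd)
  s_a <- lod$scores$raw_score[lod$scores$subject_id ==
                                sc$cohort$subject_id[1]]
  s_dup <- lod$scores$raw_score[lod$scores$subject_id == "dup"]
  expect_equal(s_a, s_dup, tolerance = 1e-8)

  # identical cohort -> degenerate decomposition surfaced as an error
  same <- pet_cohort(rep(sc$cohort$images[1], 6), paste0("s", 1:6),
                     rep(c("AD", "HC"), each = 3), sc$cohort$mask,
                     sc$cohort$voxel_size)
  expect_error(ssm_pca(same), "degenerate|variance")

  # folds must retain two subjects per class
  small <- pet_cohort(sc$cohort$images[c(1, 2, 6, 7)],
                      paste0("s", 1:4), c("AD", "AD", "HC", "HC"),
                      sc$cohort$mask, sc$cohort$voxel_size)
  expect_error(loocv_scores(small), "fewer than 2")
})

test_that("Z-standardization uses the HC LOOCV mean and SD", {
  expect_equal(zscore_standardize(4, c(1, 2, 3)), 2)
  expect_equal(zscore_standardize(2, c(1, 2, 3)), 0)
  expect_error(zscore_standardize(1, 5), "at least 2")
  expect_error(zscore_standardize(1, c(2, 2, 2)), "zero standard deviation")

  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 5, n_HC = 6, seed = 9)
  fit <- ssm_pca(sc$cohort)
  hcz <- fit$scores$z_score[fit$scores$group == "HC"]
  expect_equal(mean(hcz), 0, tolerance = 1e-10)
  expect_equal(sd(hcz), 1, tolerance = 1e-10)
})

test_that("Z-scores are invariant to global shifts and pre-SUVR scaling", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 5, n_HC = 5, seed = 12)
  fit <- ssm_pca(sc$cohort)
  # additive shift of a prospective image
  img <- sc$cohort$images[[2]]
  expect_equal(predict(fit, img + 11)$z_score, predict(fit, img)$z_score,
               tolerance = 1e-8)
  # multiplicative global rescaling removed by SUVR normalization
  raw_img <- 3.7 * img
  suvr_again <- compute_suvr(raw_img, ph$ref_mask)
  expect_equal(predict(fit, suvr_again)$z_score,
               predict(fit, compute_suvr(img, ph$ref_mask))$z_score,
               tolerance = 1e-8)
})

test_that("regional summary aggregates lobes exactly from member regions", {
  # hand-built 2-region atlas on a 10x5x2 grid of 2 mm voxels
  labels <- array(0L, dim = c(10, 5, 2))
  labels[1:5, , ] <- 1L; labels[6:10, , ] <- 2L
  atlas <- atlas_definition(labels, c("1" = "regA", "2" = "regB"),
                            c(regA = "parietal", regB = "parietal"),
                            voxel_size = c(2, 2, 2))
  mask <- labels > 0
  w <- ifelse(as.vector(labels) == 1L, 0.1, -0.05)   # constant per region
  w <- w / sqrt(sum(w^2))
  pat <- structure(list(weights = w, mask = mask, dim = dim(mask),
                        voxel_size = c(2, 2, 2), hc_profile = numeric(100),
                        log_transform = FALSE),
                   class = "disease_pattern")
  rs <- regional_summary(pat, atlas)
  ra <- rs[rs$level == "region" & rs$name == "regA", ]
  expect_equal(ra$n_voxels, 50)
  expect_equal(ra$volume_cm3, 50 * 8 / 1000)      # 0.4 cm^3
  expect_equal(ra$sd, 0)                          # constant weight per region
  lobe <- rs[rs$level == "lobe" & rs$name == "parietal", ]
  expect_equal(lobe$volume_cm3, 100 * 8 / 1000)   # 0.8 cm^3 for 100 voxels
  # lobe mean = voxel-weighted mean of member regions
  regs <- rs[rs$level == "region", ]
  expect_equal(lobe$mean,
               sum(regs$mean * regs$n_voxels) / sum(regs$n_voxels),
               tolerance = 1e-12)
  # empty region reported, not dropped
  mask2 <- mask; mask2[6:10, , ] <- FALSE
  pat2 <- pat; pat2$mask <- mask2; pat2$weights <- w[as.vector(mask2)]
  rs2 <- regional_summary(pat2, atlas)
  rb <- rs2[rs2$level == "region" & rs2$name == "regB", ]
  expect_equal(rb$n_voxels, 0)
  expect_true(is.na(rb$mean))
})

test_that("model object methods: coef, predict, fitted, print, summary", {
  ph <- test_phantom(grid = 12, n_regions = 5)
  sc <- test_static_suvr_cohort(ph, n_AD = 5, n_HC = 5, seed = 15)
  fit <- ssm_pca(sc$cohort)
  expect_named(coef(fit)[1], "(Intercept)")
  expect_equal(fitted(fit), fit$scores$z_score)
  pr <- predict(fit, sc$cohort$images[1:2])
  expect_equal(nrow(pr), 2)
  expect_true(all(is.finite(pr$raw_score)) && all(is.finite(pr$z_score)))
  # prospective z of a training image relates to its raw score consistently
  expect_equal(pr$z_score,
               (pr$raw_score - fit$hc_score_mean) / fit$hc_score_sd)
  expect_output(print(fit), "disease pattern")
  expect_output(print(summary(fit)), "Z-scores by group")
})
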