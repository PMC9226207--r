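# Shared phantom fixtures, built in code at test time.

test_phantom <- function(grid = 14, n_regions = 6, seed = 1) {
  ph <- make_phantom_atlas(rep(grid, 3), n_regions, seed = seed)
  template <- make_pattern_template(
    ph$atlas, c(parietal = -1, temporal = -0.7, frontal = -0.5), ph$mask)
  baseline <- make_phantom_baseline(ph$atlas, ph$mask, seed = seed)
  ref_labs <- as.integer(names(ph$atlas$region_names)[
    ph$atlas$lobe_map[unname(ph$atlas$region_names)] == "cerebellum"])
  ref_mask <- array(ph$atlas$labels %in% ref_labs, dim = dim(ph$mask))
  c(ph, list(template = template, baseline = baseline, ref_mask = ref_mask))
}

# Region kinetics with apparent efflux constants snapped onto the SRTM2
# basis grid, consistent with a common reference efflux rate k2'.
test_kinetics <- function(atlas, k2_prime = 0.15, seed = 3,
                          k2a_min = 0.01, k2a_max = 0.3, n_basis = 80) {
  grid <- exp(seq(log(k2a_min), log(k2a_max), length.out = n_basis))
  regions <- unname(atlas$region_names)
  is_ref <- atlas$lobe_map[regions] == "cerebellum"
  set.seed(seed)
  R1 <- ifelse(is_ref, 1, stats::runif(length(regions), 0.6, 1.3))
  BPND <- ifelse(is_ref, 0, round(stats::runif(length(regions), 0.1, 2), 2))
  k2a_want <- R1 * k2_prime / (1 + BPND)
  k2a <- grid[vapply(k2a_want, function(v) which.min(abs(grid - v)), 1L)]
  k2 <- ifelse(is_ref, k2_prime, k2a * (1 + BPND))
  R1 <- ifelse(is_ref, 1, k2 / k2_prime)
  data.frame(region = regions, R1 = R1, k2 = k2, BPND = BPND)
}

# A small AD/HC cohort of SUVR-normalized images with the template embedded.
test_static_suvr_cohort <- function(ph, n_AD = 8, n_HC = 8, noise_sd = 0.02,
                                    seed = 1) {
  cfg <- sim_config(n_AD = n_AD, n_HC = n_HC, n_MCIplus = 0, n_MCIminus = 0,
                    noise_sd = noise_sd, seed = seed)
  sim <- simulate_static_cohort(ph$template, ph$baseline, cfg, ph$mask,
                                ph$atlas$voxel_size)
  suvr <- lapply(sim$cohort$images, compute_suvr, ref_mask = ph$ref_mask)
  list(cohort = pet_cohort(suvr, sim$cohort$subject_id, sim$cohort$group,
                           ph$mask, ph$atlas$voxel_size),
       truth = sim$truth)
}

centred_template <- function(ph) {
  v <- ph$template[ph$mask]
  v - mean(v)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
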