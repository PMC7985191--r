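# Synthetic ground-truth generator: distance embedding, Gaussian-atom
# forward model, damage process, dose series, RH datasets.

pair_dists <- function(model, pairs) {
  distance_table(model, pairs)$distance
}

test_that("embedding realizes exactly realizable distance sets", {
  # regular tetrahedron: all 6 pairwise distances 3.0
  labs <- c("A", "B", "C", "D")
  cmb <- combn(labs, 2)
  d <- setNames(rep(3, 6), paste(cmb[1, ], cmb[2, ], sep = "-"))
  # labels must parse; use Mn-style names instead
  names(d) <- c("Mn1-Mn2", "Mn1-Mn3", "Mn1-Mn4", "Mn2-Mn3", "Mn2-Mn4",
                "Mn3-Mn4")
  mod <- embed_from_distances(d, seed = 2)
  got <- pair_dists(mod, names(d))
  expect_true(all(abs(got - 3) < 0.01))
  # two-point set at the published Mn1-Mn2 separation
  mod2 <- embed_from_distances(c("Mn1-Mn2" = 2.7), seed = 1)
  expect_equal(pair_dists(mod2, "Mn1-Mn2"), 2.7, tolerance = 1e-6)
})

test_that("the published cluster set embeds within 0.03 A but not 0.01 A", {
  d <- cluster_distance_set("xfel")
  # the printed table is rounded to 0.1 A and its five metal sites are
  # over-constrained, so machine-precision embedding is impossible
  expect_error(embed_from_distances(d, seed = 1, tol = 0.01),
               "not realizable")
  mod <- embed_from_distances(d, seed = 1, tol = 0.03, min_separation = 2.4)
  got <- pair_dists(mod, names(d))
  expect_true(all(abs(got - d) < 0.03))
})

test_that("forward model is linear in occupancy and matches the closed form", {
  atoms <- data.frame(element = "MN", name = "MN", resname = "OEC",
                      x = 8.05, y = 8, z = 8, occ = 1, adp = 13)
  m1 <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10,
                     cutoff_sigma = Inf)
  atoms$occ <- 0.5
  m2 <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10,
                     cutoff_sigma = Inf)
  expect_equal(m2$grid, m1$grid / 2, tolerance = 1e-12)
  # closed-form value at a voxel centre: amplitude x Gaussian falloff
  s2 <- (13 + 10) / (8 * pi^2)
  v <- m1$grid[17, 17, 17]   # voxel centre (8, 8, 8), 0.05 A from the atom
  expect_equal(v, as.numeric(element_weights["MN"]) / (2 * pi * s2)^1.5 *
                 exp(-(0.05^2) / (2 * s2)), tolerance = 1e-9)
})

test_that("metal peaks are higher than oxygen peaks at equal ADP", {
  atoms <- data.frame(element = c("MN", "O"), name = c("MN", "O1"),
                      resname = "OEC", x = c(5, 11), y = 8, z = 8,
                      occ = 1, adp = 13)
  m <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10)
  pk <- find_peaks(m, 1)
  expect_equal(nrow(pk), 2)
  expect_gt(pk$height[1], pk$height[2])
  expect_lt(abs(pk$x[1] - 5), 0.1)     # highest peak is the metal
})

test_that("atoms outside the box are reported by name", {
  atoms <- data.frame(element = "O", name = "OX", resname = "OEC",
                      x = 40, y = 8, z = 8, occ = 1, adp = 10)
  expect_error(simulate_map(atomic_model(atoms), 16, 0.5), "OX")
})

test_that("dose series damage follows the parametric model", {
  spec <- toy_small_spec()
  dmg <- damage_model(occupancy_dose_constant = 100, adp_rate = 0.01,
                      drift_targets = data.frame(
                        atom = "Mn3", away_from = "Mn2",
                        max_disp = 0.4, dose_constant = 10),
                      bond_break_dose = 150, noise_sigma_per_frame = 0)
  # choose fluence so the last frame's mid-frame dose saturates the drift
  st <- simulate_dose_series(spec, dmg, n_frames = 4, total_fluence = 200,
                             seed = 3)
  gt <- st$ground_truth
  # occupancy = exp(-D/Dc) at mid-frame cumulative dose
  mid_dose <- (4 - 0.5) / 4 * 200 * 3.7
  occ <- gt[[4]]$atoms$occ[gt[[4]]$selections$metals]
  expect_equal(unique(occ), exp(-mid_dose / 100), tolerance = 1e-9)
  # ADP inflation is linear in dose
  adp <- gt[[4]]$atoms$adp[gt[[4]]$selections$metals][1]
  expect_equal(adp, spec$cluster_adp + 0.01 * mid_dose, tolerance = 1e-9)
  # planted elongation saturates at +0.4 A
  d0 <- pair_dists(st$model, "Mn2-Mn3")
  d4 <- pair_dists(gt[[4]], "Mn2-Mn3")
  expect_equal(d4 - d0, 0.4, tolerance = 1e-3)
  # disulfide partner vanishes beyond the break dose
  expect_equal(gt[[4]]$atoms$occ[gt[[4]]$selections$disulfide[2]], 0)
  expect_gt(gt[[1]]$atoms$occ[gt[[1]]$selections$disulfide[2]], 0)
})

test_that("occupancy decay hits 1/e at one dose constant", {
  mod <- toy_small()
  dmg <- damage_model(occupancy_dose_constant = 150,
                      drift_targets = NULL, noise_sigma_per_frame = 0)
  dm <- apply_damage(mod, dmg, 150)
  occ <- dm$atoms$occ[dm$selections$metals]
  expect_equal(unique(occ), exp(-1), tolerance = 1e-9)
})

test_that("without damage and noise all frames are identical", {
  spec <- toy_small_spec()
  st <- simulate_dose_series(spec, no_damage_model(), n_frames = 3,
                             total_fluence = 9, seed = 1)
  expect_identical(st$frames[[1]]$grid, st$frames[[2]]$grid)
  expect_identical(st$frames[[2]]$grid, st$frames[[3]]$grid)
})

test_that("damage metrics are monotone in frame index with zero noise", {
  spec <- toy_small_spec()
  dmg <- damage_model(occupancy_dose_constant = 300,
                      noise_sigma_per_frame = 0)
  st <- simulate_dose_series(spec, dmg, n_frames = 5, total_fluence = 83,
                             seed = 1)
  occ <- vapply(st$ground_truth, function(g)
    g$atoms$occ[g$selections$metals[1]], numeric(1))
  expect_true(all(diff(occ) < 0))
  d23 <- vapply(st$ground_truth, function(g) pair_dists(g, "Mn2-Mn3"),
                numeric(1))
  expect_true(all(diff(d23) > 0))
})

test_that("RH fit recovers the planted B exactly on noiseless data", {
  spec <- rh_dataset_spec(true_B = 43.3, resolution_noise_sigma = 0)
  pts <- simulate_rh_dataset(spec)
  fit <- rosenthal_henderson_fit(pts)
  expect_equal(fit$B, 43.3, tolerance = 1e-9)
  expect_equal(fit$intercept, spec$intercept, tolerance = 1e-9)
})

test_that("doubling every particle count shifts the line, not the slope", {
  spec <- rh_dataset_spec(resolution_noise_sigma = 0)
  a <- simulate_rh_dataset(spec)
  b <- a; b$n_particles <- 2 * b$n_particles
  # same resolutions at doubled N: intercept absorbs (2/B) ln 2
  fa <- rosenthal_henderson_fit(a)
  fb <- rosenthal_henderson_fit(b)
  expect_equal(fb$B, fa$B, tolerance = 1e-9)
  expect_equal(fa$intercept - fb$intercept, (2 / fa$B) * log(2),
               tolerance = 1e-9)
})

test_that("noisy RH fits are unbiased across seeds", {
  Bs <- vapply(1:100, function(s) {
    pts <- simulate_rh_dataset(rh_dataset_spec(
      resolution_noise_sigma = 0.003, seed = s))
    rosenthal_henderson_fit(pts)$B
  }, numeric(1))
  se <- sd(Bs) / sqrt(length(Bs))
  expect_lt(abs(mean(Bs) - 43.3), 3 * se + 1e-9)
})
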