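# Map algebra: frame summation, normalization, subtraction, carving,
# filtering, interpolation, rigid resampling.

test_that("frame sums accumulate voxels and fluence", {
  spec <- toy_small_spec()
  st <- simulate_dose_series(spec, damage_model(noise_sigma_per_frame = 0.05),
                             n_frames = 4, total_fluence = 83, seed = 2)
  full <- sum_frames(st, c(1, 4))
  expect_equal(attr(full, "fluence"), 83)
  one <- sum_frames(st, c(2, 2))
  expect_identical(one$grid, st$frames[[2]]$grid)
  two <- sum_frames(st, c(1, 2))
  expect_equal(two$grid, st$frames[[1]]$grid + st$frames[[2]]$grid,
               tolerance = 1e-15)
  expect_error(sum_frames(st, c(0, 2)), "invalid")
  expect_error(sum_frames(st, c(3, 6)), "invalid")
})

test_that("RMS normalization matches the reference scale and is idempotent", {
  a <- random_map(seed = 1); b <- random_map(seed = 2)
  n1 <- normalize_rms(a, b)
  expect_equal(map_rms(n1), map_rms(b), tolerance = 1e-10)
  # target = 2 x reference recovers the reference exactly
  twice <- b; twice$grid <- 2 * twice$grid; twice <- update_stats(twice)
  expect_equal(normalize_rms(twice, b)$grid, b$grid, tolerance = 1e-12)
  # idempotent; normalizing a map against itself changes nothing
  expect_equal(normalize_rms(n1, b)$grid, n1$grid, tolerance = 1e-12)
  expect_equal(normalize_rms(a, a)$grid, a$grid, tolerance = 1e-12)
})

test_that("subtraction is exact and invertible", {
  a <- random_map(seed = 3); b <- random_map(seed = 4)
  z <- subtract_maps(a, a)
  expect_true(all(z$grid == 0))
  d <- subtract_maps(a, b)
  back <- d; back$grid <- back$grid + b$grid
  expect_equal(back$grid, a$grid, tolerance = 1e-15)
  bad <- random_map(n = 10, seed = 5)
  expect_error(subtract_maps(a, bad), "dimensions")
})

test_that("difference map exposes a bond broken in one arm only", {
  # intact disulfide in the low-dose arm, one partner absent at high dose
  atoms <- data.frame(element = "S", name = c("SG1", "SG2"), resname = "CYS",
                      x = c(8, 8), y = c(7, 9.05), z = 8, occ = 1, adp = 20)
  low <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10)
  atoms2 <- atoms; atoms2$occ[2] <- 0
  high <- simulate_map(atomic_model(atoms2), 16, 0.5, global_B = 10)
  diffm <- subtract_maps(low, normalize_rms(high, low))
  v <- interpolate_map(diffm, c(8, 9.05, 8))
  expect_gt(v / diffm$sigma, 4)
})

test_that("carving removes exactly the in-sphere mass", {
  # single Gaussian carved at its centre with radius 3x its width
  atoms <- data.frame(element = "O", name = "O1", resname = "OEC",
                      x = 8, y = 8, z = 8, occ = 1, adp = 13)
  m <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10)
  width <- sqrt((13 + 10) / (8 * pi^2))
  r <- 3 * width
  carved <- carve_spheres(m, c(8, 8, 8), r)
  # brute-force voxel loop: which voxel centres lie inside the sphere
  ax <- (seq_len(dim(m$grid)[1]) - 1) * 0.5
  removed <- 0; inmax <- 0
  for (i in seq_along(ax)) for (j in seq_along(ax)) for (k in seq_along(ax)) {
    if ((ax[i] - 8)^2 + (ax[j] - 8)^2 + (ax[k] - 8)^2 <= r^2) {
      removed <- removed + m$grid[i, j, k]
      inmax <- max(inmax, carved$grid[i, j, k])
    }
  }
  expect_equal(sum(m$grid) - sum(carved$grid), removed, tolerance = 1e-12)
  expect_identical(inmax, 0)
  # radius 0 removes nothing (no voxel centre coincides exactly)
  m0 <- carve_spheres(m, c(8.123, 8.456, 8.789), 0)
  expect_identical(m0$grid, m$grid)
  # removed mass is nondecreasing in radius
  masses <- vapply(c(0.5, 1, 1.5, 2), function(rr)
    sum(m$grid) - sum(carve_spheres(m, c(8, 8, 8), rr)$grid), numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("carving metal density exposes light atoms at 7 sigma", {
  mod <- toy_default()
  m <- map_default()
  got <- assign_cluster(m, mod)
  gt <- mod$atoms[c(mod$selections$cluster_oxygens, mod$selections$waters), ]
  expect_equal(nrow(got$lights), 9)
  errs <- vapply(seq_len(nrow(got$lights)), function(i)
    min(sqrt((gt$x - got$lights$x[i])^2 + (gt$y - got$lights$y[i])^2 +
             (gt$z - got$lights$z[i])^2)), numeric(1))
  expect_lt(max(errs), 0.3)
})

test_that("low-pass filtering attenuates out-of-band power, preserves mean", {
  set.seed(9)
  n <- 24
  noise <- density_map(array(rnorm(n^3), c(n, n, n)), voxel_size = 1)
  res <- 4   # Angstrom
  filt <- lowpass_filter(noise, res)
  expect_equal(filt$mean, noise$mean, tolerance = 1e-10)
  ft <- fft(filt$grid)
  fr <- function(d) { i <- seq_len(d) - 1; i[i > d / 2] <- i[i > d / 2] - d
                      i / d }
  s <- sqrt(outer(outer(fr(n)^2, fr(n)^2, "+"), fr(n)^2, "+"))
  inband <- sum(abs(ft[s <= 1 / res])^2)
  # allow the cosine ramp width beyond the cutoff
  ramp <- 5 / n
  outband <- sum(abs(ft[s > 1 / res + ramp])^2)
  expect_lt(outband / inband, 0.01)
  # a map band-limited well inside the pass band is unchanged by a
  # coarser filter (the 8 A limit with a narrow ramp keeps all content
  # below the 4 A cutoff)
  smooth <- lowpass_filter(noise, 8, edge_width = 2)
  again <- lowpass_filter(smooth, 4)
  expect_lt(max(abs(again$grid - smooth$grid)) /
            max(abs(smooth$grid)), 1e-8)
  expect_error(lowpass_filter(noise, 1.5), "Nyquist")
})

test_that("trilinear interpolation agrees with the brute-force reference", {
  m <- random_map(n = 10, voxel = 0.8, origin = c(-2, 1, 0), seed = 6)
  # voxel centre and axis midpoint
  expect_equal(interpolate_map(m, m$origin + c(3, 2, 4) * 0.8),
               m$grid[4, 3, 5], tolerance = 1e-14)
  mid <- m$origin + c(3.5, 2, 4) * 0.8
  expect_equal(interpolate_map(m, mid),
               (m$grid[4, 3, 5] + m$grid[5, 3, 5]) / 2, tolerance = 1e-14)
  set.seed(12)
  for (k in 1:100) {
    p <- m$origin + runif(3, 0.2, 8.6) * 0.8
    expect_equal(interpolate_map(m, p), brute_trilinear(m, p),
                 tolerance = 1e-12)
  }
  expect_error(interpolate_map(m, m$origin - 1), "outside")
})

test_that("cubic interpolation is exact at voxel centres and C0-consistent", {
  m <- random_map(n = 10, voxel = 0.8, origin = c(0, 0, 0), seed = 8)
  expect_equal(interpolate_map(m, c(3, 2, 4) * 0.8, method = "cubic"),
               m$grid[4, 3, 5], tolerance = 1e-12)
  # on an analytic Gaussian, cubic interpolation beats linear and is
  # accurate to better than 1 percent off-grid
  atoms <- data.frame(element = "O", name = "O1", resname = "OEC",
                      x = 8, y = 8, z = 8, occ = 1, adp = 40)
  sm <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 40,
                     cutoff_sigma = Inf)
  s2 <- (40 + 40) / (8 * pi^2)
  p <- c(7.6, 8.2, 8.3)
  truth <- as.numeric(element_weights["O"]) / (2 * pi * s2)^1.5 *
    exp(-sum((p - 8)^2) / (2 * s2))
  err_cubic <- abs(interpolate_map(sm, p, method = "cubic") - truth)
  err_linear <- abs(interpolate_map(sm, p) - truth)
  expect_lt(err_cubic, err_linear)
  expect_lt(err_cubic / truth, 0.01)
})

test_that("rigid map transforms behave like coordinate transforms", {
  m <- random_map(n = 9, voxel = 1, seed = 10)
  ident <- transform_map(m, diag(3))
  expect_equal(ident$grid, m$grid, tolerance = 1e-12)
  # 90-degree rotation about z of a cube-symmetric grid = index permutation
  n <- 9; c0 <- (n - 1) / 2     # rotate about the grid centre
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  t <- c(c0, c0, c0) - R %*% c(c0, c0, c0)
  rot <- transform_map(m, R, as.numeric(t))
  # voxel (i,j,k) of the result = voxel (j, n+1-i, k) of the input
  perm <- m$grid
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    perm[i, j, k] <- m$grid[j, n + 1 - i, k]
  expect_equal(rot$grid, perm, tolerance = 1e-9)
  # transform then inverse-transform restores a smooth map
  atoms <- data.frame(element = c("MN", "O"), name = c("MN", "O1"),
                      resname = "OEC", x = c(7, 9.5), y = 8, z = 8,
                      occ = 1, adp = 40)
  sm <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 60)
  R2 <- random_rotation(4)
  ctr <- c(8, 8, 8)
  t2 <- as.numeric(ctr - R2 %*% ctr) + c(0.3, -0.2, 0.1)
  fwd <- transform_map(sm, R2, t2)
  back <- transform_map(fwd, t(R2), as.numeric(-t(R2) %*% t2))
  keep <- sm$grid > 0.01 * max(sm$grid)
  expect_gt(cor(back$grid[keep], sm$grid[keep]), 0.999)
  expect_error(transform_map(m, diag(3) * 2), "orthonormal")
})
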