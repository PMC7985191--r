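# Restraint building, restrained real-space refinement, distance tables,
# step averaging, reference comparison.

test_that("restraints cover every metal/light contact in the bond window", {
  mod <- toy_small()
  cl <- atomic_model(mod$atoms[mod$selections$cluster, ])
  rs <- build_restraints(cl, sigma = 0.1)
  # brute-force count from the planted coordinates
  a <- cl$atoms
  metals <- which(a$element %in% c("MN", "CA"))
  lights <- setdiff(seq_len(nrow(a)), metals)
  want <- 0
  for (m in metals) for (l in lights) {
    d <- sqrt(sum((a[m, c("x", "y", "z")] - a[l, c("x", "y", "z")])^2))
    if (d >= 1.5 && d <= 3.0) want <- want + 1
  }
  expect_equal(nrow(rs), want)
  expect_true(all(rs$sigma == 0.1))
  expect_true(all(rs$target > 0))
  # a minimal fragment yields a single restraint at the current distance
  duo <- atomic_model(data.frame(element = c("MN", "O"),
                                 name = c("MN", "O1"), resname = "OEC",
                                 x = c(0, 2), y = 0, z = 0))
  r1 <- build_restraints(duo, sigma = 0.05)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$target, 2, tolerance = 1e-12)
  expect_error(build_restraints(atomic_model(duo$atoms[0, ])), "empty")
})

test_that("refinement of an undamaged map at true positions is a fixed point", {
  mod <- toy_small()
  spec <- toy_small_spec()
  m <- simulate_map(mod, spec$box_size, spec$voxel_size,
                    global_B = spec$global_B)
  cl <- atomic_model(mod$atoms[mod$selections$cluster, ])
  rs <- build_restraints(cl)
  out <- refine_positions(m, cl, rs)
  disp <- sqrt(rowSums((model_coords(out$fragment) - model_coords(cl))^2))
  # positions stay put up to the interpolation bias of 0.5 A sampling,
  # and the restrained distances hold their true targets
  expect_lt(max(disp), 0.1)
  d_true <- rs$target
  d_got <- distance_table(out$fragment,
                          paste0(rs$atom_a, "-", rs$atom_b))$distance
  expect_lt(max(abs(d_got - d_true)), 0.05)
  expect_true(out$converged)
})

test_that("restraint sigma interpolates between map optimum and target", {
  # one oxygen, displaced restraint target: tight sigma pins the distance
  # at the target, loose sigma lets the density win
  atoms <- data.frame(element = c("MN", "O"), name = c("Mn", "O1"),
                      resname = "OEC", x = c(6, 8.1), y = 8, z = 8,
                      occ = 1, adp = 13)
  m <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10)
  frag <- atomic_model(atoms)
  mk_rs <- function(sig) {
    rs <- build_restraints(frag, sigma = sig, bond_window = c(1.5, 3))
    rs$target <- 1.8   # map optimum for the pair is 2.1
    rs
  }
  d_of <- function(sig) {
    out <- refine_positions(m, frag, mk_rs(sig), sigma_schedule = sig,
                            max_outer = 1)
    distance_table(out$fragment, "Mn-O1")$distance
  }
  d_tight <- d_of(1e-4)
  d_mid1 <- d_of(0.1)
  d_mid2 <- d_of(0.05)
  d_loose <- d_of(1e4)
  expect_equal(d_tight, 1.8, tolerance = 5e-3)       # sigma -> 0: target
  expect_equal(d_loose, 2.1, tolerance = 5e-2)       # sigma -> inf: map
  # tightening 0.1 -> 0.05 moves the distance toward the target
  expect_lt(abs(d_mid2 - 1.8), abs(d_mid1 - 1.8))
  expect_true(d_tight <= d_mid2 && d_mid2 <= d_loose + 1e-6)
})

test_that("pairs refined below 1.7 A are fixed at 1.8 A and flagged", {
  # plant an oxygen whose density optimum sits at 1.55 A from the metal
  atoms <- data.frame(element = c("MN", "O"), name = c("Mn", "O1"),
                      resname = "OEC", x = c(6, 7.55), y = 8, z = 8,
                      occ = 1, adp = 13)
  m <- simulate_map(atomic_model(atoms), 16, 0.5, global_B = 10)
  frag <- atomic_model(atoms)
  rs <- build_restraints(frag, sigma = 10, bond_window = c(1.4, 3))
  out <- refine_positions(m, frag, rs)
  expect_equal(out$clamped, "Mn-O1")
  final <- distance_table(out$fragment, "Mn-O1")$distance
  expect_equal(final, 1.8, tolerance = 1e-6)
  last_step <- out$steps[[length(out$steps)]]
  expect_true(last_step$clamped[last_step$pair == "Mn-O1"])
})

test_that("distance tables agree with a brute-force all-pairs loop", {
  mod <- toy_small()
  pairs <- names(toy_small_spec()$cluster_distances)
  tab <- distance_table(mod, pairs)
  a <- mod$atoms
  for (r in seq_len(nrow(tab))) {
    nm <- strsplit(tab$pair[r], "-")[[1]]
    i <- match(nm[1], a$name); j <- match(nm[2], a$name)
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    expect_equal(tab$distance[r], d, tolerance = 1e-12)
  }
  expect_equal(distance_table(atomic_model(data.frame(
    element = c("MN", "MN"), name = c("Mn1", "Mn2"), resname = "OEC",
    x = c(0, 0), y = c(0, 0), z = c(0, 2.7))), "Mn1-Mn2")$distance, 2.7)
  expect_error(distance_table(mod, "Mn1-Zz9"), "missing")
})

test_that("step averaging reproduces the printed conventions", {
  mk <- function(d) data.frame(pair = "Mn3-O4", distance = d,
                               distance_1dp = round_half_up(d, 1))
  # the published low-dose step series
  avg <- average_steps(list(mk(2.0), mk(2.1), mk(2.1), mk(2.2)))
  expect_equal(avg$average_1dp, 2.1)
  # four identical steps average to themselves
  avg2 <- average_steps(list(mk(3.1), mk(3.1), mk(3.1), mk(3.1)))
  expect_equal(avg2$average_1dp, 3.1)
  # plain arithmetic
  avg3 <- average_steps(list(mk(1), mk(2), mk(3), mk(4)))
  expect_equal(avg3$mean_distance, 2.5)
  # only the final four of a longer series count
  avg4 <- average_steps(list(mk(9), mk(1), mk(2), mk(3), mk(4)))
  expect_equal(avg4$mean_distance, 2.5)
  # fewer than four available: averaged and flagged
  avg5 <- average_steps(list(mk(2.0), mk(2.2)))
  expect_equal(avg5$mean_distance, 2.1)
  expect_true(isTRUE(attr(avg5, "short")))
})

test_that("half-up rounding follows the printed-table convention", {
  expect_equal(round_half_up(2.875, 1), 2.9)
  expect_equal(round_half_up(2.85, 1), 2.9)
  expect_equal(round_half_up(-2.85, 1), -2.9)
  expect_equal(round_half_up(2.84999, 1), 2.8)
})

test_that("table comparison reports signed deltas against a reference", {
  ref <- oec_reference_distances()
  self <- data.frame(pair = ref$pair, mean_distance = ref$xfel)
  z <- compare_tables(self, ref, ref_col = "xfel")
  expect_true(all(z$delta == 0))
  # the high-dose average vs the damage-free reference: +0.4 on Mn2-Mn3
  obs <- data.frame(pair = ref$pair, mean_distance = ref$highdose_avg)
  cmp <- compare_tables(obs, ref, ref_col = "xfel")
  expect_equal(cmp$delta_1dp[cmp$pair == "Mn2-Mn3"], 0.4)
  expect_equal(cmp$delta_1dp[cmp$pair == "Mn2-Mn4"], 0.4)
  expect_error(compare_tables(data.frame(pair = "A-B", mean_distance = 1),
                              ref, ref_col = "xfel"), "no shared")
})
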