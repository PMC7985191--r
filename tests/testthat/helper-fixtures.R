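# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# the default synthetic complex (full scaffold) and its noiseless map
toy_default <- function() fixture("toy_default", build_toy_model(toy_complex_spec()))
map_default <- function() {
  spec <- toy_complex_spec()
  fixture("map_default",
          simulate_map(toy_default(), spec$box_size, spec$voxel_size,
                       global_B = spec$global_B))
}

# a small cluster-only complex in a compact box (fast to render)
toy_small_spec <- function()
  toy_complex_spec(scaffold_atom_count = 0, box_size = 32, voxel_size = 0.5)
toy_small <- function() fixture("toy_small", build_toy_model(toy_small_spec()))
map_small <- function() {
  spec <- toy_small_spec()
  fixture("map_small",
          simulate_map(toy_small(), spec$box_size, spec$voxel_size,
                       global_B = spec$global_B))
}

# brute-force voxel-loop reference for map statistics and mass sums
brute_stats <- function(grid) {
  n <- length(grid); s <- 0; ss <- 0
  for (v in as.numeric(grid)) { s <- s + v }
  m <- s / n
  for (v in as.numeric(grid)) { ss <- ss + (v - m)^2 }
  list(mean = m, sigma = sqrt(ss / n))
}

# brute-force trilinear interpolation at a single point
brute_trilinear <- function(map, p) {
  fi <- (p - map$origin) / map$voxel_size + 1
  i0 <- pmin(floor(fi), dim(map$grid) - 1)
  t <- fi - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    v <- v + w * map$grid[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  v
}

# independent raw MRC reader: header words + data block, no permutation
# logic beyond what the header literally states
brute_read_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hi <- readBin(con, "integer", 256, size = 4, endian = "little")
  seek(con, 0)
  hf <- readBin(con, "numeric", 256, size = 4, endian = "little")
  seek(con, 1024 + hi[24])
  vals <- readBin(con, "numeric", prod(hi[1:3]), size = 4, endian = "little")
  list(nxyz = hi[1:3], mapcrs = hi[17:19], cella = hf[11:13],
       mxyz = hi[8:10], origin = hf[50:52],
       arr = array(vals, dim = hi[1:3]))
}

# write an MRC file whose axes are stored in a permuted order
write_permuted_mrc <- function(map, path, mapcrs) {
  perm <- match(1:3, mapcrs)        # canonical axis -> file dim
  arr <- aperm(map$grid, order(perm))
  d <- dim(arr)
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L); wi(c(0L, 0L, 0L))
  wi(dim(map$grid))                                  # MX MY MZ on x,y,z
  wf(dim(map$grid) * map$voxel_size); wf(c(90, 90, 90))
  wi(mapcrs)
  wf(c(min(arr), max(arr), mean(arr)))
  wi(1L); wi(0L); wi(integer(25))
  wf(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(arr)); wi(0L); writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

# a smooth random test map
random_map <- function(n = 12, voxel = 1, origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  g <- array(stats::rnorm(n^3), c(n, n, n))
  density_map(g, voxel_size = voxel, origin = origin)
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# assignment of the cluster on an arbitrary map: peaks -> metals -> carve
# -> light atoms, labelled against a reference model
assign_cluster <- function(map, reference, peak_sigma = 17, light_sigma = 7,
                           carve_radius = 1.3, window = c(1.7, 3.0)) {
  metals <- assign_metals(find_peaks(map, peak_sigma))
  metals <- label_sites_by_reference(metals, reference)
  carved <- carve_spheres(map, model_coords(metals), carve_radius)
  lights <- assign_light_atoms(carved, metals, light_sigma, window)
  list(metals = metals, lights = lights, carved = carved)
}
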