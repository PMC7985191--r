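# Peak detection and density interpretation: metal assignment by peak
# height, light-atom assignment in the metal-subtracted map, and bond
# integrity along atom-atom segments.

#' Find local density maxima above a sigma threshold
#'
#' Local maxima over the full 26-voxel neighbourhood with value at least
#' `threshold_sigma` map standard deviations. Peak positions are refined
#' to subvoxel precision by separable 1D quadratic fits of the three
#' axial neighbours. Output is ordered by height descending, ties broken
#' by ascending grid index, so results are deterministic.
#'
#' @param map a [density_map()].
#' @param threshold_sigma detection threshold as a multiple of map sigma
#'   (> 0).
#' @return data.frame with columns `x`, `y`, `z` (Angstrom), `height`
#'   (density) and `height_sigma` (height / map sigma); zero rows if
#'   nothing qualifies.
#' @export
find_peaks <- function(map, threshold_sigma) {
  stopifnot(inherits(map, "density_map"))
  if (threshold_sigma <= 0) stop("threshold_sigma must be > 0")
  g <- map$grid
  d <- dim(g)
  if (map$sigma == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      height = numeric(), height_sigma = numeric()))
  thr <- threshold_sigma * map$sigma
  core <- g[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  is_max <- core >= thr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- g[(2 + dx):(d[1] - 1 + dx),
            (2 + dy):(d[2] - 1 + dy),
            (2 + dz):(d[3] - 1 + dz), drop = FALSE]
    is_max <- is_max & (core > nb)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      height = numeric(), height_sigma = numeric()))
  idx <- idx + 1L                               # back to full-grid indices
  pos <- matrix(NA_real_, nrow(idx), 3)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    for (k in 1:3) {
      im <- i; ip <- i
      im[k] <- im[k] - 1L; ip[k] <- ip[k] + 1L
      fm <- g[im[1], im[2], im[3]]
      f0 <- g[i[1], i[2], i[3]]
      fp <- g[ip[1], ip[2], ip[3]]
      denom <- fm - 2 * f0 + fp
      off <- if (denom < 0) 0.5 * (fm - fp) / denom else 0
      off <- max(-0.5, min(0.5, off))
      pos[r, k] <- map$origin[k] + (i[k] - 1 + off) * map$voxel_size[k]
    }
  }
  h <- g[idx]
  lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
  ord <- order(-h, lin)
  data.frame(x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
             height = h[ord], height_sigma = h[ord] / map$sigma)
}

#' Assign metal identities to the strongest peaks
#'
#' Takes the top-k peaks as the metal sites and labels them so that total
#' (scattering weight x peak height) is maximal, i.e. the heaviest
#' expected element goes to the highest peak. Deterministic.
#'
#' @param peaks peak table from [find_peaks()] (height-descending).
#' @param expected character vector of expected element symbols with
#'   multiplicity, e.g. `c("MN", "MN", "MN", "MN", "CA")`.
#' @return An [atomic_model()] fragment with one atom per expected metal,
#'   named `<element><rank>` by descending weight.
#' @export
assign_metals <- function(peaks, expected = c("MN", "MN", "MN", "MN", "CA")) {
  expected <- toupper(expected)
  k <- length(expected)
  if (nrow(peaks) < k)
    stop("fewer peaks (", nrow(peaks), ") than expected metals (", k, ")")
  w <- element_weights[expected]
  if (any(is.na(w))) stop("unknown element in expected set")
  ord <- order(-w)                 # heaviest element to highest peak
  elem <- expected[ord]
  top <- peaks[seq_len(k), , drop = FALSE]
  nm <- paste0(substr(elem, 1, 1),
               tolower(substr(elem, 2, 2)),
               stats::ave(seq_len(k), elem, FUN = seq_along))
  nm[elem == "CA" & table(elem)["CA"] == 1] <- "Ca"
  atomic_model(data.frame(
    element = elem, name = nm, resname = "OEC", chain = "A",
    resno = seq_len(k), x = top$x, y = top$y, z = top$z,
    occ = 1, adp = 0, stringsAsFactors = FALSE))
}

#' Assign light atoms in a metal-subtracted map
#'
#' Finds peaks of the carved map at or above `threshold_sigma` whose
#' distance to the nearest assigned metal lies inside `distance_window`,
#' the bonding range of metal-ligated oxygens and waters. Each candidate
#' is annotated with its nearest metal and the distance to it.
#'
#' @param map_carved the metal-subtracted [density_map()].
#' @param metals metal fragment from [assign_metals()].
#' @param threshold_sigma detection threshold in carved-map sigmas.
#' @param distance_window numeric length-2, allowed distance range to the
#'   nearest metal in Angstrom.
#' @return data.frame of candidate sites (`x`,`y`,`z`,`height_sigma`,
#'   `nearest_metal`, `distance`); zero rows allowed.
#' @export
assign_light_atoms <- function(map_carved, metals, threshold_sigma = 7,
                               distance_window = c(1.7, 3.0)) {
  pk <- find_peaks(map_carved, threshold_sigma)
  mx <- model_coords(metals)
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      height_sigma = numeric(), nearest_metal = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  dmat <- outer(seq_len(nrow(pk)), seq_len(nrow(mx)),
                Vectorize(function(i, j)
                  sqrt(sum((c(pk$x[i], pk$y[i], pk$z[i]) - mx[j, ])^2))))
  nearest <- apply(dmat, 1, which.min)
  dist <- dmat[cbind(seq_len(nrow(pk)), nearest)]
  keep <- dist >= distance_window[1] & dist <= distance_window[2]
  data.frame(x = pk$x[keep], y = pk$y[keep], z = pk$z[keep],
             height_sigma = pk$height_sigma[keep],
             nearest_metal = metals$atoms$name[nearest[keep]],
             distance = dist[keep], stringsAsFactors = FALSE)
}

#' Score bond integrity from density along the bond
#'
#' Samples the density along the segment between two atom positions at
#' 0.1 A steps; the bond is called intact if the minimum sampled value
#' stays at or above `contour_sigma` map standard deviations (the minimum,
#' not just the midpoint, so one-sided breakage is caught). The midpoint
#' density is also reported.
#'
#' @param map a [density_map()].
#' @param atom_a,atom_b length-3 Angstrom positions (must be in bounds).
#' @param contour_sigma contour level in map sigmas.
#' @return List with `intact` (logical), `min_sigma`, `midpoint_sigma`.
#' @export
bond_integrity <- function(map, atom_a, atom_b, contour_sigma = 4) {
  stopifnot(inherits(map, "density_map"))
  atom_a <- as.numeric(atom_a); atom_b <- as.numeric(atom_b)
  len <- sqrt(sum((atom_b - atom_a)^2))
  n <- max(2L, ceiling(len / 0.1) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(atom_a[1] + tt * (atom_b[1] - atom_a[1]),
               atom_a[2] + tt * (atom_b[2] - atom_a[2]),
               atom_a[3] + tt * (atom_b[3] - atom_a[3]))
  vals <- interpolate_map(map, pts) / map$sigma
  list(intact = min(vals) >= contour_sigma,
       min_sigma = min(vals),
       midpoint_sigma = vals[ceiling(n / 2)])
}
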