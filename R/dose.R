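# Dose bookkeeping, FSC resolution estimation, Rosenthal-Henderson
# B-factor fitting, and damage-metric trajectories versus accumulated
# dose.

#' Convert electron fluence to absorbed dose
#'
#' Fluence in electrons per square Angstrom is converted to absorbed dose
#' with the standard 300 kV factor of 3.7 MGy per e-/A^2, and compared
#' against the Henderson limit (20 MGy, the X-ray dose halving a
#' cryo-cooled crystal's diffraction).
#'
#' @param fluence electron fluence, e-/A^2 (vectorized, >= 0).
#' @param factor MGy per e-/A^2; 3.7 applies at 300 kV.
#' @return data.frame with `fluence`, `dose_mgy`, `henderson_limit` and
#'   `exceeds_henderson`.
#' @export
dose_to_gray <- function(fluence, factor = 3.7) {
  if (any(fluence < 0)) stop("fluence must be >= 0")
  dose <- fluence * factor
  data.frame(fluence = fluence, dose_mgy = dose, henderson_limit = 20,
             exceeds_henderson = dose > 20)
}

#' Frame range delivering a target fluence
#'
#' Under uniform fractionation the first k frames of an n-frame exposure
#' deliver `k/n` of the total fluence; k is the nearest-frame rounding of
#' `target / total * n`, never below 1. The realized fluence of the
#' selected range is reported alongside.
#'
#' @param total_fluence total fluence of the full exposure, e-/A^2.
#' @param n_frames number of frames.
#' @param target_fluence requested fluence, 0 < target <= total.
#' @return List with `frames` (c(1, k)), `n_frames_used` and
#'   `realized_fluence`.
#' @export
frames_for_dose <- function(total_fluence, n_frames, target_fluence) {
  if (target_fluence <= 0) stop("target fluence must be > 0")
  if (target_fluence > total_fluence)
    stop("target fluence ", target_fluence, " exceeds total ", total_fluence)
  k <- max(1L, as.integer(round(target_fluence / total_fluence * n_frames)))
  list(frames = c(1L, k), n_frames_used = k,
       realized_fluence = k / n_frames * total_fluence)
}

#' Fourier shell correlation between two half-maps
#'
#' Per radial shell in frequency space,
#' `Re(sum F1 * Conj(F2)) / sqrt(sum |F1|^2 * sum |F2|^2)` over the
#' Fourier voxels of the shell. Shells are uniform in spatial frequency up
#' to Nyquist.
#'
#' @param half1,half2 [density_map()]s on identical grids.
#' @param n_shells number of shells (>= 2); default half the smallest
#'   grid dimension.
#' @return data.frame of class `fsc_curve`: `freq` (shell centre, 1/A),
#'   `fsc`, `n_voxels`.
#' @export
fsc <- function(half1, half2, n_shells = NULL) {
  stopifnot(inherits(half1, "density_map"), inherits(half2, "density_map"))
  check_same_geometry(half1, half2)
  d <- dim(half1$grid)
  if (is.null(n_shells)) n_shells <- floor(min(d) / 2)
  if (n_shells < 2) stop("n_shells must be >= 2")
  f1 <- stats::fft(half1$grid)
  f2 <- stats::fft(half2$grid)
  freq_ax <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - 1
    i[i > d[k] / 2] <- i[i > d[k] / 2] - d[k]
    i / (d[k] * half1$voxel_size[k])
  })
  s <- sqrt(outer(outer(freq_ax[[1]]^2, freq_ax[[2]]^2, "+"),
                  freq_ax[[3]]^2, "+"))
  nyq <- 1 / (2 * max(half1$voxel_size))
  edges <- seq(0, nyq, length.out = n_shells + 1)
  shell <- findInterval(s, edges, rightmost.closed = TRUE)
  keep <- shell >= 1 & shell <= n_shells & s > 0
  sh <- shell[keep]
  num <- as.numeric(tapply(Re(f1[keep] * Conj(f2[keep])), sh, sum))
  p1 <- as.numeric(tapply(abs(f1[keep])^2, sh, sum))
  p2 <- as.numeric(tapply(abs(f2[keep])^2, sh, sum))
  cnt <- as.numeric(table(factor(sh, levels = seq_len(n_shells))))
  lev <- as.integer(names(table(sh)))
  corr <- rep(NA_real_, n_shells)
  corr[lev] <- num / sqrt(p1 * p2)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(freq = centres, fsc = corr, n_voxels = cnt)
  out <- out[!is.na(out$fsc), ]
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Scans the curve from low to high frequency for the first crossing
#' below `threshold` and interpolates linearly between the bracketing
#' shells. If the curve never drops below the threshold the Nyquist
#' resolution is returned with `crossed = FALSE`; a curve already below
#' threshold in its first shell returns the first shell's resolution with
#' `crossed = NA` (flagged, not an error).
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold correlation cut-off; 0.143 is the gold-standard
#'   half-map criterion.
#' @return List with `resolution` (Angstrom), `crossed` flag and
#'   `threshold`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"), nrow(curve) >= 1)
  below <- which(curve$fsc < threshold)
  if (length(below) == 0)
    return(list(resolution = 1 / max(curve$freq), crossed = FALSE,
                threshold = threshold))
  i <- below[1]
  if (i == 1)
    return(list(resolution = 1 / curve$freq[1], crossed = NA,
                threshold = threshold))
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  c0 <- curve$fsc[i - 1];  c1 <- curve$fsc[i]
  fx <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
  list(resolution = 1 / fx, crossed = TRUE, threshold = threshold)
}

#' Rosenthal-Henderson B-factor fit
#'
#' Least-squares line of inverse squared resolution on the natural log of
#' particle count; the B-factor is two over the slope. A non-positive
#' slope is flagged unphysical rather than raised.
#'
#' @param points data.frame with columns `n_particles` and `resolution`
#'   (Angstrom), at least two distinct particle counts.
#' @return List of class `rh_fit` with `B` (A^2), `intercept`, `slope`,
#'   `residual_se`, `physical` flag, and the per-point table
#'   (`ln_n`, `inv_d2`).
#' @export
rosenthal_henderson_fit <- function(points) {
  if (nrow(points) < 2 || length(unique(points$n_particles)) < 2)
    stop("need >= 2 points with distinct particle counts")
  if (any(points$n_particles <= 0)) stop("particle counts must be > 0")
  ln_n <- log(points$n_particles)
  inv_d2 <- 1 / points$resolution^2
  fit <- stats::lm(inv_d2 ~ ln_n)
  slope <- unname(stats::coef(fit)[2])
  structure(list(B = if (slope > 0) 2 / slope else NA_real_,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = slope,
                 residual_se = if (nrow(points) > 2)
                   sqrt(sum(stats::residuals(fit)^2) /
                        (nrow(points) - 2)) else 0,
                 physical = slope > 0,
                 points = data.frame(ln_n = ln_n, inv_d2 = inv_d2)),
            class = "rh_fit")
}

#' @export
print.rh_fit <- function(x, ...) {
  cat(sprintf("<rh_fit> B = %.3f A^2 (slope %.5g, intercept %.5g)%s\n",
              x$B, x$slope, x$intercept,
              if (!x$physical) " [UNPHYSICAL: slope <= 0]" else ""))
  invisible(x)
}

#' Damage metrics versus accumulated dose
#'
#' For each requested fluence: sums the corresponding leading frame range
#' of the stack, then evaluates the configured probes on the summed map --
#' bond integrity for each bond pair, peak height at each metal site
#' (reported absolutely and as an occupancy proxy, the ratio to the
#' lowest-dose row), and listed inter-site distances measured between
#' map peaks nearest the probe sites.
#'
#' @param stack a frame stack from [simulate_dose_series()].
#' @param dose_list target fluences (e-/A^2), each achievable from the
#'   stack.
#' @param probes list with optional elements `bonds` (list of 2-row
#'   coordinate matrices), `metal_sites` (n x 3 matrix), `distance_pairs`
#'   (list of 2-row coordinate matrices).
#' @param contour_sigma bond-integrity contour in map sigmas.
#' @return data.frame (`dose_series_report`): one row per dose with
#'   fluence, dose in MGy, frames used, map sigma, per-bond intact flags
#'   and midpoint densities, per-site peak heights and occupancy proxies,
#'   and probe distances.
#' @export
damage_trajectory <- function(stack, dose_list, probes,
                              contour_sigma = 4) {
  stopifnot(inherits(stack, "frame_stack"))
  dose_list <- sort(dose_list)
  n <- length(stack$frames)
  rows <- vector("list", length(dose_list))
  for (j in seq_along(dose_list)) {
    sel <- frames_for_dose(stack$total_fluence, n, dose_list[j])
    m <- sum_frames(stack, sel$frames)
    row <- data.frame(target_fluence = dose_list[j],
                      realized_fluence = attr(m, "fluence"),
                      dose_mgy = dose_to_gray(attr(m, "fluence"))$dose_mgy,
                      frames_used = sel$n_frames_used,
                      map_sigma = m$sigma)
    if (!is.null(probes$bonds)) {
      for (bi in seq_along(probes$bonds)) {
        b <- probes$bonds[[bi]]
        res <- bond_integrity(m, b[1, ], b[2, ], contour_sigma)
        row[[paste0("bond", bi, "_intact")]] <- res$intact
        row[[paste0("bond", bi, "_min_sigma")]] <- res$min_sigma
      }
    }
    if (!is.null(probes$metal_sites)) {
      ms <- as.matrix(probes$metal_sites)
      h <- interpolate_map(m, ms)
      for (si in seq_len(nrow(ms)))
        row[[paste0("site", si, "_height")]] <- h[si]
    }
    if (!is.null(probes$distance_pairs)) {
      pk <- find_peaks(m, 1)
      for (pi in seq_along(probes$distance_pairs)) {
        p <- probes$distance_pairs[[pi]]
        near <- function(q) {
          dd <- (pk$x - q[1])^2 + (pk$y - q[2])^2 + (pk$z - q[3])^2
          c(pk$x[which.min(dd)], pk$y[which.min(dd)], pk$z[which.min(dd)])
        }
        row[[paste0("dist", pi)]] <-
          sqrt(sum((near(p[1, ]) - near(p[2, ]))^2))
      }
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  # occupancy proxy: per-site height ratio against the lowest-dose row
  hcols <- grep("^site[0-9]+_height$", names(out), value = TRUE)
  for (hc in hcols) {
    ref <- out[[hc]][1] / out$frames_used[1]
    out[[sub("_height$", "_occupancy_proxy", hc)]] <-
      (out[[hc]] / out$frames_used) / ref
  }
  class(out) <- c("dose_series_report", "data.frame")
  out
}
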