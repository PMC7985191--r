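# Least-squares rigid superposition (Kabsch) and RMSD.

#' Least-squares rigid fit of one point set onto another
#'
#' SVD-based Kabsch algorithm: returns the proper rotation (det +1, never
#' a reflection) and translation minimizing the RMSD of `moving` onto
#' `fixed`, as `y = R x + t`.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, equal lengths,
#'   not all collinear.
#' @return List of class `rigid_transform` with fields `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (residual after superposition).
#' @export
kabsch_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("point sets differ in length: ", nrow(moving), " vs ", nrow(fixed))
  if (nrow(moving) < 3) stop("need at least 3 points for a rigid fit")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(A, B))          # H = A^T B ; R = V S U^T
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; rotation underdetermined")
  s <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, s))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  moved <- sweep(moving %*% t(R), 2, t, "+")
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(rowSums((moved - fixed)^2)))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> residual RMSD", format(x$rmsd, digits = 4), "A\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` from [kabsch_fit()].
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Write/read a rigid transform as a 12-number plain-text file
#'
#' Row-major rotation (9 numbers) followed by the translation (3), one
#' value per line -- the interchange format consumed by map
#' transformation.
#'
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return `path` (write) or a `rigid_transform` (read).
#' @export
write_transform <- function(transform, path) {
  writeLines(format(c(t(transform$rotation), transform$translation),
                    digits = 17), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- as.numeric(readLines(path))
  if (length(v) != 12) stop("transform file must hold 12 numbers")
  structure(list(rotation = matrix(v[1:9], 3, 3, byrow = TRUE),
                 translation = v[10:12], rmsd = NA_real_),
            class = "rigid_transform")
}

#' Root-mean-square deviation between paired coordinates
#'
#' @param a,b n x 3 coordinate matrices of equal length (n >= 1).
#' @param superpose if `TRUE`, superpose `a` onto `b` with [kabsch_fit()]
#'   first (requires n >= 3).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("point sets differ in length: ", nrow(a), " vs ", nrow(b))
  if (superpose) a <- apply_rigid(kabsch_fit(a, b), a)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Pair atoms of two models by chain, residue and atom name
#'
#' Atoms of a named selection are matched across two models on the key
#' (chain, residue number, atom name); unmatched atoms are dropped. The
#' returned pairing feeds [kabsch_fit()] and [rmsd()].
#'
#' @param a,b [atomic_model()]s.
#' @param selection selection name present in both models (e.g. `"CA"`).
#' @return List with `xyz_a`, `xyz_b` (paired n x 3 matrices) and
#'   `n_pairs`.
#' @export
pair_atoms <- function(a, b, selection = "CA") {
  stopifnot(inherits(a, "atomic_model"), inherits(b, "atomic_model"))
  for (m in list(a, b))
    if (is.null(m$selections[[selection]]))
      stop("no such selection: ", selection)
  key <- function(m) {
    at <- m$atoms[m$selections[[selection]], , drop = FALSE]
    list(at = at, k = paste(at$chain, at$resno, at$name, sep = "|"))
  }
  ka <- key(a); kb <- key(b)
  common <- intersect(ka$k, kb$k)
  if (length(common) == 0) stop("no atoms could be paired on selection '",
                                selection, "'")
  ma <- ka$at[match(common, ka$k), c("x", "y", "z")]
  mb <- kb$at[match(common, kb$k), c("x", "y", "z")]
  list(xyz_a = as.matrix(ma), xyz_b = as.matrix(mb),
       n_pairs = length(common))
}
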