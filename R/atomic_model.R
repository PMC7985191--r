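#' Element scattering weights
#'
#' Fixed positive per-element weights, proportional to atomic number, used
#' by the Gaussian-atom forward model and by metal assignment. Relative
#' magnitudes are all that matters downstream (a manganese peak must beat a
#' calcium peak, which must beat sulfur, oxygen, and carbon); true electron
#' form factors are deliberately not modelled.
#'
#' @format Named numeric vector, one entry per supported element symbol.
#' @export
element_weights <- c(
  H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28,
  CU = 29, ZN = 30
)
names(element_weights)[names(element_weights) == "NA."] <- "NA"

#' Elements treated as metals
#' @noRd
metal_elements <- c("NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN")

#' Construct an atomic model
#'
#' An `atomic_model` is an ordered table of atoms (element, atom name,
#' residue name, chain, residue number, xyz in Angstrom, occupancy, ADP in
#' square Angstrom) plus named index selections. The selections `metals`
#' (element in the metal table), `waters` (residue name HOH), `CA`
#' (atom name CA on non-water residues) and `cluster_oxygens` (oxygen atoms
#' of residue OEC) are built automatically and can be overridden.
#'
#' @param atoms data.frame with columns `element`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `occ`, `adp`. Missing label columns
#'   are filled with defaults.
#' @param selections optional named list of integer index vectors; merged
#'   over the automatic ones.
#' @return Object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, selections = list()) {
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  n <- nrow(atoms)
  defaults <- list(name = atoms$element, resname = "UNK", chain = "A",
                   resno = seq_len(n), occ = 1, adp = 0)
  for (f in names(defaults))
    if (is.null(atoms[[f]])) atoms[[f]] <- defaults[[f]]
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  unknown <- setdiff(unique(atoms$element), names(element_weights))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy must lie in [0, 1]")
  if (any(atoms$adp < 0))
    stop("ADP must be >= 0")
  atoms <- atoms[c("element", "name", "resname", "chain", "resno",
                   "x", "y", "z", "occ", "adp")]
  rownames(atoms) <- NULL
  auto <- list(
    metals = which(atoms$element %in% metal_elements),
    waters = which(atoms$resname == "HOH"),
    cluster_oxygens = which(atoms$resname == "OEC" & atoms$element == "O"),
    CA = which(atoms$name == "CA" & atoms$resname != "HOH" &
               atoms$element == "C")
  )
  sel <- utils::modifyList(auto, selections)
  bad <- vapply(sel, function(ix) length(ix) && (min(ix) < 1 || max(ix) > n),
                logical(1))
  if (any(bad))
    stop("selection(s) reference invalid atom indices: ",
         paste(names(sel)[bad], collapse = ", "))
  structure(list(atoms = atoms, selections = sel), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms (%d metals, %d waters)\n",
              nrow(x$atoms), length(x$selections$metals),
              length(x$selections$waters)))
  invisible(x)
}

#' Coordinate matrix of a model (optionally of a named selection)
#'
#' @param model an [atomic_model()].
#' @param selection optional selection name.
#' @return n x 3 numeric matrix of Angstrom coordinates.
#' @export
model_coords <- function(model, selection = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  if (!is.null(selection)) {
    if (is.null(model$selections[[selection]]))
      stop("no such selection: ", selection)
    a <- a[model$selections[[selection]], , drop = FALSE]
  }
  as.matrix(a[, c("x", "y", "z")])
}

#' Read a PDB-style coordinate file
#'
#' Thin wrapper over [bio3d::read.pdb()] that normalizes ATOM/HETATM
#' records into an [atomic_model()]. Waters are detected by residue name
#' HOH, metals by element symbol. The element column must be present
#' (columns 77-78 of the fixed-width record).
#'
#' @param path path to a PDB file.
#' @return An [atomic_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model: no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  if (any(is.na(elem) | elem == ""))
    stop("missing element column in ", path)
  atoms <- data.frame(element = elem, name = trimws(a$elety),
                      resname = trimws(a$resid), chain = a$chain,
                      resno = a$resno, x = a$x, y = a$y, z = a$z,
                      occ = a$o, adp = a$b, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  atomic_model(atoms)
}

#' Write a PDB-style coordinate file
#'
#' Fixed-column ATOM/HETATM records via [bio3d::write.pdb()]; occupancy and
#' ADP are carried in the standard occupancy and B-factor columns at their
#' fixed-width precision (2 decimals). Waters and hetero residues are
#' emitted as HETATM.
#'
#' @param model an [atomic_model()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  if (any(abs(a[, c("x", "y", "z")]) >= 10000))
    stop("coordinate exceeds fixed-width PDB field capacity (|x| >= 10000)")
  het <- a$resname %in% c("HOH", "OEC", "UNK") | a$element %in% metal_elements
  bio3d::write.pdb(file = path,
                   type = ifelse(het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   o = a$occ, b = a$adp, elesy = a$element)
  invisible(path)
}
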