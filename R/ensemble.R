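# Multi-model structure ensembles: PDB ingestion, linker stripping,
# superposition and backbone RMSD.
#
# An ensemble is stored as a fixed atom inventory (data.frame) plus a
# coordinate array [n_atoms x 3 x n_models]; every MODEL block of the input
# must present the identical atom list.

new_structure_ensemble <- function(atoms, coords, source = NA_character_) {
  stopifnot(nrow(atoms) == dim(coords)[1], dim(coords)[2] == 3)
  structure(list(atoms = atoms, coords = coords, source = source),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d atoms, %d model(s), chains %s\n",
              nrow(x$atoms), n_models(x),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one model as an atom table
#'
#' @param ensemble A `structure_ensemble`.
#' @param i Model index.
#' @return data.frame with atom fields plus `x`, `y`, `z` columns.
#' @export
get_model <- function(ensemble, i = 1L) {
  if (i < 1L || i > n_models(ensemble))
    stop("model index out of range", call. = FALSE)
  df <- ensemble$atoms
  df$x <- ensemble$coords[, 1, i]
  df$y <- ensemble$coords[, 2, i]
  df$z <- ensemble$coords[, 3, i]
  df
}

infer_element <- function(atom_name) {
  a <- gsub("[0-9' ]", "", atom_name)
  two <- toupper(substr(a, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         substr(paste0(toupper(substr(a, 1, 1)), tolower(substr(a, 2, 2))), 1, 2),
         toupper(substr(a, 1, 1)))
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) return(NULL)
  name <- trimws(substr(lines, 13, 16))
  alt <- substr(lines, 17, 17)
  use <- alt %in% c(" ", "", "A")
  lines <- lines[use]; name <- name[use]
  elem <- trimws(substr(lines, 77, 78))
  elem[!nzchar(elem)] <- infer_element(name[!nzchar(elem)])
  data.frame(
    chain = substr(lines, 22, 22),
    resnum = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    atom = name,
    element = elem,
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE
  )
}

#' Load a (possibly multi-MODEL) PDB file as an ensemble
#'
#' One model per MODEL/ENDMDL block; files without MODEL records yield an
#' ensemble of one. The atom inventory (chain, residue number/name, atom
#' name) must be identical across models; a mismatch is a format error
#' naming the offending model. Alternate locations other than `A` are
#' dropped.
#'
#' @param path PDB file path.
#' @return A `structure_ensemble`.
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    df <- parse_pdb_atoms(lines)
    if (is.null(df)) stop("no ATOM records in ", path, call. = FALSE)
    blocks <- list(df)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      stop("truncated PDB: MODEL without ENDMDL in ", path, call. = FALSE)
    blocks <- lapply(seq_along(starts), function(k) {
      parse_pdb_atoms(lines[starts[k]:ends[k]])
    })
    if (any(vapply(blocks, is.null, logical(1))))
      stop("empty MODEL block in ", path, call. = FALSE)
  }
  ref <- blocks[[1]][, c("chain", "resnum", "resname", "atom")]
  for (k in seq_along(blocks)) {
    bk <- blocks[[k]][, c("chain", "resnum", "resname", "atom")]
    if (nrow(bk) != nrow(ref) || !identical(bk, ref))
      stop("inconsistent atom inventory in model ", k, " of ", path,
           call. = FALSE)
  }
  if (anyNA(blocks[[1]]$x) || anyNA(blocks[[1]]$y) || anyNA(blocks[[1]]$z))
    stop("non-finite coordinates in ", path, call. = FALSE)
  coords <- array(NA_real_, dim = c(nrow(ref), 3, length(blocks)))
  for (k in seq_along(blocks)) {
    coords[, , k] <- as.matrix(blocks[[k]][, c("x", "y", "z")])
  }
  atoms <- blocks[[1]][, c("chain", "resnum", "resname", "atom", "element")]
  rownames(atoms) <- NULL
  new_structure_ensemble(atoms, coords, source = path)
}

#' Write an ensemble as a multi-MODEL PDB file
#'
#' @param ensemble A `structure_ensemble`.
#' @param path Output path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$atoms
  nm <- n_models(ensemble)
  for (k in seq_len(nm)) {
    if (nm > 1L) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- ensemble$coords[, , k]
    # PDB name field: element-left-padded convention for short names
    name_fmt <- ifelse(nchar(at$atom) < 4L, sprintf(" %-3s", at$atom), at$atom)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), name_fmt, at$resname, at$chain, at$resnum,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element)
    writeLines(lines, con)
    if (nm > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Remove a residue range (e.g. a chimera linker) from every model
#'
#' @param ensemble A `structure_ensemble`.
#' @param residue_range Integer vector of residue numbers to remove
#'   (e.g. `75:83`); `integer(0)` is the identity.
#' @param chain Optional chain restriction; default all chains.
#' @return A `structure_ensemble` without the stripped residues.
#' @export
strip_linker <- function(ensemble, residue_range, chain = NULL) {
  if (!length(residue_range)) return(ensemble)
  drop <- ensemble$atoms$resnum %in% residue_range
  if (!is.null(chain)) drop <- drop & ensemble$atoms$chain %in% chain
  if (all(drop)) stop("stripping would remove every atom", call. = FALSE)
  keep <- !drop
  atoms <- ensemble$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure_ensemble(atoms,
                         ensemble$coords[keep, , , drop = FALSE],
                         source = ensemble$source)
}

# Kabsch optimal superposition: returns B rotated/translated onto A.
kabsch_superpose <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(B0 %*% t(R) * 1, 2, ca, `+`)
}

backbone_coords <- function(model, residue_range, chain = NULL) {
  bb <- c("N", "CA", "C", "O")
  sel <- model$resnum %in% residue_range & model$atom %in% bb
  if (!is.null(chain)) sel <- sel & model$chain %in% chain
  m <- model[sel, , drop = FALSE]
  have <- unique(m$resnum)
  missing <- setdiff(residue_range, have)
  if (length(missing))
    stop("residues missing backbone atoms in range: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- m[order(m$chain, m$resnum, match(m$atom, bb)), , drop = FALSE]
  as.matrix(m[, c("x", "y", "z")])
}

#' Backbone RMSD after optimal superposition
#'
#' Least-squares rigid-body (Kabsch) superposition of B onto A over the
#' backbone atoms (N, CA, C, O) of the residue range, then RMSD.
#'
#' @param model_a,model_b Atom tables (see [get_model()]); an ensemble may be
#'   passed, in which case its first model is used.
#' @param residue_range Integer vector of residue numbers.
#' @param chain Optional chain restriction.
#' @param superpose If `FALSE`, skip superposition and compute raw RMSD.
#' @return RMSD in Angstroms.
#' @export
backbone_rmsd <- function(model_a, model_b, residue_range, chain = NULL,
                          superpose = TRUE) {
  if (inherits(model_a, "structure_ensemble")) model_a <- get_model(model_a, 1L)
  if (inherits(model_b, "structure_ensemble")) model_b <- get_model(model_b, 1L)
  A <- backbone_coords(model_a, residue_range, chain)
  B <- backbone_coords(model_b, residue_range, chain)
  if (nrow(A) != nrow(B))
    stop("backbone atom counts differ between structures", call. = FALSE)
  if (superpose) B <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((A - B)^2)))
}
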