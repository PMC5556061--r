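# Force-field-style parameter assignment.
#
# The packaged table is a minimal, editable heavy-atom amino-acid set
# (charges summing exactly to formal charges, 12-6 LJ in Rmin/2 + well
# depth, generalized-Born intrinsic radii with descreening scale factors,
# and a bond graph for 1-2/1-3/1-4 classification). It is a functional
# stand-in for a full force field, not a reproduction of one.

#' Load a parameter table
#'
#' @param atoms_path TSV with columns resname, atom, element, charge,
#'   lj_rmin2, lj_eps, gb_radius, gb_scale, formal_charge. Defaults to the
#'   packaged minimal set.
#' @param bonds_path TSV with columns resname, atom1, atom2 (within-residue
#'   bonds; the backbone C->N peptide link between consecutive residues is
#'   implied). Defaults to the packaged set.
#' @return A `parameter_table` (list of the two data.frames). Per-residue
#'   charge sums are validated against `formal_charge` to 1e-3.
#' @export
load_parameter_table <- function(
    atoms_path = system.file("extdata", "minimal_params_atoms.tsv",
                             package = "sh3tools"),
    bonds_path = system.file("extdata", "minimal_params_bonds.tsv",
                             package = "sh3tools")) {
  atoms <- read_tsv(atoms_path)
  bonds <- read_tsv(bonds_path)
  for (rn in unique(atoms$resname)) {
    sub <- atoms[atoms$resname == rn, ]
    if (abs(sum(sub$charge) - sub$formal_charge[1]) > 1e-3)
      stop("charges of residue ", rn, " do not sum to its formal charge",
           call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds), class = "parameter_table")
}

# Breadth-first graph distances up to depth 3 from each atom.
bonded_neighbourhoods <- function(n_atoms, edges) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  dist12 <- vector("list", n_atoms)
  dist13 <- vector("list", n_atoms)
  dist14 <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) {
    d1 <- adj[[i]]
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    dist12[[i]] <- d1; dist13[[i]] <- d2; dist14[[i]] <- d3
  }
  list(d12 = dist12, d13 = dist13, d14 = dist14)
}

#' Assign parameters to a structure model
#'
#' Every atom receives a partial charge, LJ parameters and a GB radius;
#' exclusion (1-2, 1-3) and 1-4 scaling sets are derived from the bond
#' graph (within-residue bonds plus the peptide C-N link between
#' consecutive residue numbers on the same chain).
#'
#' @param model Atom table with coordinates (see [get_model()]).
#' @param table A [load_parameter_table()].
#' @return A `param_structure`: the model with parameter columns appended,
#'   plus `bonds` (edge matrix) and `excluded`/`scaled14` pair sets.
#' @export
assign_params <- function(model, table = load_parameter_table()) {
  key_tab <- paste(table$atoms$resname, table$atoms$atom)
  key_mod <- paste(model$resname, model$atom)
  idx <- match(key_mod, key_tab)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no parameters for atom ", model$atom[bad], " of residue ",
         model$resname[bad], " ", model$resnum[bad], call. = FALSE)
  }
  ps <- model
  ps$charge <- table$atoms$charge[idx]
  ps$lj_rmin2 <- table$atoms$lj_rmin2[idx]
  ps$lj_eps <- table$atoms$lj_eps[idx]
  ps$gb_radius <- table$atoms$gb_radius[idx]
  ps$gb_scale <- table$atoms$gb_scale[idx]

  # bond graph
  edges <- list()
  resk <- paste(model$chain, model$resnum)
  for (rk in unique(resk)) {
    sel <- which(resk == rk)
    rn <- model$resname[sel[1]]
    b <- table$bonds[table$bonds$resname == rn, ]
    for (q in seq_len(nrow(b))) {
      i <- sel[model$atom[sel] == b$atom1[q]]
      j <- sel[model$atom[sel] == b$atom2[q]]
      if (length(i) == 1L && length(j) == 1L)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  # peptide links
  for (ch in unique(model$chain)) {
    nums <- sort(unique(model$resnum[model$chain == ch]))
    for (k in seq_len(length(nums) - 1L)) {
      if (nums[k + 1L] != nums[k] + 1L) next
      i <- which(model$chain == ch & model$resnum == nums[k] & model$atom == "C")
      j <- which(model$chain == ch & model$resnum == nums[k + 1L] & model$atom == "N")
      if (length(i) == 1L && length(j) == 1L)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), ncol = 2)
  nb <- bonded_neighbourhoods(nrow(model), edges)
  structure(list(atoms = ps, bonds = edges, neighbours = nb),
            class = "param_structure")
}

#' Net charge of a parameterized structure
#' @param ps A `param_structure`.
#' @return Sum of partial charges.
#' @export
net_charge <- function(ps) sum(ps$atoms$charge)
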