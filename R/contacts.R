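# Interface contact detection, ensemble occupancy and pocket assignment.
#
# Geometric criteria stand in for an interface server's unpublished internal
# rules: hydrogen bonds by donor-heavy-to-acceptor distance (plus a D-H...A
# angle when explicit hydrogens are present), salt bridges between basic
# side-chain nitrogens and carboxylate oxygens, nonpolar contacts between
# apolar carbons. All cutoffs are configurable.

#' Contact criteria
#'
#' @param hbond_da_max Donor-to-acceptor heavy-atom cutoff, Angstrom.
#' @param hbond_angle_min Minimum D-H...A angle in degrees; applied only when
#'   explicit hydrogens exist in the structure (NMR-style models refined in
#'   explicit solvent typically carry them; heavy-atom input falls back to
#'   distance-only).
#' @param salt_no_max Basic-N to acidic-O cutoff, Angstrom.
#' @param nonpolar_cc_max Apolar carbon-carbon cutoff, Angstrom.
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(hbond_da_max = 3.5, hbond_angle_min = 120,
                             salt_no_max = 4.0, nonpolar_cc_max = 4.5) {
  stopifnot(hbond_da_max > 0, salt_no_max > 0, nonpolar_cc_max > 0)
  structure(list(hbond_da_max = hbond_da_max,
                 hbond_angle_min = hbond_angle_min,
                 salt_no_max = salt_no_max,
                 nonpolar_cc_max = nonpolar_cc_max),
            class = "contact_criteria")
}

KNOWN_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL")

# Side-chain donor atoms by residue; backbone N (except PRO) always donates.
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG")

# Side-chain acceptor atoms; backbone O always accepts.
SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

BASIC_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Carbons excluded from the apolar set: carbonyl/carboxylate/amide/guanidinium.
POLARIZED_C <- list(
  ALL = "C", ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = c("CD", "CZ"))

atom_in_set <- function(resname, atom, set_list) {
  base <- set_list[["ALL"]]
  per <- set_list[[resname]]
  atom %in% c(base, per)
}

classify_atoms <- function(model) {
  res <- model$resname
  unknown <- !(res %in% KNOWN_RESIDUES)
  if (any(unknown)) {
    warning("unknown residue name(s) excluded from contact typing: ",
            paste(unique(res[unknown]), collapse = ", "))
  }
  n <- nrow(model)
  donor <- acceptor <- basic <- acidic <- apolar <- logical(n)
  for (i in seq_len(n)) {
    if (unknown[i]) next
    r <- res[i]; a <- model$atom[i]; el <- model$element[i]
    donor[i] <- (a == "N" && r != "PRO") || a %in% SIDECHAIN_DONORS[[r]]
    acceptor[i] <- (a == "O" || a == "OXT") || a %in% SIDECHAIN_ACCEPTORS[[r]]
    basic[i] <- a %in% BASIC_N[[r]]
    acidic[i] <- a %in% ACIDIC_O[[r]]
    apolar[i] <- el == "C" && !atom_in_set(r, a, POLARIZED_C)
  }
  data.frame(donor = donor, acceptor = acceptor, basic = basic,
             acidic = acidic, apolar = apolar)
}

pair_distances <- function(A, B) {
  # |A| x |B| Euclidean distance matrix
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

contact_row <- function(kind, model, i, j, d, model_index) {
  data.frame(kind = kind,
             chain_a = model$chain[i], resnum_a = model$resnum[i],
             resname_a = model$resname[i], atom_a = model$atom[i],
             chain_b = model$chain[j], resnum_b = model$resnum[j],
             resname_b = model$resname[j], atom_b = model$atom[j],
             distance = d, model_index = model_index,
             stringsAsFactors = FALSE)
}

#' Detect interface contacts in one model
#'
#' Enumerates hydrogen bonds, salt bridges and nonpolar contacts between the
#' two sides of an interface partition. A pair inside both the hydrogen-bond
#' and salt-bridge criteria is reported under both kinds.
#'
#' @param model Atom table with coordinates (see [get_model()]).
#' @param criteria A [contact_criteria()].
#' @param partition Named list with elements `receptor` and `ligand`, each a
#'   character vector of chain identifiers.
#' @param model_index Index recorded in the output (bookkeeping only).
#' @return data.frame of contacts (kind, partner atoms, distance).
#' @export
detect_contacts <- function(model, criteria = contact_criteria(),
                            partition, model_index = 1L) {
  stopifnot(all(c("receptor", "ligand") %in% names(partition)))
  side_r <- model$chain %in% partition$receptor
  side_l <- model$chain %in% partition$ligand
  if (!any(side_r) || !any(side_l))
    stop("partition leaves one side empty", call. = FALSE)
  cls <- classify_atoms(model)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  has_h <- any(model$element == "H")
  heavy <- model$element != "H"

  idx_r <- which(side_r & heavy); idx_l <- which(side_l & heavy)
  D <- pair_distances(xyz[idx_r, , drop = FALSE], xyz[idx_l, , drop = FALSE])

  res <- list()
  add <- function(kind, ii, jj, dd) {
    if (length(ii))
      res[[length(res) + 1L]] <<- contact_row(kind, model, ii, jj, dd, model_index)
  }

  # hydrogen bonds (both donor->acceptor directions across the interface)
  hb_pairs <- function(don_idx, acc_idx, Dmat) {
    hit <- which(Dmat <= criteria$hbond_da_max, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    di <- don_idx[hit[, 1]]; aj <- acc_idx[hit[, 2]]
    keep <- rep(TRUE, length(di))
    if (has_h && !is.null(criteria$hbond_angle_min)) {
      for (k in seq_along(di)) {
        hs <- which(model$element == "H" &
                      model$chain == model$chain[di[k]] &
                      model$resnum == model$resnum[di[k]])
        if (!length(hs)) next
        hd <- pair_distances(xyz[hs, , drop = FALSE],
                             xyz[di[k], , drop = FALSE])
        hs <- hs[hd[, 1] < 1.25]
        if (!length(hs)) { keep[k] <- FALSE; next }
        ang <- max(vapply(hs, function(h) {
          v1 <- xyz[di[k], ] - xyz[h, ]; v2 <- xyz[aj[k], ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, numeric(1)))
        keep[k] <- ang >= criteria$hbond_angle_min
      }
    }
    list(i = di[keep], j = aj[keep],
         d = Dmat[hit[keep, , drop = FALSE]])
  }
  don_r <- idx_r[cls$donor[idx_r]]; acc_l <- idx_l[cls$acceptor[idx_l]]
  if (length(don_r) && length(acc_l)) {
    p <- hb_pairs(don_r, acc_l,
                  D[match(don_r, idx_r), match(acc_l, idx_l), drop = FALSE])
    if (!is.null(p)) add("hbond", p$i, p$j, p$d)
  }
  don_l <- idx_l[cls$donor[idx_l]]; acc_r <- idx_r[cls$acceptor[idx_r]]
  if (length(don_l) && length(acc_r)) {
    p <- hb_pairs(don_l, acc_r,
                  t(D)[match(don_l, idx_l), match(acc_r, idx_r), drop = FALSE])
    if (!is.null(p)) add("hbond", p$j, p$i, p$d)  # store receptor side as a
  }

  # salt bridges (either polarity)
  sb <- function(bas_idx, aci_idx, Dmat, flip) {
    hit <- which(Dmat <= criteria$salt_no_max, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    bi <- bas_idx[hit[, 1]]; aj <- aci_idx[hit[, 2]]
    if (flip) add("salt_bridge", aj, bi, Dmat[hit]) else
      add("salt_bridge", bi, aj, Dmat[hit])
  }
  bas_r <- idx_r[cls$basic[idx_r]]; aci_l <- idx_l[cls$acidic[idx_l]]
  if (length(bas_r) && length(aci_l))
    sb(bas_r, aci_l, D[match(bas_r, idx_r), match(aci_l, idx_l), drop = FALSE], FALSE)
  bas_l <- idx_l[cls$basic[idx_l]]; aci_r <- idx_r[cls$acidic[idx_r]]
  if (length(bas_l) && length(aci_r))
    sb(bas_l, aci_r, t(D)[match(bas_l, idx_l), match(aci_r, idx_r), drop = FALSE], TRUE)

  # nonpolar carbon-carbon
  ap_r <- idx_r[cls$apolar[idx_r]]; ap_l <- idx_l[cls$apolar[idx_l]]
  if (length(ap_r) && length(ap_l)) {
    Dn <- D[match(ap_r, idx_r), match(ap_l, idx_l), drop = FALSE]
    hit <- which(Dn <= criteria$nonpolar_cc_max, arr.ind = TRUE)
    if (nrow(hit))
      add("nonpolar", ap_r[hit[, 1]], ap_l[hit[, 2]], Dn[hit])
  }

  if (!length(res)) {
    return(data.frame(kind = character(0), chain_a = character(0),
                      resnum_a = integer(0), resname_a = character(0),
                      atom_a = character(0), chain_b = character(0),
                      resnum_b = integer(0), resname_b = character(0),
                      atom_b = character(0), distance = numeric(0),
                      model_index = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$kind, out$resnum_a, out$resnum_b, out$atom_a, out$atom_b), ]
  rownames(out) <- NULL
  out
}

#' Ensemble contact occupancy
#'
#' For every residue-pair interaction (kind, receptor residue, ligand
#' residue), the fraction of models in which at least one atom pair of that
#' kind satisfies the criteria. Occupancy bands follow the conventional
#' ensemble bookkeeping: conserved > 0.90, moderate 0.51-0.90, transient
#' 0.21-0.50, weak <= 0.20.
#'
#' @param ensemble A `structure_ensemble`.
#' @param criteria A [contact_criteria()].
#' @param partition See [detect_contacts()].
#' @return An `occupancy_table` data.frame: kind, residue identifiers on both
#'   sides, `n_present`, `occupancy`, `band`; attribute `n_models`.
#' @export
ensemble_occupancy <- function(ensemble, criteria = contact_criteria(),
                               partition) {
  nm <- n_models(ensemble)
  all_contacts <- do.call(rbind, lapply(seq_len(nm), function(k) {
    detect_contacts(get_model(ensemble, k), criteria, partition, model_index = k)
  }))
  if (is.null(all_contacts) || !nrow(all_contacts)) {
    out <- data.frame(kind = character(0), chain_a = character(0),
                      resnum_a = integer(0), resname_a = character(0),
                      chain_b = character(0), resnum_b = integer(0),
                      resname_b = character(0), n_present = integer(0),
                      occupancy = numeric(0), band = character(0))
    attr(out, "n_models") <- nm
    class(out) <- c("occupancy_table", "data.frame")
    return(out)
  }
  key <- with(all_contacts, paste(kind, chain_a, resnum_a, resname_a,
                                  chain_b, resnum_b, resname_b, sep = "|"))
  per_model <- unique(data.frame(key = key,
                                 model_index = all_contacts$model_index,
                                 stringsAsFactors = FALSE))
  counts <- table(per_model$key)
  info <- all_contacts[match(names(counts), key),
                       c("kind", "chain_a", "resnum_a", "resname_a",
                         "chain_b", "resnum_b", "resname_b")]
  out <- cbind(info,
               n_present = as.integer(counts),
               occupancy = as.numeric(counts) / nm)
  out$band <- occupancy_band(out$occupancy)
  out <- out[order(-out$occupancy, out$kind, out$resnum_a, out$resnum_b), ]
  rownames(out) <- NULL
  attr(out, "n_models") <- nm
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Band label for an occupancy fraction
#'
#' @param occupancy Numeric vector in \[0, 1\].
#' @return Character vector: `conserved` (> 0.90), `moderate` (0.51-0.90),
#'   `transient` (0.21-0.50), `weak` (<= 0.20).
#' @export
occupancy_band <- function(occupancy) {
  stopifnot(all(occupancy >= 0 & occupancy <= 1))
  ifelse(occupancy > 0.90, "conserved",
         ifelse(occupancy > 0.50, "moderate",
                ifelse(occupancy > 0.20, "transient", "weak")))
}

#' Assign ligand motif positions to receptor binding pockets
#'
#' Maps each ligand residue (labelled by its motif position relative to the
#' configured P0 residue) to the pocket(s) of the receptor residues it
#' contacts. Contacts to receptor residues absent from the map are labelled
#' `outside`.
#'
#' @param contacts data.frame from [detect_contacts()] or rows of an
#'   occupancy table (receptor side `a`, ligand side `b`).
#' @param pocket_map Named list: pocket label -> integer vector of receptor
#'   residue numbers. See [default_pocket_map()].
#' @param p0_resnum Ligand residue number corresponding to motif position 0.
#' @return data.frame with columns `ligand_resnum`, `motif_position`,
#'   `pocket` (one row per ligand residue/pocket combination).
#' @export
classify_pockets <- function(contacts, pocket_map = default_pocket_map(),
                             p0_resnum = NULL) {
  if (!nrow(contacts)) {
    return(data.frame(ligand_resnum = integer(0), motif_position = character(0),
                      pocket = character(0), stringsAsFactors = FALSE))
  }
  pocket_of <- function(resnum) {
    hits <- names(pocket_map)[vapply(pocket_map, function(v) resnum %in% v,
                                     logical(1))]
    if (!length(hits)) "outside" else hits
  }
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    pk <- pocket_of(contacts$resnum_a[i])
    for (p in pk) {
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_resnum = contacts$resnum_b[i],
        pocket = p, stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  out$motif_position <- if (is.null(p0_resnum)) NA_character_ else
    as.character(out$ligand_resnum - p0_resnum)
  out <- out[order(out$ligand_resnum, out$pocket),
             c("ligand_resnum", "motif_position", "pocket")]
  rownames(out) <- NULL
  out
}

#' Default receptor pocket map
#'
#' Receptor residue numbers (domain numbering) for the four ligand-binding
#' pockets of the lysine-anchored SH3 interface: the upstream/zero pocket
#' that receives acidic flanking elements, the first xP pocket, the second
#' (charged) xP pocket, and the third/specificity pocket.
#'
#' @return Named list of integer vectors.
#' @export
default_pocket_map <- function() {
  list(zero = c(25L, 26L),
       pocket1 = c(12L, 56L, 58L, 59L),
       pocket2 = c(14L, 17L, 43L),
       pocket3 = c(18L, 20L, 21L))
}

#' Write an occupancy table as TSV
#' @param occupancy An `occupancy_table`.
#' @param path Output path.
#' @export
write_occupancy_tsv <- function(occupancy, path) {
  write_tsv(as.data.frame(occupancy), path)
}
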