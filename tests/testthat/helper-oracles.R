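# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# Regex-based motif matcher: builds a lookahead regex from a pattern's
# allowed sets and reports all (overlapping) 1-based starts.
oracle_match_starts <- function(sequence, pattern = motif_pattern()) {
  classes <- vapply(pattern, function(set) {
    paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Brute-force all-atom-pair contact detection with plain loops.
oracle_contacts <- function(model, criteria, partition) {
  cls <- sh3tools:::classify_atoms(model)
  out <- list()
  n <- nrow(model)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!(model$chain[i] %in% partition$receptor)) next
      if (!(model$chain[j] %in% partition$ligand)) next
      if (model$element[i] == "H" || model$element[j] == "H") next
      d <- sqrt((model$x[i] - model$x[j])^2 + (model$y[i] - model$y[j])^2 +
                  (model$z[i] - model$z[j])^2)
      kinds <- character(0)
      if (d <= criteria$hbond_da_max &&
          ((cls$donor[i] && cls$acceptor[j]) ||
           (cls$donor[j] && cls$acceptor[i]))) kinds <- c(kinds, "hbond")
      if (d <= criteria$salt_no_max &&
          ((cls$basic[i] && cls$acidic[j]) ||
           (cls$basic[j] && cls$acidic[i]))) kinds <- c(kinds, "salt_bridge")
      if (d <= criteria$nonpolar_cc_max && cls$apolar[i] && cls$apolar[j])
        kinds <- c(kinds, "nonpolar")
      for (k in kinds) {
        out[[length(out) + 1L]] <- data.frame(
          kind = k, resnum_a = model$resnum[i], atom_a = model$atom[i],
          resnum_b = model$resnum[j], atom_b = model$atom[j],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$kind, res$resnum_a, res$resnum_b, res$atom_a, res$atom_b), ]
}

# Brute-force double-loop interface Coulomb + LJ sums over a parameterized
# structure (cross-partition pairs only).
oracle_interface_mm <- function(ps, ligand_chains, eps_int = 1) {
  a <- ps$atoms
  lig <- a$chain %in% ligand_chains
  elec <- 0; vdw <- 0
  for (i in which(!lig)) {
    for (j in which(lig)) {
      r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
      elec <- elec + 332.0636 * a$charge[i] * a$charge[j] / (eps_int * r)
      rmin <- a$lj_rmin2[i] + a$lj_rmin2[j]
      eps <- sqrt(a$lj_eps[i] * a$lj_eps[j])
      vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  c(elec = elec, vdw = vdw)
}

# Random peptide generator for property tests.
random_sequences <- function(n, len_range = c(12, 40), seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    # K/P/A/L/R-enriched alphabet so that matches actually occur
    alpha <- c(sh3tools:::AA_STANDARD, rep(c("P", "K", "A", "L", "R"), 4))
    vapply(seq_len(n), function(i) {
      L <- sample(len_range[1]:len_range[2], 1)
      paste(sample(alpha, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

toy_rigid_motion <- function(xyz, angle = 0.7, axis = c(1, 2, 2) / 3,
                             shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(xyz %*% t(R), 2, shift, `+`)
}
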