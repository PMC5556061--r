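# Interaction-energy decomposition in the single-trajectory GBSA style:
# gas-phase Coulomb + Lennard-Jones cross terms, generalized-Born (HCT
# pairwise descreening, Tsui-Case flavour) polar solvation with
# Debye-Hueckel salt screening, and a solvent-accessible-surface-area
# nonpolar term. Per-residue attribution splits every cross term half/half
# between the two partner residues, so residue contributions sum exactly to
# the total interaction energy.

COULOMB_K <- 332.0636  # kcal*A/(mol*e^2)

#' Energetics configuration
#'
#' @param interior_dielectric Solute dielectric (default 1.0).
#' @param solvent_dielectric Solvent dielectric (default 78.5).
#' @param ionic_strength Monovalent salt, mol/L (default 0.150); sets the
#'   Debye screening constant at 298 K.
#' @param surften Surface tension, kcal/mol/A^2 (default 0.0072).
#' @param surfoff SASA-term offset, kcal/mol (default 0).
#' @param gb_offset Intrinsic-radius offset, Angstrom (default 0.09).
#' @param probe_radius Solvent probe radius for SASA, Angstrom (default 1.4).
#' @param sphere_points Sphere-sampling points per atom (default 960).
#' @param scale14_elec,scale14_vdw 1-4 scaling factors (defaults 1/1.2, 1/2).
#' @return An `energetics_config` list (includes derived `kappa`, 1/A).
#' @export
energetics_config <- function(interior_dielectric = 1.0,
                              solvent_dielectric = 78.5,
                              ionic_strength = 0.150,
                              surften = 0.0072, surfoff = 0.0,
                              gb_offset = 0.09,
                              probe_radius = 1.4, sphere_points = 960,
                              scale14_elec = 1 / 1.2, scale14_vdw = 0.5) {
  stopifnot(interior_dielectric > 0, solvent_dielectric > 0,
            ionic_strength >= 0)
  # Debye length 3.04/sqrt(I) Angstrom for 1:1 electrolyte in water at 298 K
  kappa <- if (ionic_strength > 0) sqrt(ionic_strength) / 3.04 else 0
  structure(list(interior_dielectric = interior_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 ionic_strength = ionic_strength, kappa = kappa,
                 surften = surften, surfoff = surfoff,
                 gb_offset = gb_offset, probe_radius = probe_radius,
                 sphere_points = sphere_points,
                 scale14_elec = scale14_elec, scale14_vdw = scale14_vdw),
            class = "energetics_config")
}

#' Molecular-mechanics pair energy
#'
#' Coulomb (`332.0636 q_i q_j / (eps_int r)`) and 12-6 Lennard-Jones
#' (Lorentz-Berthelot-style Rmin/2 sum, geometric well depth) for one atom
#' pair of a parameterized structure. 1-2/1-3 pairs are excluded (error);
#' 1-4 pairs are scaled by the configured factors.
#'
#' @param ps A `param_structure` from [assign_params()].
#' @param i,j Atom indices.
#' @param config An [energetics_config()].
#' @return Named numeric vector `c(elec = , vdw = )`, kcal/mol.
#' @export
mm_pair_energy <- function(ps, i, j, config = energetics_config()) {
  a <- ps$atoms
  r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
  if (r == 0) stop("zero interatomic distance", call. = FALSE)
  if (j %in% ps$neighbours$d12[[i]] || j %in% ps$neighbours$d13[[i]])
    stop("pair ", i, "-", j, " is bonded-excluded (1-2/1-3)", call. = FALSE)
  s_e <- 1; s_v <- 1
  if (j %in% ps$neighbours$d14[[i]]) {
    s_e <- config$scale14_elec; s_v <- config$scale14_vdw
  }
  elec <- s_e * COULOMB_K * a$charge[i] * a$charge[j] /
    (config$interior_dielectric * r)
  rmin <- a$lj_rmin2[i] + a$lj_rmin2[j]
  eps <- sqrt(a$lj_eps[i] * a$lj_eps[j])
  sr6 <- (rmin / r)^6
  vdw <- s_v * eps * (sr6^2 - 2 * sr6)
  c(elec = elec, vdw = vdw)
}

# HCT pairwise-descreening effective Born radii.
# rho: intrinsic radii; scale: descreening factors; offset subtracted from
# intrinsic radii before integration. Non-positive inverse radii are clamped
# (warning) to a large radius.
born_radii <- function(xyz, rho, scale, offset = 0.09, clamp = 30) {
  n <- nrow(xyz)
  rhot <- rho - offset
  inv <- 1 / rhot
  if (n > 1L) {
    D <- pair_distances(xyz, xyz)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        r <- D[i, j]
        sj <- scale[j] * rhot[j]
        if (rhot[i] >= r + sj) next  # j fully inside i
        L <- max(rhot[i], abs(r - sj))
        U <- r + sj
        term <- 0.5 * ((1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
                         (1 / (2 * r)) * log(L / U) +
                         (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
        inv[i] <- inv[i] - term
      }
    }
  }
  bad <- inv <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive effective Born radii clamped to ",
            clamp, " A")
    inv[bad] <- 1 / clamp
  }
  1 / inv
}

# Generalized-Born polar solvation for one state.
# Returns total (kcal/mol) and a per-atom decomposition (pair terms split
# half/half; self terms whole) that sums exactly to the total.
gb_energy <- function(xyz, charges, radii, config) {
  n <- nrow(xyz)
  D <- if (n > 1L) pair_distances(xyz, xyz) else matrix(0, 1, 1)
  RR <- outer(radii, radii)
  fgb <- sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
  diag(fgb) <- radii
  tau <- COULOMB_K * (1 / config$interior_dielectric -
                        exp(-config$kappa * fgb) / config$solvent_dielectric)
  E <- -0.5 * tau * outer(charges, charges) / fgb
  per_atom <- rowSums(E)
  list(total = sum(E), per_atom = per_atom, radii = radii, fgb = fgb)
}

#' Generalized-Born polar solvation energy
#'
#' Effective Born radii by HCT pairwise descreening, energy by the canonical
#' GB cross term with Debye-Hueckel screening `exp(-kappa f_GB)` applied to
#' the solvent-dielectric part.
#'
#' @param ps A `param_structure`, or a data.frame with columns `x`, `y`,
#'   `z`, `charge`, `gb_radius`, `gb_scale`.
#' @param config An [energetics_config()].
#' @return List with `total` (kcal/mol), `per_atom` contributions, and the
#'   effective `radii`.
#' @export
gb_polar <- function(ps, config = energetics_config()) {
  a <- if (inherits(ps, "param_structure")) ps$atoms else ps
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- born_radii(xyz, a$gb_radius, a$gb_scale, offset = config$gb_offset)
  gb_energy(xyz, a$charge, radii, config)
}

# Golden-spiral unit sphere points.
sphere_grid <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA per atom with the configured probe radius and point
#' count. Atom radii are the LJ Rmin/2 values.
#'
#' @param ps A `param_structure`, or data.frame with `x`, `y`, `z` and
#'   `lj_rmin2` columns.
#' @param config An [energetics_config()].
#' @return Numeric vector of per-atom SASA, A^2.
#' @export
sasa_atoms <- function(ps, config = energetics_config()) {
  a <- if (inherits(ps, "param_structure")) ps$atoms else ps
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- a$lj_rmin2 + config$probe_radius
  n <- nrow(xyz)
  grid <- sphere_grid(config$sphere_points)
  D <- pair_distances(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < radii[i] + radii & seq_len(n) != i)
    pts <- sweep(grid * radii[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      d2 <- pair_distances(pts, xyz[nb, , drop = FALSE])
      exposed <- rowSums(d2 < rep(radii[nb], each = nrow(pts))) == 0L
    } else {
      exposed <- rep(TRUE, nrow(pts))
    }
    out[i] <- 4 * pi * radii[i]^2 * mean(exposed)
  }
  out
}

#' Nonpolar (SASA) solvation energy
#'
#' `surften * SASA + surfoff` over the whole structure.
#'
#' @inheritParams sasa_atoms
#' @return List with `total` (kcal/mol) and per-atom `sasa` (A^2).
#' @export
sasa_nonpolar <- function(ps, config = energetics_config()) {
  s <- sasa_atoms(ps, config)
  list(total = config$surften * sum(s) + config$surfoff, sasa = s)
}

#' Per-residue interaction-energy decomposition
#'
#' Single-trajectory interaction energy of a receptor-ligand partition,
#' `E(complex) - E(receptor) - E(ligand)`, over Coulomb, Lennard-Jones,
#' GB polar and SASA nonpolar components, decomposed per residue.
#' Cross-partition pair terms are attributed half to each partner residue;
#' the GB and SASA state differences decompose per atom by construction.
#'
#' @param model Atom table with coordinates (see [get_model()]).
#' @param ligand_chains Character vector of ligand chain identifiers; all
#'   other chains form the receptor.
#' @param config An [energetics_config()].
#' @param table A [load_parameter_table()].
#' @return An `energy_decomposition` data.frame: `chain`, `resnum`,
#'   `resname`, `side`, `elec`, `vdw`, `gb`, `sasa`, `total` (kcal/mol),
#'   with attribute `totals` (component totals).
#' @export
per_residue_decomposition <- function(model, ligand_chains,
                                      config = energetics_config(),
                                      table = load_parameter_table()) {
  is_lig <- model$chain %in% ligand_chains
  if (!any(is_lig)) stop("empty ligand selection", call. = FALSE)
  if (all(is_lig)) stop("empty receptor selection", call. = FALSE)
  ps <- assign_params(model, table)
  a <- ps$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  idx_r <- which(!is_lig); idx_l <- which(is_lig)

  # gas-phase cross terms (inter-chain pairs are never bonded-excluded)
  D <- pair_distances(xyz[idx_r, , drop = FALSE], xyz[idx_l, , drop = FALSE])
  qq <- outer(a$charge[idx_r], a$charge[idx_l])
  Eel <- COULOMB_K * qq / (config$interior_dielectric * D)
  rmin <- outer(a$lj_rmin2[idx_r], a$lj_rmin2[idx_l], `+`)
  epsm <- sqrt(outer(a$lj_eps[idx_r], a$lj_eps[idx_l]))
  sr6 <- (rmin / D)^6
  Evd <- epsm * (sr6^2 - 2 * sr6)
  elec_atom <- numeric(n); vdw_atom <- numeric(n)
  elec_atom[idx_r] <- rowSums(Eel) / 2; elec_atom[idx_l] <- colSums(Eel) / 2
  vdw_atom[idx_r] <- rowSums(Evd) / 2; vdw_atom[idx_l] <- colSums(Evd) / 2

  # GB: complex minus separated partitions
  gb_state <- function(sel) {
    radii <- born_radii(xyz[sel, , drop = FALSE], a$gb_radius[sel],
                        a$gb_scale[sel], offset = config$gb_offset)
    gb_energy(xyz[sel, , drop = FALSE], a$charge[sel], radii, config)$per_atom
  }
  gb_atom <- gb_state(seq_len(n))
  gb_atom[idx_r] <- gb_atom[idx_r] - gb_state(idx_r)
  gb_atom[idx_l] <- gb_atom[idx_l] - gb_state(idx_l)

  # SASA: complex minus separated partitions
  sasa_state <- function(sel) sasa_atoms(a[sel, , drop = FALSE], config)
  sasa_atom <- config$surften * sasa_state(seq_len(n))
  sasa_atom[idx_r] <- sasa_atom[idx_r] - config$surften * sasa_state(idx_r)
  sasa_atom[idx_l] <- sasa_atom[idx_l] - config$surften * sasa_state(idx_l)
  # per-state surfoff constants cancel to -surfoff; spread evenly over atoms
  sasa_atom <- sasa_atom - config$surfoff / n

  resk <- paste(a$chain, a$resnum)
  agg <- function(v) vapply(split(v, resk), sum, numeric(1))
  ord <- !duplicated(resk)
  keys <- resk[ord]
  out <- data.frame(chain = a$chain[ord], resnum = a$resnum[ord],
                    resname = a$resname[ord],
                    side = ifelse(is_lig[ord], "ligand", "receptor"),
                    elec = as.numeric(agg(elec_atom)[keys]),
                    vdw = as.numeric(agg(vdw_atom)[keys]),
                    gb = as.numeric(agg(gb_atom)[keys]),
                    sasa = as.numeric(agg(sasa_atom)[keys]),
                    stringsAsFactors = FALSE)
  out$total <- out$elec + out$vdw + out$gb + out$sasa
  out <- out[order(out$chain, out$resnum), ]
  rownames(out) <- NULL
  attr(out, "totals") <- c(elec = sum(out$elec), vdw = sum(out$vdw),
                           gb = sum(out$gb), sasa = sum(out$sasa),
                           total = sum(out$total))
  class(out) <- c("energy_decomposition", "data.frame")
  out
}

#' Ensemble-averaged per-residue decomposition
#'
#' Runs [per_residue_decomposition()] on every model of an ensemble and
#' reports the arithmetic mean and standard error of the mean per residue
#' and for the totals.
#'
#' @param ensemble A `structure_ensemble` (>= 2 models for a SEM).
#' @inheritParams per_residue_decomposition
#' @return data.frame with per-residue mean and SEM of each component;
#'   attributes `totals_mean` and `totals_sem`.
#' @export
ensemble_mmgbsa <- function(ensemble, ligand_chains,
                            config = energetics_config(),
                            table = load_parameter_table()) {
  nm <- n_models(ensemble)
  if (nm < 2L) stop("need >= 2 models for an ensemble mean +/- sem",
                    call. = FALSE)
  decs <- lapply(seq_len(nm), function(k) {
    per_residue_decomposition(get_model(ensemble, k), ligand_chains,
                              config, table)
  })
  base <- decs[[1]][, c("chain", "resnum", "resname", "side")]
  comp <- c("elec", "vdw", "gb", "sasa", "total")
  for (cc in comp) {
    m <- sapply(decs, function(d) d[[cc]])
    base[[paste0(cc, "_mean")]] <- rowMeans(m)
    base[[paste0(cc, "_sem")]] <- apply(m, 1, stats::sd) / sqrt(nm)
  }
  tot <- sapply(decs, function(d) attr(d, "totals")["total"])
  attr(base, "totals_mean") <- mean(tot)
  attr(base, "totals_sem") <- stats::sd(tot) / sqrt(nm)
  attr(base, "n_models") <- nm
  class(base) <- c("energy_decomposition_ensemble", "data.frame")
  base
}

#' Write a per-residue decomposition as TSV
#' @param decomposition An `energy_decomposition` (single-model or ensemble).
#' @param path Output path.
#' @export
write_decomposition_tsv <- function(decomposition, path) {
  write_tsv(as.data.frame(decomposition), path)
}
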