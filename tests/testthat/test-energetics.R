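ptab <- load_parameter_table()

test_that("parameter assignment validates charges and names failures", {
  # neutral glycine dipeptide: net charge 0
  gly2 <- data.frame(chain = "A", resnum = rep(1:2, each = 4),
                     resname = "GLY", atom = rep(c("N", "CA", "C", "O"), 2),
                     element = rep(c("N", "C", "C", "O"), 2),
                     x = seq(0, 7, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  ps <- assign_params(gly2, ptab)
  expect_equal(net_charge(ps), 0, tolerance = 1e-3)

  # charged side chains carry their formal charge
  tc <- toy_complex()
  lys <- tc$atoms[tc$atoms$chain == "B" & tc$atoms$resnum == 4, ]
  expect_equal(sum(assign_params(lys, ptab)$atoms$charge), 1, tolerance = 1e-3)
  glu <- tc$atoms[tc$atoms$chain == "A" & tc$atoms$resnum == 2, ]
  expect_equal(sum(assign_params(glu, ptab)$atoms$charge), -1, tolerance = 1e-3)

  bad <- gly2; bad$resname[1] <- "XYZ"
  expect_error(assign_params(bad, ptab), "XYZ")

  # peptide link makes N(i+1) a 1-2 and CA(i+1) a 1-3 neighbour of C(i)
  expect_true(5L %in% ps$neighbours$d12[[3]])
  expect_true(6L %in% ps$neighbours$d13[[3]])
})

test_that("mm_pair_energy reproduces closed forms", {
  d <- 3.320636
  m <- data.frame(chain = c("A", "B"), resnum = 1L, resname = "GLY",
                  atom = c("N", "N"), element = "N", x = c(0, d), y = 0, z = 0,
                  stringsAsFactors = FALSE)
  ps <- assign_params(m, ptab)
  ps$atoms$charge <- c(1, -1)
  e <- mm_pair_energy(ps, 1, 2)
  expect_equal(unname(e["elec"]), -100.0, tolerance = 0.01)

  # zero charge pair -> zero electrostatics
  ps$atoms$charge <- c(0, 0.5)
  expect_equal(unname(mm_pair_energy(ps, 1, 2)["elec"]), 0)

  # LJ minimum: at r = Rmin(i) + Rmin(j), vdw = -sqrt(eps_i eps_j)
  rmin <- 2 * ps$atoms$lj_rmin2[1]
  m2 <- m; m2$x <- c(0, rmin)
  ps2 <- assign_params(m2, ptab)
  expect_equal(unname(mm_pair_energy(ps2, 1, 2)["vdw"]),
               -ps2$atoms$lj_eps[1], tolerance = 1e-12)

  # excluded and coincident pairs error
  gly <- data.frame(chain = "A", resnum = 1L, resname = "GLY",
                    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                    x = c(0, 1.4, 2.4, 3), y = 0, z = 0, stringsAsFactors = FALSE)
  psg <- assign_params(gly, ptab)
  expect_error(mm_pair_energy(psg, 1, 2), "1-2/1-3")
  expect_error(mm_pair_energy(psg, 1, 3), "1-2/1-3")
})

test_that("1-4 pairs are scaled by the configured factors", {
  # LYS side chain: CB(5) CG(6) CD(7) CE(8) NZ(9); CB-CE is a 1-4 pair
  tc <- toy_complex()
  lys <- tc$atoms[tc$atoms$chain == "B" & tc$atoms$resnum == 4, ]
  ps <- assign_params(lys, ptab)
  i <- which(ps$atoms$atom == "CB"); j <- which(ps$atoms$atom == "CE")
  expect_true(j %in% ps$neighbours$d14[[i]])
  cfg1 <- energetics_config(scale14_elec = 1, scale14_vdw = 1)
  cfg2 <- energetics_config()  # 1/1.2 and 1/2
  ps$atoms$charge[c(i, j)] <- c(0.3, 0.3)
  e1 <- mm_pair_energy(ps, i, j, cfg1)
  e2 <- mm_pair_energy(ps, i, j, cfg2)
  expect_equal(e2[["elec"]], e1[["elec"]] / 1.2, tolerance = 1e-12)
  expect_equal(e2[["vdw"]], e1[["vdw"]] / 2, tolerance = 1e-12)
})

test_that("gb_polar reproduces the Born limit and additivity", {
  cfg0 <- energetics_config(ionic_strength = 0, gb_offset = 0)
  ion <- function(x, q, a) {
    data.frame(x = x, y = 0, z = 0, charge = q, gb_radius = a, gb_scale = 0.8)
  }
  # single ion: -166.0318 q^2 (1 - 1/eps) / a
  for (a in c(1.5, 2, 3)) {
    g <- gb_polar(ion(0, 1, a), cfg0)
    expect_equal(g$total, -0.5 * 332.0636 * (1 - 1 / 78.5) / a,
                 tolerance = 1e-9)
  }
  # two (effectively) infinitely separated ions: sum of Born self terms
  far <- rbind(ion(0, 1, 2), ion(1e6, -1, 1.5))
  g2 <- gb_polar(far, cfg0)
  self <- function(q, a) -0.5 * 332.0636 * (1 - 1 / 78.5) * q^2 / a
  expect_equal(g2$total, self(1, 2) + self(-1, 1.5), tolerance = 1e-3)

  # salt screening weakens the net electrostatic interaction of a charge
  # pair (Coulomb plus GB cross term, self energies removed)
  pair <- rbind(ion(0, 1, 2), ion(4, -1, 2))
  coul <- 332.0636 * 1 * -1 / 4
  interaction <- function(cfg) {
    g <- gb_polar(pair, cfg)
    radii <- g$radii
    selfsum <- sum(vapply(1:2, function(i) {
      gb_polar(pair[i, , drop = FALSE], cfg)$total
    }, numeric(1)))
    coul + (g$total - selfsum)
  }
  e0 <- interaction(cfg0)
  e1 <- interaction(energetics_config(ionic_strength = 0.15, gb_offset = 0))
  expect_lt(e0, 0)  # screened attraction remains attractive without salt
  expect_lte(abs(e1), abs(e0))
})

test_that("per-atom GB decomposition sums to the total", {
  tc <- toy_complex()
  ps <- assign_params(tc$atoms, ptab)
  g <- gb_polar(ps)
  expect_equal(sum(g$per_atom), g$total, tolerance = 1e-9)
})

test_that("SASA reproduces the isolated-sphere closed form and convergence", {
  cfg <- energetics_config()
  for (rho in c(1.5, 1.908)) {
    one <- data.frame(x = 0, y = 0, z = 0, lj_rmin2 = rho)
    s <- sasa_atoms(one, cfg)
    expect_equal(s, 4 * pi * (rho + 1.4)^2, tolerance = 0.01)
  }
  # fully buried atom has zero SASA
  shell_dirs <- sh3tools:::sphere_grid(60)
  buried <- rbind(
    data.frame(x = 0, y = 0, z = 0, lj_rmin2 = 1.5),
    data.frame(x = shell_dirs[, 1] * 2.2, y = shell_dirs[, 2] * 2.2,
               z = shell_dirs[, 3] * 2.2, lj_rmin2 = 2.0))
  expect_equal(sasa_atoms(buried, cfg)[1], 0)

  # doubling the sphere points moves the toy-complex SASA by < 1%
  tc <- toy_complex()
  ps <- assign_params(tc$atoms, ptab)
  s1 <- sum(sasa_atoms(ps, energetics_config(sphere_points = 960)))
  s2 <- sum(sasa_atoms(ps, energetics_config(sphere_points = 1920)))
  expect_lt(abs(s2 - s1) / s1, 0.01)
})

test_that("interface elec/vdw equal the brute-force pair-sum oracle", {
  tc <- toy_complex()
  dec <- per_residue_decomposition(tc$atoms, "B")
  ps <- assign_params(tc$atoms, ptab)
  ref <- oracle_interface_mm(ps, "B")
  tot <- attr(dec, "totals")
  expect_equal(unname(tot["elec"]), unname(ref["elec"]), tolerance = 1e-6)
  expect_equal(unname(tot["vdw"]), unname(ref["vdw"]), tolerance = 1e-6)
})

test_that("decomposition conserves every component and honours nulls", {
  tc <- toy_complex()
  dec <- per_residue_decomposition(tc$atoms, "B")
  tot <- attr(dec, "totals")
  for (cc in c("elec", "vdw", "gb", "sasa", "total")) {
    expect_equal(sum(dec[[cc]]), unname(tot[cc]), tolerance = 1e-6)
  }
  expect_error(per_residue_decomposition(tc$atoms, "Z"), "ligand")

  # zeroing ligand charges and LJ wells removes elec and vdw exactly
  tab0 <- load_parameter_table()
  m <- tc$atoms
  dec0 <- local({
    # neutral ghost ligand: copy the table with zero charge/eps for chain B
    ps <- assign_params(m, tab0)
    ps$atoms$charge[ps$atoms$chain == "B"] <- 0
    ps$atoms$lj_eps[ps$atoms$chain == "B"] <- 0
    ref <- oracle_interface_mm(ps, "B")
    ref
  })
  expect_equal(unname(dec0["elec"]), 0)
  expect_equal(unname(dec0["vdw"]), 0)
})

test_that("charge-neutralized central lysine loses attraction", {
  tc <- toy_complex()
  dec <- per_residue_decomposition(tc$atoms, "B")
  k_row <- dec[dec$chain == "B" & dec$resnum == 4, ]
  # neutralize the lysine ammonium group
  tab2 <- load_parameter_table()
  sel <- tab2$atoms$resname == "LYS" & tab2$atoms$atom %in% c("CE", "NZ")
  tab2$atoms$charge[sel] <- 0
  tab2$atoms$formal_charge[tab2$atoms$resname == "LYS"] <- 0
  dec2 <- per_residue_decomposition(tc$atoms, "B", table = tab2)
  k2_row <- dec2[dec2$chain == "B" & dec2$resnum == 4, ]
  expect_lt(k_row$total, k2_row$total)
})

test_that("central lysine is the top attractive ligand contribution", {
  tc <- toy_complex()
  dec <- per_residue_decomposition(tc$atoms, "B")
  lig <- dec[dec$side == "ligand", ]
  expect_equal(lig$resnum[which.min(lig$total)], 4L)
  expect_lt(min(lig$total), 0)
})

test_that("ensemble mean and sem behave as frozen arithmetic dictates", {
  ge <- gen_complex_ensemble(n_models = 4, jitter_sd = 0, seed = 2)
  em <- ensemble_mmgbsa(ge$ensemble, "B")
  expect_equal(unname(attr(em, "totals_sem")), 0, tolerance = 1e-9)
  expect_true(all(abs(em$total_sem) < 1e-9))

  # jittered ensemble mean stays near the template value
  gj <- gen_complex_ensemble(n_models = 10, jitter_sd = 0.05, seed = 6)
  ej <- ensemble_mmgbsa(gj$ensemble, "B")
  tpl <- attr(per_residue_decomposition(toy_complex()$atoms, "B"), "totals")
  expect_equal(unname(attr(ej, "totals_mean")), unname(tpl["total"]),
               tolerance = 0.15 * abs(tpl["total"]))
  expect_error(ensemble_mmgbsa(gen_complex_ensemble(n_models = 1,
                                                    jitter_sd = 0)$ensemble,
                               "B"), ">= 2 models")
})
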