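test_that("multi-MODEL PDB writing and loading round-trips", {
  ge <- gen_complex_ensemble(n_models = 40, jitter_sd = 0.3, seed = 1)
  pdb <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ge$ensemble, pdb)
  ens <- load_ensemble(pdb)
  expect_equal(n_models(ens), 40)
  expect_identical(ens$atoms, ge$ensemble$atoms)
  expect_equal(ens$coords, ge$ensemble$coords, tolerance = 1e-3)

  # single-model file (no MODEL records) -> ensemble of one
  one <- gen_complex_ensemble(n_models = 1, jitter_sd = 0, seed = 1)
  pdb1 <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(one$ensemble, pdb1)
  expect_equal(n_models(load_ensemble(pdb1)), 1)

  # truncated file is a format error
  lines <- readLines(pdb)
  trunc <- tempfile(fileext = ".pdb")
  writeLines(lines[-grep("^ENDMDL", lines)[40]], trunc)
  expect_error(load_ensemble(trunc), "truncated|inconsistent")

  # inconsistent atom inventory names the model
  bad <- lines
  atom_lines <- grep("^ATOM", bad)
  bad <- bad[-atom_lines[length(atom_lines)]]  # drop an atom of model 40
  badf <- tempfile(fileext = ".pdb")
  writeLines(bad, badf)
  expect_error(load_ensemble(badf), "model 40")
})

test_that("strip_linker removes a residue range from every model", {
  ge <- gen_complex_ensemble(n_models = 5, jitter_sd = 0.1, seed = 3)
  ens <- ge$ensemble
  stripped <- strip_linker(ens, 5:7, chain = "B")
  expect_false(any(stripped$atoms$chain == "B" & stripped$atoms$resnum %in% 5:7))
  expect_equal(n_models(stripped), 5)
  # identity on empty range
  expect_identical(strip_linker(ens, integer(0)), ens)
  # removing everything is an error
  expect_error(strip_linker(ens, 1:8, chain = c("A", "B")), "every atom")
  # contacts never involve stripped residues
  ct <- detect_contacts(get_model(strip_linker(ens, 8, chain = "B"), 1),
                        partition = ge$partition)
  expect_false(any(ct$chain_b == "B" & ct$resnum_b == 8))
})

test_that("detect_contacts matches a two-residue toy and cutoff logic", {
  mk <- function(d) {
    data.frame(chain = c("A", "B"), resnum = c(1L, 1L),
               resname = c("GLU", "LYS"), atom = c("OE1", "NZ"),
               element = c("O", "N"), x = c(0, d), y = 0, z = 0,
               stringsAsFactors = FALSE)
  }
  ct <- detect_contacts(mk(2.9), partition = list(receptor = "A", ligand = "B"))
  expect_setequal(ct$kind, c("hbond", "salt_bridge"))
  expect_equal(unique(ct$distance), 2.9, tolerance = 1e-9)
  ct6 <- detect_contacts(mk(6.0), partition = list(receptor = "A", ligand = "B"))
  expect_equal(nrow(ct6), 0)
  # unknown residue names are excluded with a warning, not an error
  m <- mk(2.9); m$resname[2] <- "XYZ"
  expect_warning(ct_u <- detect_contacts(m, partition = list(receptor = "A",
                                                             ligand = "B")),
                 "unknown residue")
  expect_false("salt_bridge" %in% ct_u$kind)
})

test_that("detect_contacts equals the brute-force all-pairs oracle", {
  crit <- contact_criteria()
  tc <- toy_complex()
  models <- list(tc$atoms)
  ge <- gen_complex_ensemble(n_models = 3, jitter_sd = 0.6, seed = 17)
  for (k in 1:3) models[[k + 1]] <- get_model(ge$ensemble, k)
  for (m in models) {
    got <- detect_contacts(m, crit, tc$partition)
    got <- got[order(got$kind, got$resnum_a, got$resnum_b, got$atom_a,
                     got$atom_b), c("kind", "resnum_a", "atom_a", "resnum_b",
                                    "atom_b", "distance")]
    rownames(got) <- NULL
    ref <- oracle_contacts(m, crit, tc$partition)
    rownames(ref) <- NULL
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("planted toy contacts are all detected", {
  tc <- toy_complex()
  ct <- detect_contacts(tc$atoms, partition = tc$partition)
  pk <- with(tc$planted_contacts, paste(kind, resnum_a, resnum_b))
  dk <- paste(ct$kind, ct$resnum_a, ct$resnum_b)
  expect_true(all(pk %in% dk))
})

test_that("ensemble occupancy counts models exactly and bands are correct", {
  ge <- gen_complex_ensemble(n_models = 10, jitter_sd = 0, seed = 1)
  ens <- ge$ensemble
  # jitter 0: every planted contact occupied in all models
  occ <- ensemble_occupancy(ens, partition = ge$partition)
  key <- paste(occ$kind, occ$resnum_a, occ$resnum_b)
  pk <- with(ge$truth$planted_contacts, paste(kind, resnum_a, resnum_b))
  expect_true(all(pk %in% key))
  expect_true(all(occ$occupancy[key %in% pk] == 1))
  expect_true(all(occ$band[key %in% pk] == "conserved"))

  # break the salt bridge in chosen models by displacing the lysine NZ
  nz <- which(ens$atoms$chain == "B" & ens$atoms$resnum == 4 &
                ens$atoms$atom == "NZ")
  ens9 <- ens; ens9$coords[nz, 2, 10] <- 100
  occ9 <- ensemble_occupancy(ens9, partition = ge$partition)
  row9 <- occ9[occ9$kind == "salt_bridge" & occ9$resnum_b == 4, ]
  expect_equal(row9$occupancy, 0.9)
  expect_equal(row9$band, "moderate")

  ens3 <- ens; ens3$coords[nz, 2, 4:10] <- 100
  occ3 <- ensemble_occupancy(ens3, partition = ge$partition)
  row3 <- occ3[occ3$kind == "salt_bridge" & occ3$resnum_b == 4, ]
  expect_equal(row3$occupancy, 0.3)
  expect_equal(row3$band, "transient")
})

test_that("occupancy is monotone non-increasing as cutoffs shrink", {
  ge <- gen_complex_ensemble(n_models = 20, jitter_sd = 0.5, seed = 9)
  loose <- contact_criteria()
  tight <- contact_criteria(hbond_da_max = 3.0, salt_no_max = 3.4,
                            nonpolar_cc_max = 4.0)
  o_loose <- ensemble_occupancy(ge$ensemble, loose, ge$partition)
  o_tight <- ensemble_occupancy(ge$ensemble, tight, ge$partition)
  expect_true(all(o_loose$occupancy >= 0 & o_loose$occupancy <= 1))
  kl <- paste(o_loose$kind, o_loose$resnum_a, o_loose$resnum_b)
  kt <- paste(o_tight$kind, o_tight$resnum_a, o_tight$resnum_b)
  common <- intersect(kl, kt)
  expect_true(all(o_tight$occupancy[match(common, kt)] <=
                    o_loose$occupancy[match(common, kl)]))
  expect_true(all(kt %in% kl))
})

test_that("occupancy_band implements the stated bands", {
  expect_equal(occupancy_band(c(0.95, 0.9, 0.51, 0.5, 0.21, 0.2, 0)),
               c("conserved", "moderate", "moderate", "transient",
                 "transient", "weak", "weak"))
})

test_that("classify_pockets maps ligand positions through receptor contacts", {
  tc <- toy_complex()
  ct <- detect_contacts(tc$atoms, partition = tc$partition)
  pm <- list(pocket2 = 2L, pocket1 = 4L, pocket3 = 6L)
  pa <- classify_pockets(ct, pm, p0_resnum = tc$p0_resnum)
  # central lysine (B4, position +2) contacts the glutamate pocket
  expect_true(any(pa$ligand_resnum == 4 & pa$pocket == "pocket2"))
  expect_equal(unique(pa$motif_position[pa$ligand_resnum == 4]), "2")
  # leucine +6 contacts receptor Arg6 -> pocket3
  expect_true(any(pa$ligand_resnum == 8 & pa$pocket == "pocket3"))
  # unmapped receptor residues label as outside
  pa2 <- classify_pockets(ct, list(pocket1 = 99L), p0_resnum = 2L)
  expect_true(all(pa2$pocket == "outside"))
  # no contacts -> empty assignment
  expect_equal(nrow(classify_pockets(ct[0, ], pm)), 0)
})

test_that("backbone RMSD is zero on identity and invariant to rigid motions", {
  ge <- gen_complex_ensemble(n_models = 2, jitter_sd = 0.4, seed = 5)
  m1 <- get_model(ge$ensemble, 1)
  m2 <- get_model(ge$ensemble, 2)
  expect_equal(backbone_rmsd(m1, m1, 1:7, chain = "A"), 0, tolerance = 1e-9)

  m1r <- m1
  m1r[, c("x", "y", "z")] <- toy_rigid_motion(as.matrix(m1[, c("x", "y", "z")]))
  expect_equal(backbone_rmsd(m1, m1r, 1:7, chain = "A"), 0, tolerance = 1e-6)

  r12 <- backbone_rmsd(m1, m2, 1:7, chain = "A")
  expect_gt(r12, 0)
  # symmetry and invariance of either argument under rigid motion
  expect_equal(backbone_rmsd(m2, m1, 1:7, chain = "A"), r12, tolerance = 1e-6)
  m2r <- m2
  m2r[, c("x", "y", "z")] <- toy_rigid_motion(as.matrix(m2[, c("x", "y", "z")]),
                                              angle = 1.2, shift = c(-8, 1, 4))
  expect_equal(backbone_rmsd(m1, m2r, 1:7, chain = "A"), r12, tolerance = 1e-6)

  # disabled superposition: uniform +1 A x-shift gives exactly 1.0
  m1s <- m1; m1s$x <- m1s$x + 1
  expect_equal(backbone_rmsd(m1, m1s, 1:7, chain = "A", superpose = FALSE), 1)

  expect_error(backbone_rmsd(m1, m2, 1:9, chain = "A"), "missing")
})

test_that("relative CSP normalizes to unit standard deviation", {
  free <- data.frame(residue = 1:10, H_ppm = 8 + (1:10) / 100,
                     N_ppm = 115 + (1:10) / 10)
  bound <- free
  bound$H_ppm[4] <- bound$H_ppm[4] + 0.1
  bound$N_ppm[4] <- bound$N_ppm[4] + 0.5
  bound$H_ppm[7] <- bound$H_ppm[7] + 0.03
  out <- relative_csp(free, bound)
  expect_equal(out$csp[4], sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(sd(out$relative_csp), 1, tolerance = 1e-9)
  expect_false(attr(out, "degenerate"))

  same <- relative_csp(free, free)
  expect_true(attr(same, "degenerate"))
  expect_true(all(same$relative_csp == 0))

  expect_error(relative_csp(free[1:2, ], bound[1:2, ]), "at least 3")
})
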