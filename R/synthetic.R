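# Seeded synthetic-data generators with machine-readable truth tables.
# Every generator is deterministic under (seed, parameters) and leaves the
# caller's RNG state untouched.

#' Fixture registry of one-site binding parameters
#'
#' Ground-truth thermodynamic parameters for the four core octapeptides used
#' throughout the test fixtures: measured dissociation constants with
#' equimolar stoichiometry, and package-chosen exothermic binding enthalpies
#' typical of SH3-polyproline recognition.
#'
#' @return data.frame with columns `peptide`, `kd_um`, `dh_kcal_mol`, `n`.
#' @export
binding_truth_registry <- function() {
  data.frame(
    peptide = c("PPPKPPRL", "APPKPPLP", "PPSKPPRP", "PPSKPPLP"),
    kd_um = c(5.29, 15.70, 15.29, 46.65),
    dh_kcal_mol = c(-8.6, -7.4, -7.9, -6.8),
    n = c(1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Fixture registry of displacement-curve parameters
#'
#' Ground truth for the phage clone-1 competitive displacement readout:
#' half-maximal competitor concentration 363 nM, with plate-reader-scale
#' absorbance plateaus and a unit Hill slope.
#'
#' @return data.frame with columns `clone`, `ec50_nm`, `top`, `bottom`,
#'   `hill`.
#' @export
elisa_truth_registry <- function() {
  data.frame(clone = "clone1", ec50_nm = 363, top = 1.2, bottom = 0.05,
             hill = 1.0, stringsAsFactors = FALSE)
}

#' Competitor dose ladder in nanomolar
#'
#' Log-spaced dose series emulating a serial dilution of the free competitor
#' domain from `from_ugml` to `to_ugml` (default 1-800 micrograms/ml of a
#' 34 kDa GST-fusion construct), converted to molar units.
#'
#' @param n_points Number of doses (default 12).
#' @param from_ugml,to_ugml Mass-concentration range, micrograms/ml.
#' @param mw_kda Molecular weight of the competitor, kDa (default 34).
#' @return Strictly increasing numeric vector of doses in nM.
#' @export
displacement_doses_nm <- function(n_points = 12, from_ugml = 1,
                                  to_ugml = 800, mw_kda = 34) {
  ugml <- exp(seq(log(from_ugml), log(to_ugml), length.out = n_points))
  ugml / mw_kda * 1000  # ug/ml / (kg/mol) -> nmol/L
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

sample_residues <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Sample one pattern-conforming 8-residue core; with a PFM, residues are
# drawn from the column probabilities restricted to the allowed sets.
sample_core <- function(pattern, pfm = NULL) {
  chars <- vapply(seq_len(8), function(k) {
    allowed <- pattern[[k]]
    if (is.null(pfm)) {
      sample(allowed, 1)
    } else {
      p <- pfm[k, allowed]
      sample(allowed, 1, prob = p / sum(p))
    }
  }, character(1))
  paste(chars, collapse = "")
}

#' Generate a motif-bearing peptide library
#'
#' `n` 12-mers, each containing exactly one pattern-conforming core at a
#' random offset; flanking residues are drawn from the background
#' composition, with rejection so that no accidental second core arises.
#'
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param pattern A [motif_pattern()].
#' @param pfm Optional PFM biasing the core residue draws.
#' @param peptide_length Total length (default 12).
#' @param background Residue frequencies for flanks.
#' @return data.frame with columns `id`, `sequence`, `core_start` (the truth
#'   table); attribute `seed`.
#' @export
gen_peptide_library <- function(n, seed = 1L, pattern = motif_pattern(),
                                pfm = NULL, peptide_length = 12,
                                background = swissprot_background()) {
  stopifnot(n >= 1, peptide_length >= 8)
  out <- with_seed(seed, {
    res <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        core <- sample_core(pattern, pfm)
        off <- sample.int(peptide_length - 7L, 1)
        nl <- off - 1L
        nr <- peptide_length - 8L - nl
        seq_i <- paste0(
          paste(sample_residues(nl, background), collapse = ""),
          core,
          paste(sample_residues(nr, background), collapse = ""))
        if (identical(locate_core(seq_i, pattern), off)) break
      }
      res[[i]] <- data.frame(id = sprintf("pep%02d", i), sequence = seq_i,
                             core_start = off, stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic proteome with planted motifs
#'
#' Background residues are drawn from a SwissProt-like composition;
#' `n_plants` pattern-conforming cores are planted at random positions in
#' random records. With `reject_accidental = TRUE` (default), background
#' windows that accidentally satisfy the pattern are disrupted (the +2
#' position mutated away from lysine), so the truth table is exhaustive.
#'
#' @param n_records Number of protein records.
#' @param n_plants Number of planted motif cores.
#' @param seed Integer seed.
#' @param length_range Record length range (uniform; default 150-400).
#' @param pattern A [motif_pattern()].
#' @param background Residue frequencies.
#' @param reject_accidental Disrupt accidental background cores.
#' @return List with `records` (data.frame id/description/sequence) and
#'   `truth` (data.frame record_id/start/window); attribute `seed`.
#' @export
gen_proteome <- function(n_records = 50, n_plants = 10, seed = 1L,
                         length_range = c(150L, 400L),
                         pattern = motif_pattern(),
                         background = swissprot_background(),
                         reject_accidental = TRUE) {
  stopifnot(n_records >= 1, n_plants >= 0)
  result <- with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_records, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample_residues(L, background), collapse = ""), character(1))
    ids <- sprintf("SYN%04d", seq_len(n_records))

    truth <- data.frame(record_id = character(0), start = integer(0),
                        window = character(0), stringsAsFactors = FALSE)
    if (n_plants > 0) {
      rec_pick <- sample(rep_len(seq_len(n_records), max(n_plants, n_records)),
                         n_plants)
      for (p in seq_len(n_plants)) {
        r <- rec_pick[p]
        repeat {
          s <- sample.int(nchar(seqs[r]) - 7L, 1)
          # avoid overlapping a previous plant in the same record
          prev <- truth$start[truth$record_id == ids[r]]
          if (!length(prev) || all(abs(prev - s) >= 8L)) break
        }
        core <- sample_core(pattern)
        substr(seqs[r], s, s + 7L) <- core
        truth <- rbind(truth, data.frame(record_id = ids[r], start = s,
                                         window = core,
                                         stringsAsFactors = FALSE))
      }
    }
    if (reject_accidental) {
      non_k <- setdiff(AA_STANDARD, c("K", "R"))
      for (r in seq_len(n_records)) {
        guard <- 0L
        repeat {
          hits <- locate_core(seqs[r], pattern)
          planted <- truth$start[truth$record_id == ids[r]]
          accid <- setdiff(hits, planted)
          if (!length(accid) || guard > 50L) break
          for (s in accid) {
            substr(seqs[r], s + 3L, s + 3L) <- sample(non_k, 1)
          }
          guard <- guard + 1L
        }
      }
    }
    truth <- truth[order(truth$record_id, truth$start), , drop = FALSE]
    # re-read planted windows (a plant may sit inside a mutated region only
    # if overlapping, which the placement loop forbids)
    truth$window <- vapply(seq_len(nrow(truth)), function(k) {
      r <- match(truth$record_id[k], ids)
      substr(seqs[r], truth$start[k], truth$start[k] + 7L)
    }, character(1))
    list(records = data.frame(id = ids,
                              description = paste("synthetic record", seq_len(n_records)),
                              sequence = seqs, stringsAsFactors = FALSE),
         truth = truth)
  })
  attr(result, "seed") <- seed
  result
}

#' Write protein records as FASTA
#'
#' @param records data.frame with `id`, `sequence` (optional `description`).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_proteome_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[i],
                  if ("description" %in% names(records) &&
                      nzchar(records$description[i]))
                    paste0(" ", records$description[i]) else "")
    writeLines(hdr, con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---- toy complex template -------------------------------------------------

toy_atom <- function(chain, resnum, resname, atom, x, y, z) {
  data.frame(chain = chain, resnum = as.integer(resnum), resname = resname,
             atom = atom,
             element = substr(atom, 1, 1), x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

toy_backbone <- function(chain, resnum, resname, x0, y0, flip = FALSE) {
  s <- if (flip) 1 else -1  # side chains (and carbonyls) away from interface
  rbind(toy_atom(chain, resnum, resname, "N", x0 - 1.2, y0 + 0.6 * s, 0.3),
        toy_atom(chain, resnum, resname, "CA", x0, y0, 0),
        toy_atom(chain, resnum, resname, "C", x0 + 1.2, y0 + 0.4 * s, -0.3),
        toy_atom(chain, resnum, resname, "O", x0 + 1.6, y0 + 1.3 * s, -0.4))
}

#' Hand-built toy receptor-ligand complex
#'
#' A minimal heavy-atom complex used as the structural fixture template: a
#' seven-residue receptor strand (chain A, Gly-Glu-Gly-Trp-Gly-Arg-Gly)
#' presenting glutamate, tryptophan and arginine side chains opposite an
#' eight-residue PPPKPPRL ligand (chain B, residue 4 = the central lysine,
#' motif position +2), with one planted salt bridge (Lys4 NZ to Glu2 OE1,
#' 2.9 A), one hydrogen bond (Arg6 NH1 to Leu8 backbone O, 3.0 A) and
#' nonpolar contacts from the two prolines flanking the tryptophan ring
#' (Pro5/Pro6 to Trp4, within 3.8-3.9 A). The geometry is schematic
#' (no physical realism is claimed): only interface distances are
#' meaningful.
#'
#' @return List with `atoms` (coordinate table), `partition` (receptor/
#'   ligand chains), `p0_resnum` (ligand residue at motif position 0) and
#'   `planted_contacts` (data.frame of the three planted interactions).
#' @export
toy_complex <- function() {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  # receptor chain A: G E G W G R G at x = 3.8 * resnum, side chains +y
  rec_seq <- c("GLY", "GLU", "GLY", "TRP", "GLY", "ARG", "GLY")
  for (i in seq_along(rec_seq)) {
    x0 <- 3.8 * i
    add(toy_backbone("A", i, rec_seq[i], x0, 0, flip = FALSE))
  }
  add(toy_atom("A", 2, "GLU", "CB", 7.6, 1.4, 0.2))
  add(toy_atom("A", 2, "GLU", "CG", 7.6, 2.7, -0.2))
  add(toy_atom("A", 2, "GLU", "CD", 7.6, 3.9, 0.1))
  add(toy_atom("A", 2, "GLU", "OE1", 7.6, 4.9, 0.0))
  add(toy_atom("A", 2, "GLU", "OE2", 8.6, 4.3, 0.4))
  add(toy_atom("A", 4, "TRP", "CB", 15.2, 1.4, 0.2))
  add(toy_atom("A", 4, "TRP", "CG", 15.2, 2.6, -0.1))
  add(toy_atom("A", 4, "TRP", "CD1", 16.2, 3.3, -0.3))
  add(toy_atom("A", 4, "TRP", "CD2", 14.2, 3.4, 0.0))
  add(toy_atom("A", 4, "TRP", "NE1", 16.0, 4.5, -0.3))
  add(toy_atom("A", 4, "TRP", "CE2", 14.8, 4.6, -0.1))
  add(toy_atom("A", 4, "TRP", "CE3", 12.9, 3.3, 0.2))
  add(toy_atom("A", 4, "TRP", "CZ2", 14.1, 5.7, 0.0))
  add(toy_atom("A", 4, "TRP", "CZ3", 12.2, 4.4, 0.3))
  add(toy_atom("A", 4, "TRP", "CH2", 12.8, 5.6, 0.2))
  add(toy_atom("A", 6, "ARG", "CB", 22.8, 1.3, 0.3))
  add(toy_atom("A", 6, "ARG", "CG", 22.8, 2.6, -0.2))
  add(toy_atom("A", 6, "ARG", "CD", 23.3, 3.6, 0.5))
  add(toy_atom("A", 6, "ARG", "NE", 23.6, 4.3, -0.2))
  add(toy_atom("A", 6, "ARG", "CZ", 24.1, 4.6, 0.5))
  add(toy_atom("A", 6, "ARG", "NH1", 24.4, 4.5, -0.4))
  add(toy_atom("A", 6, "ARG", "NH2", 25.4, 4.0, 0.9))

  # ligand chain B: P P P K P P R L at x = 3.8 * resnum - 7.6, y = 8.6,
  # carbonyl O pointing away from the interface except Leu8
  lig_seq <- c("PRO", "PRO", "PRO", "LYS", "PRO", "PRO", "ARG", "LEU")
  for (i in seq_along(lig_seq)) {
    x0 <- 3.8 * i - 7.6
    add(toy_backbone("B", i, lig_seq[i], x0, 8.6, flip = TRUE))
  }
  # Leu8 carbonyl O re-pointed toward Arg6 NH1 (planted H-bond, 3.0 A)
  pro_side <- function(resnum) {
    x0 <- 3.8 * resnum - 7.6
    rbind(toy_atom("B", resnum, "PRO", "CB", x0 + 0.6, 9.4, 0.6),
          toy_atom("B", resnum, "PRO", "CG", x0 + 0.3, 10.4, 1.4),
          toy_atom("B", resnum, "PRO", "CD", x0 - 0.8, 9.6, 0.9))
  }
  add(pro_side(1)); add(pro_side(2)); add(pro_side(3)); add(pro_side(5))
  # Pro6 ring lowered toward Trp (planted nonpolar contact via CG)
  add(toy_atom("B", 6, "PRO", "CB", 15.8, 9.6, 0.7))
  add(toy_atom("B", 6, "PRO", "CG", 14.1, 9.5, 0.0))
  add(toy_atom("B", 6, "PRO", "CD", 13.9, 9.8, 1.1))
  # Lys4 side chain descending to NZ above Glu2 OE1 (planted salt bridge)
  add(toy_atom("B", 4, "LYS", "CB", 8.3, 8.2, 1.2))
  add(toy_atom("B", 4, "LYS", "CG", 8.9, 7.8, 2.4))
  add(toy_atom("B", 4, "LYS", "CD", 8.5, 7.9, 3.8))
  add(toy_atom("B", 4, "LYS", "CE", 7.7, 8.0, 1.3))
  add(toy_atom("B", 4, "LYS", "NZ", 7.6, 7.8, 0.0))
  add(toy_atom("B", 7, "ARG", "CB", 19.6, 9.5, 0.5))
  add(toy_atom("B", 7, "ARG", "CG", 19.3, 10.6, 1.3))
  add(toy_atom("B", 7, "ARG", "CD", 19.9, 11.5, 0.6))
  add(toy_atom("B", 7, "ARG", "NE", 19.6, 12.5, 1.2))
  add(toy_atom("B", 7, "ARG", "CZ", 20.1, 13.5, 0.7))
  add(toy_atom("B", 7, "ARG", "NH1", 21.0, 13.4, -0.2))
  add(toy_atom("B", 7, "ARG", "NH2", 19.7, 14.7, 1.0))
  add(toy_atom("B", 8, "LEU", "CB", 23.4, 9.5, 0.8))
  add(toy_atom("B", 8, "LEU", "CG", 23.1, 10.6, 1.7))
  add(toy_atom("B", 8, "LEU", "CD1", 23.9, 11.7, 1.2))
  add(toy_atom("B", 8, "LEU", "CD2", 22.0, 11.0, 2.5))

  atoms <- do.call(rbind, rows)
  # Leu8 O toward the interface
  atoms$y[atoms$chain == "B" & atoms$resnum == 8 & atoms$atom == "O"] <- 7.5
  atoms$x[atoms$chain == "B" & atoms$resnum == 8 & atoms$atom == "O"] <- 24.4
  atoms$z[atoms$chain == "B" & atoms$resnum == 8 & atoms$atom == "O"] <- -0.4
  atoms <- atoms[order(atoms$chain, atoms$resnum,
                       match(atoms$atom, unique(atoms$atom))), ]
  rownames(atoms) <- NULL

  planted <- data.frame(
    kind = c("salt_bridge", "hbond", "hbond", "nonpolar", "nonpolar"),
    chain_a = "A", resnum_a = c(2L, 2L, 6L, 4L, 4L),
    resname_a = c("GLU", "GLU", "ARG", "TRP", "TRP"),
    chain_b = "B", resnum_b = c(4L, 4L, 8L, 5L, 6L),
    resname_b = c("LYS", "LYS", "LEU", "PRO", "PRO"),
    stringsAsFactors = FALSE)

  list(atoms = atoms,
       partition = list(receptor = "A", ligand = "B"),
       p0_resnum = 2L,
       planted_contacts = planted)
}

#' Generate a jittered complex ensemble
#'
#' `n_models` copies of a template complex with independent zero-mean
#' Gaussian coordinate jitter, as a `structure_ensemble` plus a truth table
#' (planted contacts, jitter SD, seed).
#'
#' @param template A [toy_complex()]-style list (default the toy complex).
#' @param n_models Number of models (default 40).
#' @param jitter_sd Coordinate jitter SD, Angstrom (>= 0).
#' @param seed Integer seed.
#' @return List with `ensemble`, `truth` (list: planted_contacts,
#'   jitter_sd, seed, n_models), `partition`, `p0_resnum`.
#' @export
gen_complex_ensemble <- function(template = toy_complex(), n_models = 40,
                                 jitter_sd = 0.3, seed = 1L) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  at <- template$atoms
  base <- as.matrix(at[, c("x", "y", "z")])
  coords <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(nrow(at), 3, n_models))
    for (k in seq_len(n_models)) {
      arr[, , k] <- base + matrix(stats::rnorm(length(base), 0, jitter_sd),
                                  ncol = 3)
    }
    arr
  })
  ens <- new_structure_ensemble(
    at[, c("chain", "resnum", "resname", "atom", "element")], coords,
    source = "synthetic")
  list(ensemble = ens,
       truth = list(planted_contacts = template$planted_contacts,
                    jitter_sd = jitter_sd, seed = seed, n_models = n_models),
       partition = template$partition,
       p0_resnum = template$p0_resnum)
}

#' Generate replicate ITC titrations
#'
#' @param params One row of [binding_truth_registry()] (or any list with
#'   `kd_um`/`kd`, `dh_kcal_mol`/`dh`, `n`).
#' @param replicates Number of replicate titrations.
#' @param noise_sd Heat noise SD, microcal.
#' @param seed Base seed; replicate r uses a derived child seed.
#' @param schedule A [titration_schedule()].
#' @param out_dir Optional directory; when given, one TSV per replicate and
#'   a `truth.json` are written.
#' @return List of titration data.frames; attribute `truth`.
#' @export
gen_titrations <- function(params, replicates = 3, noise_sd = 0.1, seed = 1L,
                           schedule = titration_schedule(), out_dir = NULL) {
  p <- list(kd = params$kd_um %||% params$kd,
            dh = params$dh_kcal_mol %||% params$dh,
            n = params$n)
  sims <- lapply(seq_len(replicates), function(r) {
    simulate_itc(p, schedule, noise_sd, seed = derive_seed(seed, r))
  })
  truth <- list(kd_um = p$kd, dh_kcal_mol = p$dh, n = p$n,
                noise_sd = noise_sd, seed = seed, replicates = replicates,
                generator = "gen_titrations/0.1.0")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(replicates))
      write_curve_tsv(sims[[r]], file.path(out_dir, sprintf("titration_%02d.tsv", r)))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(sims, "truth") <- truth
  sims
}

#' Generate replicate displacement curves
#'
#' @param truth One row of [elisa_truth_registry()] (or list with `ec50_nm`
#'   or `ec50`, `top`, `bottom`, `hill`).
#' @param replicates Number of replicate curves.
#' @param doses Dose vector, nM (default [displacement_doses_nm()]).
#' @param noise_frac Gaussian noise SD as a fraction of `top` (default
#'   0.02).
#' @param seed Base seed; replicate r uses a derived child seed.
#' @param out_dir Optional output directory (TSVs + truth.json).
#' @return List of dose-response data.frames; attribute `truth`.
#' @export
gen_displacement_curves <- function(truth, replicates = 7,
                                    doses = displacement_doses_nm(),
                                    noise_frac = 0.02, seed = 1L,
                                    out_dir = NULL) {
  tr <- list(ec50 = truth$ec50_nm %||% truth$ec50, top = truth$top,
             bottom = truth$bottom, hill = truth$hill)
  sims <- lapply(seq_len(replicates), function(r) {
    simulate_displacement(tr, doses, noise_sd = noise_frac * tr$top,
                          seed = derive_seed(seed, r))
  })
  meta <- c(tr, list(noise_frac = noise_frac, seed = seed,
                     replicates = replicates,
                     generator = "gen_displacement_curves/0.1.0"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(replicates))
      write_curve_tsv(sims[[r]], file.path(out_dir, sprintf("curve_%02d.tsv", r)))
    jsonlite::write_json(meta, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(sims, "truth") <- meta
  sims
}
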