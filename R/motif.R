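# Consensus-motif model for SH3 ligand cores.
#
# The ligand core is an eight-position window labelled -1, 0, +1, ..., +6
# relative to the first conserved proline (position 0). The high-affinity
# consensus is (A/P)(-1) P(0) x(+1) K(+2) P(+3) x(+4) (L/R)(+5) Z(+6),
# Z = L/P/S/T. Position +2 lysine is the central anchor; +5 is the
# specificity-pocket anchor.

MOTIF_POSITIONS <- c("-1", "0", "+1", "+2", "+3", "+4", "+5", "+6")

#' Consensus ligand-core pattern
#'
#' Builds the eight-position allowed-residue pattern for the lysine-anchored
#' class II ligand core. Unconstrained positions admit any of the 20 standard
#' residues; `X` (unknown) never matches, at any position.
#'
#' @param relaxed Logical; if `TRUE`, additionally admit arginine at +2
#'   (an acceptable, lower-affinity central anchor) and drop the +6
#'   constraint. Off by default.
#' @return An object of class `motif_pattern`: a named list of length 8,
#'   one character vector of permitted residues per position.
#' @export
#' @examples
#' motif_pattern()[["+2"]]
motif_pattern <- function(relaxed = FALSE) {
  p <- list(
    "-1" = c("A", "P"),
    "0"  = "P",
    "+1" = AA_STANDARD,
    "+2" = "K",
    "+3" = "P",
    "+4" = AA_STANDARD,
    "+5" = c("L", "R"),
    "+6" = c("L", "P", "S", "T")
  )
  if (relaxed) {
    p[["+2"]] <- c("K", "R")
    p[["+6"]] <- AA_STANDARD
  }
  structure(p, class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Ligand-core pattern (positions -1..+6):\n")
  for (pos in names(x)) {
    set <- x[[pos]]
    lab <- if (length(set) == length(AA_STANDARD)) "x (any)" else
      paste(set, collapse = "/")
    cat(sprintf("  %3s : %s\n", pos, lab))
  }
  invisible(x)
}

# Does an 8-char window satisfy the pattern? X matches nothing.
window_matches <- function(chars, pattern) {
  for (k in seq_len(8L)) {
    if (!(chars[k] %in% pattern[[k]])) return(FALSE)
  }
  TRUE
}

#' Locate motif cores within a peptide
#'
#' Finds every 1-based start position (the position of the -1 residue) at
#' which the eight-residue window satisfies the pattern.
#'
#' @param peptide Amino-acid string (1-letter codes; `X` allowed but never
#'   matches).
#' @param pattern A [motif_pattern()].
#' @return Integer vector of 1-based core start positions (possibly empty).
#' @export
#' @examples
#' locate_core("FHAPPSKPPLPK")  # clone-1 style 12-mer -> start 4
locate_core <- function(peptide, pattern = motif_pattern()) {
  peptide <- check_sequence(peptide, what = "peptide")
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 8L) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - 7L)) {
    if (window_matches(chars[s:(s + 7L)], pattern)) hits <- c(hits, s)
  }
  hits
}

#' Build a position frequency matrix from anchored peptides
#'
#' @param peptides Character vector of peptide sequences.
#' @param core_start Integer vector (recycled if length 1): 1-based start of
#'   the motif -1 position within each peptide. Every start must leave a full
#'   8-residue window.
#' @param pseudocount Non-negative pseudocount added per residue; column
#'   probabilities are `(count + pseudocount) / (n + 20 * pseudocount)`.
#'   Default 0.5 (Jeffreys-like).
#' @return A `pfm` object: an 8 x 20 matrix of probabilities (rows are motif
#'   positions -1..+6, columns the standard residues), with attributes
#'   `pseudocount` and `n_sequences`.
#' @export
build_pfm <- function(peptides, core_start, pseudocount = 0.5) {
  if (length(peptides) < 1L) stop("need at least one peptide", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  core_start <- rep_len(as.integer(core_start), length(peptides))
  counts <- matrix(0L, nrow = 8L, ncol = length(AA_STANDARD),
                   dimnames = list(MOTIF_POSITIONS, AA_STANDARD))
  for (i in seq_along(peptides)) {
    seq_i <- check_sequence(peptides[i], what = "peptide")
    s <- core_start[i]
    if (s < 1L || s + 7L > nchar(seq_i))
      stop("core_start ", s, " does not admit an 8-residue window in peptide ",
           i, call. = FALSE)
    win <- strsplit(substr(seq_i, s, s + 7L), "", fixed = TRUE)[[1]]
    if (any(win == "X"))
      stop("X not permitted inside a motif core window (peptide ", i, ")",
           call. = FALSE)
    for (k in 1:8) counts[k, win[k]] <- counts[k, win[k]] + 1L
  }
  n <- length(peptides)
  probs <- (counts + pseudocount) / (n + 20 * pseudocount)
  structure(probs, class = c("pfm", "matrix"),
            pseudocount = pseudocount, n_sequences = n)
}

#' Log-odds score of an 8-residue window
#'
#' Sum over positions of `log2(p[pos, residue] / background[residue])`,
#' in bits. Higher scores are closer to the consensus.
#'
#' @param window 8-residue string (no X).
#' @param pfm A [build_pfm()] result.
#' @param background Named residue probability vector, strictly positive,
#'   summing to 1. Default uniform 1/20.
#' @return Score in bits.
#' @export
score_window <- function(window, pfm,
                         background = stats::setNames(rep(1 / 20, 20), AA_STANDARD)) {
  window <- check_sequence(window, allow_x = FALSE, what = "window")
  if (nchar(window) != 8L) stop("window must have length 8", call. = FALSE)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6)
    stop("background must be strictly positive and sum to 1", call. = FALSE)
  if (any(pfm == 0))
    stop("scoring requires pseudocount > 0 (PFM contains zero probabilities)",
         call. = FALSE)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  sum(vapply(1:8, function(k) {
    log2(pfm[k, chars[k]] / background[[chars[k]]])
  }, numeric(1)))
}

#' Match a sequence against the ligand-core pattern
#'
#' Reports every satisfying 8-residue window (overlaps included), sorted by
#' start. Start positions are 1-based and address the motif -1 residue.
#'
#' @param sequence_id Label for the sequence.
#' @param sequence Amino-acid string.
#' @param pattern A [motif_pattern()].
#' @param pfm Optional [build_pfm()] result; when given, a log-odds score is
#'   attached to each match.
#' @param background Background for scoring (see [score_window()]).
#' @return data.frame with columns `sequence_id`, `start`, `end`, `window`,
#'   `score` (NA when no PFM given).
#' @export
#' @examples
#' match_sequence("clone16", "AHTPPPKPTRPP")
match_sequence <- function(sequence_id, sequence, pattern = motif_pattern(),
                           pfm = NULL,
                           background = stats::setNames(rep(1 / 20, 20), AA_STANDARD)) {
  sequence <- check_sequence(sequence, what = "sequence")
  starts <- locate_core(sequence, pattern)
  windows <- vapply(starts, function(s) substr(sequence, s, s + 7L), character(1))
  score <- rep(NA_real_, length(starts))
  if (!is.null(pfm) && length(starts)) {
    score <- vapply(windows, score_window, numeric(1),
                    pfm = pfm, background = background, USE.NAMES = FALSE)
  }
  data.frame(sequence_id = rep(as.character(sequence_id), length(starts)),
             start = as.integer(starts),
             end = as.integer(starts + 7L),
             window = windows,
             score = score,
             stringsAsFactors = FALSE)
}

#' Anchor a peptide set on its motif cores
#'
#' Two-pass anchoring for peptides that may carry more than one candidate
#' core: a bootstrap PFM is built from the peptides with a unique core, then
#' ambiguous peptides are anchored at their highest-scoring core (ties broken
#' leftmost). Peptides with no core are dropped with a warning.
#'
#' @param peptides Character vector of peptide sequences.
#' @param ids Optional labels (default `pep1`, `pep2`, ...).
#' @param pattern A [motif_pattern()].
#' @param pseudocount Pseudocount for the bootstrap PFM.
#' @return data.frame with columns `id`, `sequence`, `core_start`.
#' @export
align_peptide_set <- function(peptides, ids = NULL, pattern = motif_pattern(),
                              pseudocount = 0.5) {
  if (is.null(ids)) ids <- paste0("pep", seq_along(peptides))
  cores <- lapply(peptides, locate_core, pattern = pattern)
  n_hits <- lengths(cores)
  if (any(n_hits == 0L)) {
    warning(sum(n_hits == 0L), " peptide(s) without a core match dropped")
  }
  keep <- n_hits > 0L
  peptides <- peptides[keep]; ids <- ids[keep]; cores <- cores[keep]
  n_hits <- n_hits[keep]
  if (!length(peptides)) stop("no peptide contains a core match", call. = FALSE)
  core_start <- vapply(cores, `[`, integer(1), 1L)
  if (any(n_hits > 1L) && any(n_hits == 1L)) {
    boot <- build_pfm(peptides[n_hits == 1L], core_start[n_hits == 1L],
                      pseudocount = max(pseudocount, 0.5))
    for (i in which(n_hits > 1L)) {
      sc <- vapply(cores[[i]], function(s) {
        score_window(substr(peptides[i], s, s + 7L), boot)
      }, numeric(1))
      core_start[i] <- cores[[i]][which.max(sc)]  # which.max: leftmost tie
    }
  }
  data.frame(id = ids, sequence = peptides, core_start = core_start,
             stringsAsFactors = FALSE)
}

#' Read peptides from FASTA or plain text
#'
#' FASTA input (first non-blank character `>`) is parsed with Biostrings;
#' otherwise one sequence per line is assumed.
#'
#' @param path File path.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && startsWith(trimws(first[1]), ">")) {
    ss <- Biostrings::readAAStringSet(path)
    data.frame(id = sub("\\s.*$", "", names(ss)),
               sequence = toupper(as.character(ss)),
               stringsAsFactors = FALSE)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    data.frame(id = paste0("pep", seq_along(lines)),
               sequence = toupper(lines), stringsAsFactors = FALSE)
  }
}

#' Export a PFM as a tab-separated matrix
#'
#' Positions as rows, residues as columns; consumable by logo renderers as a
#' position probability matrix.
#'
#' @param pfm A [build_pfm()] result.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = rownames(pfm),
                   as.data.frame(unclass(pfm)), check.names = FALSE)
  write_tsv(df, path)
}

#' Read a PFM written by [write_pfm()]
#' @param path Input path.
#' @return A `pfm` object (pseudocount attribute restored as NA, n unknown).
#' @export
read_pfm <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, AA_STANDARD])
  rownames(m) <- df$position
  structure(m, class = c("pfm", "matrix"),
            pseudocount = if (any(m == 0)) 0 else NA_real_,
            n_sequences = NA_integer_)
}
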