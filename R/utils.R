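# Shared constants and small helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, alphabetical.
#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid composition
#'
#' SwissProt-like average residue frequencies used as scanning background
#' and by the synthetic proteome generator. Values are the long-run UniProtKB
#' /Swiss-Prot composition statistics, renormalized to sum to one.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
#' @examples
#' sum(swissprot_background())
swissprot_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.36, V = 6.85,
         W = 1.10, Y = 2.92)
  f <- f[AA_STANDARD]
  f / sum(f)
}

# Validate and normalize a protein sequence string. X is tolerated when
# allow_x; nucleotide-looking or otherwise invalid alphabets are rejected.
check_sequence <- function(sequence, allow_x = TRUE, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  ok <- c(AA_STANDARD, if (allow_x) "X")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), ok)
  if (length(bad))
    stop("invalid residue character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  sequence
}

# Deterministic child seeds (kept well below .Machine$integer.max).
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 20000L) * 100000L + as.integer(i)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
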