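# Column-level analysis of SH3-domain multiple sequence alignments:
# mapping reference residues to alignment columns, column composition,
# and allowed-residue filtering (e.g. the acidic second-pocket position
# that licenses a centrally located ligand lysine).

#' Construct an alignment object
#'
#' @param sequences Named character vector of aligned sequences. `-` and `.`
#'   are both treated as gaps; case is preserved (lowercase insert-state
#'   columns retained).
#' @return An `msa_alignment` list with `records` and `length`.
#' @export
msa_alignment <- function(sequences) {
  if (!length(sequences)) stop("empty alignment", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("seq", seq_along(sequences))
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("aligned sequences must all have equal length", call. = FALSE)
  structure(list(records = sequences, length = len), class = "msa_alignment")
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' Format is auto-detected (`# STOCKHOLM` header vs `>` FASTA).
#'
#' @param path File path.
#' @return An `msa_alignment`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("^#\\s*STOCKHOLM", lines[1])) {
    seqs <- list()
    for (ln in lines[-1]) {
      if (startsWith(ln, "#") || startsWith(ln, "//")) next
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) next
      seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
    }
    msa_alignment(unlist(seqs))
  } else {
    ss <- Biostrings::readBStringSet(path)
    msa_alignment(stats::setNames(as.character(ss),
                                  sub("\\s.*$", "", names(ss))))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$records, "", fixed = TRUE))
}

is_gap <- function(chars) chars %in% c("-", ".")

#' Map a reference residue number to an alignment column
#'
#' Returns the 1-based alignment column whose ungapped index in the
#' reference sequence equals `reference_residue_number - numbering_offset`.
#'
#' @param alignment An `msa_alignment`.
#' @param reference_id Record name of the reference sequence.
#' @param reference_residue_number Residue number in the reference's own
#'   numbering.
#' @param numbering_offset Offset such that ungapped index =
#'   `reference_residue_number - numbering_offset` (default 0: residue 1 is
#'   the first non-gap character).
#' @return 1-based column index.
#' @export
map_column <- function(alignment, reference_id, reference_residue_number,
                       numbering_offset = 0L) {
  if (!reference_id %in% names(alignment$records))
    stop("reference ", reference_id, " not in alignment", call. = FALSE)
  chars <- strsplit(alignment$records[[reference_id]], "", fixed = TRUE)[[1]]
  non_gap <- which(!is_gap(chars))
  k <- reference_residue_number - numbering_offset
  if (k < 1L || k > length(non_gap))
    stop("residue number ", reference_residue_number,
         " outside the reference's ungapped length", call. = FALSE)
  non_gap[k]
}

#' Residue composition of one alignment column
#'
#' @param alignment An `msa_alignment`.
#' @param column 1-based column index.
#' @return A `column_profile` list: `column`, `counts` (residue table,
#'   uppercased), `gaps`, `n_records`, `percent_all` and `percent_nongap`
#'   per residue.
#' @export
column_frequencies <- function(alignment, column) {
  if (column < 1L || column > alignment$length)
    stop("column out of range", call. = FALSE)
  chars <- toupper(substr(alignment$records, column, column))
  gap <- is_gap(chars)
  counts <- table(chars[!gap])
  n <- length(chars)
  structure(list(column = column,
                 counts = counts,
                 gaps = sum(gap),
                 n_records = n,
                 percent_all = 100 * as.numeric(counts) / n,
                 percent_nongap = if (sum(!gap))
                   100 * as.numeric(counts) / sum(!gap) else numeric(0)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("column %d: %d records, %d gaps\n", x$column, x$n_records, x$gaps))
  df <- data.frame(residue = names(x$counts), count = as.integer(x$counts),
                   pct_all = round(x$percent_all, 1),
                   pct_nongap = round(x$percent_nongap, 1))
  print(df[order(-df$count), ], row.names = FALSE)
  invisible(x)
}

#' Select alignment records by residue at a column
#'
#' @param alignment An `msa_alignment`.
#' @param column 1-based column index.
#' @param allowed Character vector of permitted residues (case-insensitive).
#' @param unique_sequences If `TRUE`, collapse records with identical
#'   (gap-stripped, uppercased) sequences before counting.
#' @return List with `alignment` (the sub-alignment, possibly empty) and
#'   `count`.
#' @export
select_by_column <- function(alignment, column, allowed,
                             unique_sequences = FALSE) {
  if (column < 1L || column > alignment$length)
    stop("column out of range", call. = FALSE)
  chars <- toupper(substr(alignment$records, column, column))
  keep <- chars %in% toupper(allowed)
  recs <- alignment$records[keep]
  if (unique_sequences && length(recs)) {
    canon <- toupper(gsub("[-.]", "", recs))
    recs <- recs[!duplicated(canon)]
  }
  list(alignment = if (length(recs)) msa_alignment(recs) else NULL,
       count = length(recs))
}

#' Position probability matrix of equal-length sequences
#'
#' Normalized per-column residue probabilities (gaps excluded from the
#' normalization), suitable for logo rendering.
#'
#' @param sequences Character vector of equal-length sequences, or an
#'   `msa_alignment`.
#' @return Matrix: columns are positions, rows the residues observed;
#'   every column sums to 1 (all-gap columns are all zero).
#' @export
position_probability_matrix <- function(sequences) {
  if (inherits(sequences, "msa_alignment")) sequences <- sequences$records
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("ragged input", call. = FALSE)
  m <- toupper(do.call(rbind, strsplit(sequences, "", fixed = TRUE)))
  residues <- sort(setdiff(unique(as.vector(m)), c("-", ".")))
  out <- matrix(0, nrow = length(residues), ncol = len,
                dimnames = list(residues, seq_len(len)))
  for (j in seq_len(len)) {
    col <- m[, j]
    col <- col[!is_gap(col)]
    if (!length(col)) next
    tb <- table(col)
    out[names(tb), j] <- as.numeric(tb) / length(col)
  }
  out
}

#' Write a sub-alignment as aligned FASTA
#' @param alignment An `msa_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(alignment$records)) {
    writeLines(c(paste0(">", nm), alignment$records[[nm]]), con)
  }
  invisible(path)
}
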