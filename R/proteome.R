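# Proteome scanning for ligand-core motif hits.

#' Read a protein FASTA into scan records
#'
#' Wrapped or unwrapped FASTA, case-insensitive. Duplicate record ids are an
#' error (they would corrupt truth-table evaluation downstream). Sequences
#' that fail the amino-acid alphabet check (e.g. nucleotide input) are
#' rejected rather than silently translated.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `description`, `sequence`.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("FASTA parse failure for ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  desc <- sub("^\\S+\\s*", "", names(ss))
  seqs <- toupper(as.character(ss))
  for (i in seq_along(seqs)) check_sequence(seqs[i], what = paste0("record ", ids[i]))
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan protein records for ligand-core motif hits
#'
#' All satisfying 8-residue windows across all records, in deterministic
#' order (record order, then start). `flank_acidity` counts D/E in the up to
#' six residues immediately N-terminal of the window, capturing the acidic
#' upstream flank enrichment typical of high-affinity ligands.
#'
#' @param records data.frame with columns `id`, `sequence` (e.g. from
#'   [read_proteome()]).
#' @param pattern A [motif_pattern()].
#' @param pfm Optional PFM; attaches log-odds scores.
#' @param background Scoring background (see [score_window()]).
#' @return data.frame with columns `record_id`, `start`, `end`, `window`,
#'   `score`, `flank_acidity`.
#' @export
scan_proteome <- function(records, pattern = motif_pattern(), pfm = NULL,
                          background = stats::setNames(rep(1 / 20, 20), AA_STANDARD)) {
  if (is.character(records))
    records <- data.frame(id = paste0("seq", seq_along(records)),
                          sequence = records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$id))
    stop("duplicate record id(s) in scan input", call. = FALSE)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    seq_i <- records$sequence[i]
    if (nchar(seq_i) < 8L) {
      warning("record ", records$id[i], " shorter than 8 residues; skipped")
      next
    }
    m <- match_sequence(records$id[i], seq_i, pattern, pfm, background)
    if (!nrow(m)) next
    flank <- vapply(m$start, function(s) {
      lo <- max(1L, s - 6L)
      if (lo >= s) return(0L)
      sum(strsplit(substr(seq_i, lo, s - 1L), "", fixed = TRUE)[[1]] %in% c("D", "E"))
    }, integer(1))
    names(m)[names(m) == "sequence_id"] <- "record_id"
    m$flank_acidity <- flank
    out[[i]] <- m
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), window = character(0),
                      score = numeric(0), flank_acidity = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank scan hits by a weighted key
#'
#' Stable descending sort on `weights["score"] * score +
#' weights["flank_acidity"] * flank_acidity`; ties broken by `record_id`
#' then `start` (ascending).
#'
#' @param hits data.frame from [scan_proteome()].
#' @param weights Named numeric vector with entries `score` and
#'   `flank_acidity`.
#' @return The hits, reordered.
#' @export
rank_hits <- function(hits, weights = c(score = 1, flank_acidity = 0)) {
  if (!nrow(hits)) return(hits)
  w_s <- if ("score" %in% names(weights)) weights[["score"]] else 0
  w_f <- if ("flank_acidity" %in% names(weights)) weights[["flank_acidity"]] else 0
  if (w_s != 0 && anyNA(hits$score))
    stop("hits must be scored when the score weight is nonzero", call. = FALSE)
  key <- w_s * ifelse(is.na(hits$score), 0, hits$score) +
    w_f * hits$flank_acidity
  ord <- order(-key, hits$record_id, hits$start)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scan hits as TSV
#'
#' Header plus one row per hit; round-trips losslessly through
#' [read_hits_tsv()].
#'
#' @param hits data.frame from [scan_proteome()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  ok <- tryCatch({ write_tsv(hits, path); TRUE },
                 error = function(e) stop("cannot write hits to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read scan hits written by [write_hits_tsv()]
#' @param path Input path.
#' @return data.frame of hits.
#' @export
read_hits_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c(record_id = "character"))
  df$score <- as.numeric(df$score)
  df
}
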