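# Amide chemical shift perturbation analysis.

#' Combined and relative chemical shift perturbations
#'
#' Per-residue combined CSP between two titration states,
#' `sqrt(dH^2 + (alpha * dN)^2)`, and the relative CSP obtained by dividing
#' by the standard deviation of the CSP over the included residues (so the
#' relative CSP vector has unit standard deviation).
#'
#' @param shifts_free,shifts_bound data.frames with columns `residue`,
#'   `H_ppm`, `N_ppm`. Only residues present in both tables are used; at
#'   least 3 overlapping residues are required.
#' @param alpha Nitrogen scaling weight (field-standard 0.2).
#' @return data.frame with columns `residue`, `dH`, `dN`, `csp`,
#'   `relative_csp`, plus attribute `degenerate` (TRUE when all CSPs are
#'   identical and the relative CSP is returned as zeros).
#' @export
relative_csp <- function(shifts_free, shifts_bound, alpha = 0.2) {
  common <- intersect(shifts_free$residue, shifts_bound$residue)
  if (length(common) < 3L)
    stop("need at least 3 overlapping residues for a relative CSP",
         call. = FALSE)
  a <- shifts_free[match(common, shifts_free$residue), ]
  b <- shifts_bound[match(common, shifts_bound$residue), ]
  dH <- b$H_ppm - a$H_ppm
  dN <- b$N_ppm - a$N_ppm
  csp <- sqrt(dH^2 + (alpha * dN)^2)
  s <- stats::sd(csp)
  degenerate <- !is.finite(s) || s == 0
  rel <- if (degenerate) rep(0, length(csp)) else csp / s
  out <- data.frame(residue = common, dH = dH, dN = dN, csp = csp,
                    relative_csp = rel)
  attr(out, "degenerate") <- degenerate
  out
}

#' Read an amide shift table (TSV: residue, H_ppm, N_ppm)
#' @param path Input path.
#' @return data.frame with the three columns.
#' @export
read_shift_table <- function(path) {
  df <- read_tsv(path)
  need <- c("residue", "H_ppm", "N_ppm")
  if (!all(need %in% names(df)))
    stop("shift table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
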