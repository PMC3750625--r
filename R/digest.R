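#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with trypsin (C-terminal to K/R, not before
#' P) or chymotrypsin (C-terminal to F/Y/W/L/M, not before P) and returns
#' every fragment carrying up to `max_missed` missed cleavages.
#'
#' Positions are reported in the parent protein's own numbering, which
#' starts at `offset` (1 by default; constructs whose initiator Met is
#' counted as residue 0 use `offset = 0`).
#'
#' @param sequence Protein sequence, standard one-letter codes.
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param max_missed Maximum number of missed cleavage sites per peptide.
#' @param offset Residue number of the first residue of `sequence`.
#' @param specificity Optional character vector overriding the cleavage
#'   residues of the chosen protease.
#' @return Data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`. With `max_missed = 0` the fragments tile the
#'   parent exactly.
#' @examples
#' digest("AKGR", "trypsin", 0)
#' digest("AKPG", "trypsin", 0)   # K before P is not cleaved
#' @export
digest <- function(sequence, protease = c("trypsin", "chymotrypsin"),
                   max_missed = 0, offset = 1, specificity = NULL) {
  protease <- match.arg(protease)
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, .aa_mass_table$residue)
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  cleave_after <- if (is.null(specificity)) {
    switch(protease, trypsin = c("K", "R"), chymotrypsin = c("F", "Y", "W", "L", "M"))
  } else specificity

  n <- length(res)
  # cleavage site after position i (1..n-1), suppressed before proline
  cut_after <- which(res[-n] %in% cleave_after & res[-1] != "P")
  bounds <- c(0L, cut_after, n)            # fragment k spans bounds[k]+1 .. bounds[k+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:min(max_missed, nfrag - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + m + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(res[s:e], collapse = ""),
        start = s + offset - 1L, end = e + offset - 1L,
        missed_cleavages = m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Peptide mass
#'
#' Sums residue masses plus one water, plus any fixed modification
#' deltas. Modifications are given as a data frame with columns
#' `position` (1-based within the peptide) and `delta` (Da, added to both
#' mass types).
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param modifications Optional data frame of `(position, delta)`.
#' @return Named numeric vector `c(mono =, avg =)` in Da.
#' @examples
#' peptide_mass("TKL")                                    # 360.2373
#' peptide_mass("TKL", data.frame(position = 2, delta = 156.0786))
#' @export
peptide_mass <- function(sequence, modifications = NULL) {
  if (!nzchar(sequence)) stop("empty peptide")
  res <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(res, .aa_mass_table$residue)
  if (anyNA(idx)) stop("unknown residue letter(s): ",
                       paste(unique(res[is.na(idx)]), collapse = ", "))
  mono <- sum(.aa_mass_table$mono[idx]) + .mass_water_mono
  avg <- sum(.aa_mass_table$avg[idx]) + .mass_water_avg
  if (!is.null(modifications) && nrow(modifications)) {
    if (any(modifications$position < 1 | modifications$position > length(res)))
      stop("modification position outside peptide span")
    mono <- mono + sum(modifications$delta)
    avg <- avg + sum(modifications$delta)
  }
  c(mono = mono, avg = avg)
}
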