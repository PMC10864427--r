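#' Enumerate mutant/wildtype peptide windows covering a substitution
#'
#' Lists every k-mer window (k in `lengths`, 8--12 by default) that lies
#' within the protein and covers the substituted residue, following the
#' pVAC-Seq convention of scoring all registers per length. The mutant
#' sequence is the wildtype window with the single residue replaced, so each
#' pair differs at exactly one position (`mut_offset`, 1-based within the
#' window).
#'
#' For window length k at protein position p in a protein of length L, the
#' admissible starts are `max(1, p-k+1) .. min(p, L-k+1)`, giving
#' `max(0, min(p, L-k+1) - max(1, p-k+1) + 1)` windows; an interior position
#' therefore yields 8+9+10+11+12 = 50 pairs at the default lengths.
#'
#' @param proteinSeq wildtype protein sequence (character or
#'   [Biostrings::AAString-class]); canonical 20-letter alphabet only —
#'   selenocysteine or ambiguity codes are rejected, since binding predictors
#'   do not accept them.
#' @param position 1-based residue index of the substitution.
#' @param wtAA,mtAA wildtype and mutant residues (single letters). The
#'   protein must carry `wtAA` at `position`; a mismatch is an error naming
#'   the gene, position, expected and found residues.
#' @param lengths window lengths to enumerate.
#' @param gene optional gene label carried into the output (and error
#'   messages).
#' @return A [S4Vectors::DataFrame-class] with one row per pair, ordered by
#'   increasing length then increasing start: `gene`, `protein_pos`, `wt_aa`,
#'   `mt_aa`, `substitution` (e.g. "E274K"), `length`, `start`, `mut_offset`,
#'   `mt_seq`, `wt_seq`.
#' @examples
#' enumerateWindows("KTDIDLAVDE", 10, "E", "K", lengths = 8:10)
#' @export
enumerateWindows <- function(proteinSeq, position, wtAA, mtAA,
                             lengths = 8:12, gene = NA_character_) {
  seq <- as.character(proteinSeq)
  stopifnot(length(seq) == 1L, nzchar(seq))
  position <- .checkCount(position, "position", min = 1L)
  L <- nchar(seq)
  if (position > L)
    stop(sprintf("position %d beyond protein length %d", position, L), call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad))
    stop(sprintf("protein%s contains non-canonical residue(s) %s; predictors accept the 20 canonical letters only",
                 if (is.na(gene)) "" else paste0(" ", gene),
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!wtAA %in% .AA20 || !mtAA %in% .AA20 || wtAA == mtAA)
    stop("wtAA and mtAA must be distinct canonical amino acids", call. = FALSE)
  if (chars[position] != wtAA)
    stop(sprintf("annotation/sequence mismatch for gene %s at position %d: expected %s, found %s",
                 ifelse(is.na(gene), "<unknown>", gene), position, wtAA, chars[position]),
         call. = FALSE)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L)) stop("window lengths must be positive", call. = FALSE)

  rows <- list()
  for (k in lengths) {
    starts <- seq.int(max(1L, position - k + 1L), min(position, L - k + 1L))
    starts <- starts[starts >= 1L & starts + k - 1L <= L]
    for (s in starts) {
      wt <- substr(seq, s, s + k - 1L)
      off <- position - s + 1L
      mt <- wt
      substr(mt, off, off) <- mtAA
      rows[[length(rows) + 1L]] <- data.frame(
        length = k, start = s, mut_offset = off, mt_seq = mt, wt_seq = wt)
    }
  }
  base <- if (length(rows)) do.call(rbind, rows) else
    data.frame(length = integer(), start = integer(), mut_offset = integer(),
               mt_seq = character(), wt_seq = character())
  S4Vectors::DataFrame(
    gene = rep(gene, nrow(base)),
    protein_pos = rep(position, nrow(base)),
    wt_aa = rep(wtAA, nrow(base)), mt_aa = rep(mtAA, nrow(base)),
    substitution = rep(paste0(wtAA, position, mtAA), nrow(base)),
    base)
}
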