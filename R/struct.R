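# a structure frame is a data.frame: chain, resno, resid, atom, element, x, y, z
.checkFrame <- function(frame) {
  need <- c("chain", "resno", "atom", "element", "x", "y", "z")
  if (!is.data.frame(frame) || !all(need %in% names(frame)))
    stop("a structure frame needs columns chain, resno, atom, element, x, y, z",
         call. = FALSE)
  if (!all(is.finite(frame$x) & is.finite(frame$y) & is.finite(frame$z)))
    stop("frame coordinates must be finite", call. = FALSE)
  invisible(frame)
}

.chainAtoms <- function(frame, chain) {
  sub <- frame[frame$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("chain '%s' not present in frame", chain), call. = FALSE)
  sub
}

#' Read structure frames from a PDB file
#'
#' Parses a single- or multi-model PDB with `bio3d`; each MODEL record
#' becomes one frame.
#'
#' @param pdbFile path to the PDB file.
#' @return List of frame `data.frame`s (columns `chain`, `resno`, `resid`,
#'   `atom`, `element`, `x`, `y`, `z`).
#' @export
readStructureFrames <- function(pdbFile) {
  pdb <- bio3d::read.pdb(pdbFile, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1L, 1L)
  nFrames <- nrow(pdb$xyz)
  lapply(seq_len(nFrames), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               atom = trimws(at$elety), element = trimws(elem),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

#' Anchor (P2--P9) C-alpha distance
#'
#' Euclidean distance between the C-alpha atoms of two peptide positions,
#' by default the P2 and P9 anchor residues whose separation gauges the
#' canonical extended binding pose in the HLA class I groove.
#'
#' @param frame structure frame `data.frame`.
#' @param peptideChain peptide chain id; when `NULL`, auto-detected as the
#'   shortest chain with 8--12 residues.
#' @param fromPos,toPos 1-based residue positions within the peptide chain.
#' @return Distance in angstroms.
#' @export
anchorDistance <- function(frame, peptideChain = NULL, fromPos = 2L, toPos = 9L) {
  .checkFrame(frame)
  if (is.null(peptideChain)) peptideChain <- .detectPeptideChain(frame)
  pep <- .chainAtoms(frame, peptideChain)
  resnos <- sort(unique(pep$resno))
  ca <- function(pos) {
    if (pos > length(resnos))
      stop(sprintf("peptide chain '%s' has %d residues; position %d absent",
                   peptideChain, length(resnos), pos), call. = FALSE)
    hit <- pep[pep$resno == resnos[pos] & pep$atom == "CA", , drop = FALSE]
    if (nrow(hit) == 0L)
      stop(sprintf("residue %d of chain '%s' lacks a CA atom", pos, peptideChain),
           call. = FALSE)
    as.numeric(hit[1L, c("x", "y", "z")])
  }
  sqrt(sum((ca(fromPos) - ca(toPos))^2))
}

.detectPeptideChain <- function(frame) {
  nres <- vapply(split(frame$resno, frame$chain),
                 function(r) length(unique(r)), integer(1))
  cand <- nres[nres >= 8L & nres <= 12L]
  if (!length(cand))
    stop("no chain with 8-12 residues; name the peptide chain explicitly",
         call. = FALSE)
  names(cand)[order(cand, names(cand))][1L]
}

#' Count inter-chain atom contacts
#'
#' Number of atom pairs, one atom from each chain, within `cutoff`
#' angstroms (inclusive). Hydrogens are excluded by default, the usual
#' heavy-atom contact convention.
#'
#' @param frame structure frame `data.frame`.
#' @param chainA,chainB the two chain ids.
#' @param cutoff distance cutoff, angstroms.
#' @param heavyOnly drop hydrogens before counting.
#' @return Integer pair count.
#' @export
countContacts <- function(frame, chainA, chainB, cutoff = 4.5, heavyOnly = TRUE) {
  .checkFrame(frame)
  a <- .chainAtoms(frame, chainA)
  b <- .chainAtoms(frame, chainB)
  if (heavyOnly) {
    a <- a[toupper(a$element) != "H", , drop = FALSE]
    b <- b[toupper(b$element) != "H", , drop = FALSE]
  }
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  sum(d2 <= cutoff^2)
}

#' Count inter-chain hydrogen bonds
#'
#' Geometric hydrogen-bond count between two chains: a donor is an N or O
#' carrying a covalently attached hydrogen (attachment inferred by proximity,
#' H within `hBondLength` of the heavy atom in the same residue), an
#' acceptor is any N or O on the other chain. A bond requires donor--acceptor
#' heavy-atom distance at most `dCutoff` and D-H...A angle at least
#' `angleCutoff` degrees. Both donor directions (chain A to B and B to A)
#' are counted. When the frame carries no hydrogens the angle term cannot be
#' evaluated; this is an error unless `distanceOnly = TRUE`, which falls
#' back to counting N/O--N/O pairs by distance alone.
#'
#' @param frame structure frame `data.frame`.
#' @param chainA,chainB the two chain ids.
#' @param dCutoff donor--acceptor heavy-atom distance cutoff, angstroms.
#' @param angleCutoff minimum D-H...A angle, degrees.
#' @param distanceOnly count by donor--acceptor distance alone (for
#'   hydrogen-free frames).
#' @param hBondLength maximum H-to-heavy-atom distance treated as covalent.
#' @return Integer hydrogen-bond count.
#' @export
countHbonds <- function(frame, chainA, chainB, dCutoff = 3.5, angleCutoff = 120,
                        distanceOnly = FALSE, hBondLength = 1.3) {
  .checkFrame(frame)
  a <- .chainAtoms(frame, chainA)
  b <- .chainAtoms(frame, chainB)
  isNO <- function(df) toupper(df$element) %in% c("N", "O")
  hasH <- any(toupper(frame$element) == "H")
  if (!hasH && !distanceOnly)
    stop("frame carries no hydrogens, so the D-H...A angle cannot be evaluated; set distanceOnly = TRUE to count donor-acceptor pairs by distance alone",
         call. = FALSE)
  if (distanceOnly) {
    da <- a[isNO(a), , drop = FALSE]; db <- b[isNO(b), , drop = FALSE]
    if (nrow(da) == 0L || nrow(db) == 0L) return(0L)
    d2 <- outer(da$x, db$x, "-")^2 + outer(da$y, db$y, "-")^2 + outer(da$z, db$z, "-")^2
    return(sum(d2 <= dCutoff^2))
  }
  countDir <- function(don, acc) {
    dHeavy <- don[isNO(don), , drop = FALSE]
    dH <- don[toupper(don$element) == "H", , drop = FALSE]
    accNO <- acc[isNO(acc), , drop = FALSE]
    if (nrow(dHeavy) == 0L || nrow(dH) == 0L || nrow(accNO) == 0L) return(0L)
    n <- 0L
    for (i in seq_len(nrow(dHeavy))) {
      D <- as.numeric(dHeavy[i, c("x", "y", "z")])
      sameRes <- dH[dH$resno == dHeavy$resno[i], , drop = FALSE]
      if (nrow(sameRes) == 0L) next
      hd <- sqrt((sameRes$x - D[1])^2 + (sameRes$y - D[2])^2 + (sameRes$z - D[3])^2)
      hyd <- sameRes[hd <= hBondLength, , drop = FALSE]
      if (nrow(hyd) == 0L) next
      for (j in seq_len(nrow(accNO))) {
        A <- as.numeric(accNO[j, c("x", "y", "z")])
        if (sqrt(sum((D - A)^2)) > dCutoff) next
        # bond if any attached H satisfies the angle
        for (k in seq_len(nrow(hyd))) {
          H <- as.numeric(hyd[k, c("x", "y", "z")])
          v1 <- D - H; v2 <- A - H
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          if (ang >= angleCutoff) { n <- n + 1L; break }
        }
      }
    }
    n
  }
  countDir(a, b) + countDir(b, a)
}

#' MM/GBSA binding free energy over a trajectory window
#'
#' Averages the per-frame binding free energy
#' `g_complex - g_receptor - g_ligand` over the frames whose time lies in
#' the closed window (default the final 20 ns of a 100 ns trajectory, 80 to
#' 100 ns inclusive, the equilibrated portion).
#'
#' @param series an [EnergySeries-class].
#' @param window numeric length-2, window start and end in ns (closed on
#'   both ends).
#' @return List with `mean`, `sd` (sample standard deviation, `NA` for a
#'   single frame) and `n_frames`.
#' @examples
#' s <- simulateEnergySeries(200, meanDG = -30, noiseSD = 0, seed = 1)
#' mmgbsaWindow(s)
#' @export
mmgbsaWindow <- function(series, window = c(80, 100)) {
  stopifnot(is(series, "EnergySeries"), length(window) == 2L,
            window[1] <= window[2])
  fr <- series@frames
  keep <- fr$time_ns >= window[1] & fr$time_ns <= window[2]
  if (!any(keep))
    stop(sprintf("no frames inside the window [%g, %g] ns", window[1], window[2]),
         call. = FALSE)
  dg <- bindingEnergy(series)[keep]
  list(mean = mean(dg),
       sd = if (length(dg) > 1L) stats::sd(dg) else NA_real_,
       n_frames = length(dg))
}

#' Read a per-frame energy series from TSV
#'
#' Tab-separated with header `time_ns`, `g_complex`, `g_receptor`,
#' `g_ligand` (kcal/mol).
#'
#' @param file path to the TSV.
#' @return An [EnergySeries-class].
#' @export
readEnergySeries <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("time_ns", "g_complex", "g_receptor", "g_ligand")
  if (!all(need %in% names(df)))
    stop("energy series needs columns time_ns, g_complex, g_receptor, g_ligand",
         call. = FALSE)
  EnergySeries(df$time_ns, df$g_complex, df$g_receptor, df$g_ligand)
}

#' Write a per-frame energy series to TSV
#'
#' @param series an [EnergySeries-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeEnergySeries <- function(series, file) {
  stopifnot(is(series, "EnergySeries"))
  utils::write.table(series@frames, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
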