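# Independent oracles and small fixture builders used across the suite.

# brute-force window enumeration: scan every (length, start) and keep windows
# inside the protein that cover position p; no closed-form arithmetic
bruteForceWindows <- function(L, p, lengths = 8:12) {
  out <- list()
  for (k in lengths) for (s in seq_len(max(L, 1L))) {
    e <- s + k - 1L
    if (e <= L && s <= p && p <= e)
      out[[length(out) + 1L]] <- c(length = k, start = s)
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("length", "start")))
}

# independent 64-entry codon translation via seqinr (stop = '*')
seqinrTranslate <- function(codon) {
  vapply(codon, function(cd)
    seqinr::translate(strsplit(tolower(cd), "")[[1]]), character(1),
    USE.NAMES = FALSE)
}

# all-pairs O(n^2) inter-chain contact count
bruteContacts <- function(frame, chainA, chainB, cutoff = 4.5, heavyOnly = TRUE) {
  a <- frame[frame$chain == chainA, ]
  b <- frame[frame$chain == chainB, ]
  if (heavyOnly) {
    a <- a[a$element != "H", ]
    b <- b[b$element != "H", ]
  }
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (d <= cutoff) n <- n + 1L
  }
  n
}

# brute-force hydrogen-bond count: donor N/O with an H within hBondLength in
# the same residue, acceptor N/O on the other chain, D-A <= dCutoff and
# D-H...A angle >= angleCutoff; both directions
bruteHbonds <- function(frame, chainA, chainB, dCutoff = 3.5, angleCutoff = 120,
                        hBondLength = 1.3) {
  oneDir <- function(don, acc) {
    dh <- don[don$element %in% c("N", "O"), ]
    hs <- don[don$element == "H", ]
    ac <- acc[acc$element %in% c("N", "O"), ]
    n <- 0L
    for (i in seq_len(nrow(dh))) for (j in seq_len(nrow(ac))) {
      D <- c(dh$x[i], dh$y[i], dh$z[i]); A <- c(ac$x[j], ac$y[j], ac$z[j])
      if (sqrt(sum((D - A)^2)) > dCutoff) next
      found <- FALSE
      for (k in seq_len(nrow(hs))) {
        if (hs$resno[k] != dh$resno[i]) next
        H <- c(hs$x[k], hs$y[k], hs$z[k])
        if (sqrt(sum((H - D)^2)) > hBondLength) next
        v1 <- D - H; v2 <- A - H
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        if (acos(max(-1, min(1, cosang))) * 180 / pi >= angleCutoff) found <- TRUE
      }
      if (found) n <- n + 1L
    }
    n
  }
  a <- frame[frame$chain == chainA, ]
  b <- frame[frame$chain == chainB, ]
  oneDir(a, b) + oneDir(b, a)
}

# minimal atomic frame builder for constructed geometries
atomFrame <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), resid = "GLY",
               atom = r[[3]], element = r[[4]],
               x = as.numeric(r[[5]]), y = as.numeric(r[[6]]),
               z = as.numeric(r[[7]]))))
}

# apply a rigid rotation + translation to a frame
rigidMove <- function(frame, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle),  cos(angle), 0,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}

# write a (possibly multi-model) PDB for readStructureFrames tests
writePdbFixture <- function(frames, path) {
  lines <- character()
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (length(frames) > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(fr)))
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, fr$atom[i], fr$resid[i], fr$chain[i], fr$resno[i],
        fr$x[i], fr$y[i], fr$z[i], fr$element[i]))
    if (length(frames) > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# set a decoy's violated field back to a passing value (cohort surgery used
# by the per-criterion sensitivity checks); returns the modified cohort
restoreDecoy <- function(cohort, id, criterion,
                         thresholds = FilterThresholds(),
                         panel = PredictorPanel()) {
  v <- cohortVariants(cohort)
  i <- match(id, v$id)
  cache <- cohortBindingCache(cohort)
  expr <- cohortExpression(cohort)
  if (criterion %in% 4:6) {
    # locate the register/allele the screen selects for this variant
    cs <- as.data.frame(candidates(screenCohort(cohort, panel = panel,
                                                thresholds = thresholds)))
    row <- cs[cs$id == id, ]
  }
  if (criterion == 1L) {
    v$dna_depth[i] <- as.integer(thresholds@minDepth)  # alt was depth, VAF stays >= 0.4
    v$dna_alt[i] <- min(v$dna_alt[i], v$dna_depth[i])
  } else if (criterion == 2L) {
    v$dna_alt[i] <- as.integer(ceiling(v$dna_depth[i] * min(1, thresholds@minVAF + 0.2)))
  } else if (criterion == 3L) {
    expr$fpkm[expr$gene_id == v$gene[i]] <- 10 * thresholds@minFPKM
  } else if (criterion == 4L) {
    sel <- cache$peptide == row$mt_seq & cache$allele == row$allele &
      cache$predictor == panel@primary
    cache$ic50_nM[sel] <- thresholds@maxIC50Primary / 5
  } else if (criterion == 5L) {
    sel <- cache$peptide == row$mt_seq & cache$allele == row$allele &
      cache$predictor %in% panel@consensus
    cache$ic50_nM[sel] <- thresholds@consensusIC50 / 5
  } else if (criterion == 6L) {
    sel <- cache$peptide == row$wt_seq & cache$allele == row$allele &
      cache$predictor == panel@primary
    cache$ic50_nM[sel] <- row$mt_ic50 * 4
  }
  methods::initialize(cohort, variants = v, expression = expr,
                      bindingCache = cache)
}
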