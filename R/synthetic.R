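#' Simulate a proteome
#'
#' Draws protein sequences uniformly over the 20 canonical amino acids (the
#' simplest exchangeable null; no compositional model is imposed). Sequences
#' must be at least 13 residues so that every 8--12-mer window around an
#' interior residue exists.
#'
#' @param nProteins number of proteins (>= 1).
#' @param lengthRange inclusive length bounds; minimum 13.
#' @param seed integer seed; identical arguments give identical output.
#' @return A named [Biostrings::AAStringSet-class] (`gene_001`, ...).
#' @examples
#' simulateProteome(3, c(50, 60), seed = 1)
#' @export
simulateProteome <- function(nProteins, lengthRange = c(50, 500), seed = 1L) {
  nProteins <- .checkCount(nProteins, "nProteins", min = 1L)
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2])
  if (lengthRange[1] < 13)
    stop("protein lengths must be >= 13 so all 8-12-mer windows exist around interior residues",
         call. = FALSE)
  set.seed(.substream(seed, "proteome"))
  rng <- seq.int(lengthRange[1], lengthRange[2])
  lens <- rng[sample.int(length(rng), nProteins, replace = TRUE)]
  seqs <- vapply(lens, function(L)
    paste(sample(.AA20, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("gene_%03d", seq_len(nProteins))
  Biostrings::AAStringSet(seqs)
}

# single-nucleotide missense neighbours of wt_aa: returns a data.frame of
# (codon_ref, codon_alt, mt_aa) over all codons of wt_aa
.missenseNeighbors <- function(wtAA) {
  code <- Biostrings::GENETIC_CODE
  refs <- names(code)[code == wtAA]
  out <- list()
  for (ref in refs) {
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(ref, p, p) == b) next
      alt <- ref
      substr(alt, p, p) <- b
      aa <- unname(code[alt])
      if (aa != "*" && aa != wtAA)
        out[[length(out) + 1L]] <- data.frame(codon_ref = ref, codon_alt = alt,
                                              mt_aa = aa, nt_pos = p,
                                              ref_base = substr(ref, p, p),
                                              alt_base = b)
    }
  }
  do.call(rbind, out)
}

#' Simulate a tumor cohort with planted filter outcomes
#'
#' Builds every input the screen consumes — variants with DNA/RNA depths and
#' allele counts, an expression table, and a deterministic binding-prediction
#' cache — such that `nPass` variants clear all six filter criteria with
#' margin and, for each criterion, `nFailPerCriterion` decoys violate exactly
#' that criterion while clearing the other five with margin. Margins relative
#' to the thresholds: passing depth >= 2x, VAF >= threshold + 0.2, FPKM >=
#' 10x, primary mutant IC50 <= threshold/2 with 4 of 5 consensus predictors
#' agreeing, and wildtype IC50 >= 4x mutant. Each decoy's violation is
#' carried by a single field, so toggling that field to a passing value makes
#' the variant pass.
#'
#' Each variant gets its own protein (one gene, one expression record); the
#' codon change is a real single-nucleotide missense edit consistent with the
#' amino-acid substitution, so annotation consistency checks hold. The
#' binding cache covers every (peptide, allele, predictor) triple the screen
#' can query and is identical across calls with the same arguments.
#'
#' @param proteome named [Biostrings::AAStringSet-class]; needs at least
#'   `nPass + 6 * nFailPerCriterion` proteins.
#' @param nPass number of planted passers.
#' @param nFailPerCriterion decoys per criterion (6 criteria).
#' @param thresholds a [FilterThresholds-class].
#' @param panel a [PredictorPanel-class].
#' @param alleles patient HLA class I alleles.
#' @param seed integer master seed.
#' @param margins list of margin factors: `depthFactor`, `vafMargin`,
#'   `fpkmFactor`, `ic50Factor`, `foldFactor` (defaults above), exposed so
#'   boundary behavior can be probed separately from recovery.
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- simulateCohort(simulateProteome(11, c(40, 80), 1),
#'                          nPass = 5, nFailPerCriterion = 1, seed = 42)
#' cohortTruth(cohort)
#' @export
simulateCohort <- function(proteome, nPass, nFailPerCriterion,
                           thresholds = FilterThresholds(),
                           panel = PredictorPanel(),
                           alleles = c("HLA-A*11:01", "HLA-A*24:02"),
                           seed = 1L,
                           margins = list(depthFactor = 2, vafMargin = 0.2,
                                          fpkmFactor = 10, ic50Factor = 0.5,
                                          foldFactor = 4)) {
  nPass <- .checkCount(nPass, "nPass", min = 0L)
  nFailPerCriterion <- .checkCount(nFailPerCriterion, "nFailPerCriterion", min = 0L)
  stopifnot(is(thresholds, "FilterThresholds"), is(panel, "PredictorPanel"))
  .checkAllele(alleles)
  validObject(thresholds)
  if (thresholds@minVAF + margins$vafMargin > 1)
    stop("minVAF + vafMargin exceeds 1; no passing VAF exists", call. = FALSE)

  n <- nPass + 6L * nFailPerCriterion
  prot <- as.character(proteome)
  if (length(prot) < n)
    stop(sprintf("proteome has %d proteins but %d variants were requested",
                 length(prot), n), call. = FALSE)

  ids <- c(if (nPass) sprintf("pass_%02d", seq_len(nPass)),
           if (nFailPerCriterion)
             as.vector(t(outer(1:6, seq_len(nFailPerCriterion),
                               function(k, j) sprintf("fail_c%d_%02d", k, j)))))
  failCrit <- c(rep(NA_integer_, nPass),
                rep(1:6, each = nFailPerCriterion))

  set.seed(.substream(seed, "cohort"))
  lowDepth <- max(1L, floor(thresholds@minDepth / 2))
  passDepth <- function() sample(seq.int(ceiling(margins$depthFactor * thresholds@minDepth),
                                         ceiling(4 * thresholds@minDepth)), 1L)
  passAlt <- function(depth) min(depth, ceiling(depth * stats::runif(1, thresholds@minVAF + margins$vafMargin, 0.98)))
  failAlt <- function(depth) max(0L, floor(depth * max(0, thresholds@minVAF - margins$vafMargin)))

  varRows <- vector("list", n)
  cacheRows <- vector("list", n)
  exprFpkm <- numeric(n)
  gpos <- 0L
  for (i in seq_len(n)) {
    gene <- names(prot)[i]
    pseq <- prot[[i]]
    L <- nchar(pseq)
    pos <- sample.int(L, 1L)
    wtAA <- substr(pseq, pos, pos)
    nb <- .missenseNeighbors(wtAA)
    pick <- nb[sample.int(nrow(nb), 1L), ]
    crit <- failCrit[i]

    dnaDepth <- passDepth(); rnaDepth <- passDepth()
    if (identical(crit, 1L)) dnaDepth <- lowDepth
    dnaAlt <- passAlt(dnaDepth); rnaAlt <- passAlt(rnaDepth)
    # depth decoys carry VAF 1 on the shallow sample, so restoring the depth
    # field alone restores the pass
    if (identical(crit, 1L)) dnaAlt <- dnaDepth
    if (identical(crit, 2L)) dnaAlt <- failAlt(dnaDepth)
    exprFpkm[i] <- if (identical(crit, 3L))
      stats::runif(1, 0, thresholds@minFPKM / 2)
    else stats::runif(1, margins$fpkmFactor * thresholds@minFPKM,
                      2 * margins$fpkmFactor * thresholds@minFPKM)

    pairs <- enumerateWindows(pseq, pos, wtAA, pick$mt_aa, gene = gene)
    np <- nrow(pairs)
    bestPair <- sample.int(np, 1L)
    bestAllele <- sample(alleles, 1L)

    grid <- expand.grid(pair = seq_len(np), allele = alleles,
                        stringsAsFactors = FALSE)
    isBest <- grid$pair == bestPair & grid$allele == bestAllele
    lowMax <- thresholds@maxIC50Primary * margins$ic50Factor
    # primary MT: designated best register/allele carries the minimum
    mtPrimary <- stats::runif(nrow(grid), 600, 5000)
    mtPrimary[isBest] <- stats::runif(1, lowMax / 5, lowMax)
    if (identical(crit, 4L)) {
      mtPrimary <- stats::runif(nrow(grid), 3000, 5000)
      mtPrimary[isBest] <- stats::runif(1, 2 * thresholds@maxIC50Primary,
                                        4 * thresholds@maxIC50Primary)
    }
    # primary WT for every register/allele; the fold-change margin sits on the
    # designated best
    wtPrimary <- stats::runif(nrow(grid), 600, 5000)
    wtPrimary[isBest] <- if (identical(crit, 6L))
      mtPrimary[isBest] * stats::runif(1, 0.25, 0.5)
    else mtPrimary[isBest] * margins$foldFactor * stats::runif(1, 1, 3)
    # consensus MT IC50s: background above threshold everywhere, then the
    # designated best register gets its planted vote pattern
    nCons <- length(panel@consensus)
    consensus <- matrix(stats::runif(nrow(grid) * nCons, 600, 5000),
                        nrow = nrow(grid))
    nLow <- if (identical(crit, 5L)) max(0L, as.integer(thresholds@consensusMinSupport) - 1L)
            else min(nCons, as.integer(thresholds@consensusMinSupport) + 1L)
    if (nLow > 0L)
      consensus[isBest, seq_len(nLow)] <- stats::runif(nLow, 50, lowMax)
    consensus[isBest, -seq_len(max(nLow, 1L))] <- stats::runif(nCons - max(nLow, 1L), 600, 1000)
    if (nLow == 0L)
      consensus[isBest, ] <- stats::runif(nCons, 600, 1000)

    cacheRows[[i]] <- data.frame(
      peptide = c(pairs$mt_seq[grid$pair], pairs$wt_seq[grid$pair],
                  rep(pairs$mt_seq[grid$pair], nCons)),
      allele = c(grid$allele, grid$allele, rep(grid$allele, nCons)),
      predictor = c(rep(panel@primary, 2L * nrow(grid)),
                    rep(panel@consensus, each = nrow(grid))),
      ic50_nM = c(mtPrimary, wtPrimary, as.vector(consensus)))

    gpos <- gpos + 1000L
    varRows[[i]] <- data.frame(
      id = ids[i], gene = gene, transcript = paste0("tx_", gene),
      chrom = "chr1", genomic_pos = gpos + pick$nt_pos,
      ref = pick$ref_base, alt = pick$alt_base,
      codon_ref = pick$codon_ref, codon_alt = pick$codon_alt,
      protein_pos = pos, wt_aa = wtAA, mt_aa = pick$mt_aa,
      dna_depth = dnaDepth, dna_alt = dnaAlt,
      rna_depth = rnaDepth, rna_alt = rnaAlt)
  }

  variants <- S4Vectors::DataFrame(do.call(rbind, varRows))
  expression <- data.frame(gene_id = names(prot),
                           fpkm = c(exprFpkm, stats::runif(length(prot) - n, 0, 50)))
  cache <- do.call(rbind, cacheRows)
  # duplicate peptides across registers can repeat triples; keep first, they
  # agree only by construction order — resolve deterministically
  cache <- cache[!duplicated(paste(cache$peptide, cache$allele, cache$predictor, sep = "|")), ]
  rownames(cache) <- NULL

  truth <- new("CohortTruth",
               plantedPass = ids[is.na(failCrit)],
               plantedFail = stats::setNames(failCrit[!is.na(failCrit)],
                                             ids[!is.na(failCrit)]),
               seed = as.integer(seed))
  new("SyntheticCohort", variants = variants, expression = expression,
      bindingCache = cache, truth = truth,
      proteome = Biostrings::AAStringSet(prot), alleles = alleles)
}

#' Run the screen on a simulated cohort
#'
#' Convenience wrapper: screens a [SyntheticCohort-class] with its own
#' binding cache and allele list.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param panel,thresholds as in [screenNeoantigens()].
#' @return A [CandidateSet-class].
#' @export
screenCohort <- function(cohort, panel = PredictorPanel(),
                         thresholds = FilterThresholds()) {
  stopifnot(is(cohort, "SyntheticCohort"))
  screenNeoantigens(cohortVariants(cohort), cohortExpression(cohort),
                    cohortProteome(cohort), cohortAlleles(cohort),
                    cachePredictionSource(cohortBindingCache(cohort)),
                    panel = panel, thresholds = thresholds)
}

#' Simulate a per-frame MM/GBSA energy series
#'
#' Generates component energies whose per-frame binding free energy
#' `g_complex - g_receptor - g_ligand` equals `meanDG` plus Gaussian noise
#' with standard deviation `noiseSD` (exactly `meanDG` on every frame when
#' `noiseSD = 0`). Timestamps span 0 to `tMax` ns uniformly.
#'
#' @param nFrames number of frames (>= 2).
#' @param meanDG expected binding free energy, kcal/mol.
#' @param noiseSD per-frame noise standard deviation, kcal/mol (>= 0).
#' @param seed integer seed.
#' @param tMax trajectory end time, ns.
#' @return An [EnergySeries-class].
#' @examples
#' simulateEnergySeries(100, meanDG = -30, noiseSD = 0, seed = 1)
#' @export
simulateEnergySeries <- function(nFrames, meanDG = -30, noiseSD = 1,
                                 seed = 1L, tMax = 100) {
  nFrames <- .checkCount(nFrames, "nFrames", min = 2L)
  if (!is.finite(noiseSD) || noiseSD < 0) stop("noiseSD must be >= 0", call. = FALSE)
  set.seed(.substream(seed, "energy"))
  t <- seq(0, tMax, length.out = nFrames)
  # integer-valued receptor/ligand jitter keeps the component subtraction
  # exact in floating point, so a noise-free series has dG == meanDG exactly
  gRec <- -800 + round(stats::rnorm(nFrames, 0, 5))
  gLig <- -120 + round(stats::rnorm(nFrames, 0, 2))
  gCpx <- gRec + gLig + meanDG + stats::rnorm(nFrames, 0, noiseSD)
  EnergySeries(t, gCpx, gRec, gLig)
}

#' Simulate a peptide--HLA-like structure frame
#'
#' Builds a two-chain atomic frame for testing geometric metrics: a receptor
#' chain of `nReceptor` residues and a peptide chain of `nPeptide` residues,
#' each residue carrying backbone N, CA, C, O atoms (plus an amide hydrogen
#' on N when `hydrogens = TRUE`) at randomized coordinates inside a cube of
#' side `boxSize` angstroms. Purely synthetic geometry — no force field, no
#' stereochemistry — sufficient to exercise distance, contact and
#' hydrogen-bond counting against brute-force oracles.
#'
#' @param nPeptide peptide residues (chain "P").
#' @param nReceptor receptor residues (chain "A").
#' @param hydrogens add an amide hydrogen 1.0 angstrom from each backbone N.
#' @param boxSize cube side, angstroms.
#' @param seed integer seed.
#' @return `data.frame` with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @export
simulateComplexFrame <- function(nPeptide = 9L, nReceptor = 30L,
                                 hydrogens = TRUE, boxSize = 30, seed = 1L) {
  nPeptide <- .checkCount(nPeptide, "nPeptide", min = 1L)
  nReceptor <- .checkCount(nReceptor, "nReceptor", min = 1L)
  set.seed(.substream(seed, "frame"))
  mkChain <- function(chain, nres) {
    rows <- list()
    for (r in seq_len(nres)) {
      base <- stats::runif(3, 0, boxSize)
      atoms <- data.frame(
        atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
        dx = c(0, 1.46, 2.4, 3.0), dy = c(0, 0.3, 1.1, 2.2), dz = c(0, 0.2, 0.4, 0.3))
      if (hydrogens)
        atoms <- rbind(atoms, data.frame(atom = "H", element = "H",
                                         dx = -0.6, dy = -0.8, dz = 0))
      rows[[r]] <- data.frame(chain = chain, resno = r, resid = sample(.AA20, 1L),
                              atom = atoms$atom, element = atoms$element,
                              x = base[1] + atoms$dx, y = base[2] + atoms$dy,
                              z = base[3] + atoms$dz)
    }
    do.call(rbind, rows)
  }
  out <- rbind(mkChain("A", nReceptor), mkChain("P", nPeptide))
  rownames(out) <- NULL
  out
}

#' Simulate replicate assay readings
#'
#' Gaussian replicate readings per condition (spot counts, optical
#' densities, or percent frequencies) for exercising the assay summary and
#' comparison statistics.
#'
#' @param conditions condition labels.
#' @param means expected reading per condition.
#' @param sd replicate standard deviation.
#' @param nReplicates replicates per condition.
#' @param donor donor label.
#' @param etRatio effector:target ratio label.
#' @param seed integer seed.
#' @return `data.frame` with `donor`, `condition`, `et_ratio`, `replicate`,
#'   `value` (truncated at zero, as readings are non-negative).
#' @export
simulateAssayPlate <- function(conditions = c("MT", "WT", "UP"),
                               means = c(60, 15, 10), sd = 5,
                               nReplicates = 3L, donor = "donor1",
                               etRatio = "20:1", seed = 1L) {
  stopifnot(length(conditions) == length(means))
  nReplicates <- .checkCount(nReplicates, "nReplicates", min = 1L)
  set.seed(.substream(seed, "plate"))
  out <- do.call(rbind, lapply(seq_along(conditions), function(i)
    data.frame(donor = donor, condition = conditions[i], et_ratio = etRatio,
               replicate = seq_len(nReplicates),
               value = pmax(0, stats::rnorm(nReplicates, means[i], sd)))))
  rownames(out) <- NULL
  out
}

# minimal VCF v4.2 emission of a cohort variant table (two tumor samples,
# AD/DP FORMAT, single annotation INFO key); parsing is VariantAnnotation's job
.vcfText <- function(variants, infoKey = "PANN",
                     sampleNames = c("TUMOR_DNA", "TUMOR_RNA")) {
  v <- as.data.frame(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Protein annotation: gene|transcript|protein_pos|wt_aa|mt_aa|codon_ref|codon_alt|class\">", infoKey),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##contig=<ID=chr1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    ann <- paste(v$gene[i], v$transcript[i], v$protein_pos[i], v$wt_aa[i],
                 v$mt_aa[i], v$codon_ref[i], v$codon_alt[i], "missense", sep = "|")
    paste(v$chrom[i], v$genomic_pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
          paste0(infoKey, "=", ann), "DP:AD",
          sprintf("%d:%d,%d", v$dna_depth[i], v$dna_depth[i] - v$dna_alt[i], v$dna_alt[i]),
          sprintf("%d:%d,%d", v$rna_depth[i], v$rna_depth[i] - v$rna_alt[i], v$rna_alt[i]),
          sep = "\t")
  }, character(1))
  c(header, body)
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the pipeline's on-disk formats: proteome FASTA,
#' variants VCF (FORMAT `AD`/`DP` for samples `TUMOR_DNA` and `TUMOR_RNA`,
#' protein annotation in INFO key `PANN`), expression TSV
#' (`gene_id<TAB>fpkm`), binding cache TSV, allele list (one per line) and a
#' JSON ground-truth file.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param outdir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, outdir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(outdir, "proteome.fasta"),
    vcf = file.path(outdir, "variants.vcf"),
    expression = file.path(outdir, "expression.tsv"),
    cache = file.path(outdir, "binding_cache.tsv"),
    alleles = file.path(outdir, "alleles.txt"),
    truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(cohortProteome(cohort), paths["proteome"])
  writeLines(.vcfText(cohortVariants(cohort)), paths["vcf"])
  utils::write.table(cohortExpression(cohort), paths["expression"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeBindingCache(cohortBindingCache(cohort), paths["cache"])
  writeLines(cohortAlleles(cohort), paths["alleles"])
  tr <- cohortTruth(cohort)
  jsonlite::write_json(
    list(planted_pass = tr@plantedPass,
         planted_fail = as.list(tr@plantedFail),
         seed = tr@seed),
    paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
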