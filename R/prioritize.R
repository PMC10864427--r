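#' Apply the six-criterion neoantigen filter
#'
#' Evaluates each criterion independently (no short-circuiting), so the
#' report can show every reason a candidate failed:
#' \enumerate{
#'   \item tumor DNA and RNA depth `>= minDepth` (inclusive),
#'   \item tumor DNA and RNA VAF `>= minVAF` (inclusive),
#'   \item FPKM `> minFPKM` (strict),
#'   \item primary-predictor mutant IC50 `<= maxIC50Primary` (inclusive),
#'   \item mutant IC50 `<= consensusIC50` in at least `consensusMinSupport`
#'     consensus predictors (inclusive),
#'   \item fold change `wt_ic50 / mt_ic50 > minFoldChange` (strict).
#' }
#' Boundary semantics follow the printed inequality of each criterion.
#' Depth and VAF apply to both the DNA and the RNA sample. A missing
#' expression record (`fpkm = NA`) fails criterion 3 and is flagged in the
#' result as `fpkm_missing`.
#'
#' @param dnaDepth,rnaDepth site depths for the tumor DNA and RNA samples.
#' @param dnaVaf,rnaVaf variant allele fractions for the two samples.
#' @param fpkm gene expression in FPKM, or `NA` when no record exists.
#' @param mtIC50,wtIC50 primary-predictor IC50s (nM) for the mutant and
#'   wildtype peptide at the selected allele and register.
#' @param consensusIC50s mutant IC50s from the consensus panel.
#' @param thresholds a [FilterThresholds-class].
#' @return List with `flags` (named logical, `crit1`..`crit6`), `passed`,
#'   `fold_change`, and `fpkm_missing`.
#' @examples
#' applyFilters(20, 20, 0.5, 0.5, 8, 100, 400, c(100, 100, 100, 900, 900))
#' @export
applyFilters <- function(dnaDepth, rnaDepth, dnaVaf, rnaVaf, fpkm,
                         mtIC50, wtIC50, consensusIC50s,
                         thresholds = FilterThresholds()) {
  stopifnot(is(thresholds, "FilterThresholds"))
  fc <- foldChange(wtIC50, mtIC50)
  fpkmMissing <- is.na(fpkm)
  flags <- c(
    crit1 = dnaDepth >= thresholds@minDepth && rnaDepth >= thresholds@minDepth,
    crit2 = dnaVaf >= thresholds@minVAF && rnaVaf >= thresholds@minVAF,
    crit3 = !fpkmMissing && fpkm > thresholds@minFPKM,
    crit4 = mtIC50 <= thresholds@maxIC50Primary,
    crit5 = consensusVote(consensusIC50s, thresholds@consensusIC50,
                          thresholds@consensusMinSupport),
    crit6 = fc > thresholds@minFoldChange
  )
  list(flags = flags, passed = all(flags), fold_change = fc,
       fpkm_missing = fpkmMissing)
}

#' Screen somatic missense variants for candidate neoantigens
#'
#' The full prioritization pipeline: for each variant, enumerate all
#' mutant/wildtype peptide pairs covering the substitution
#' ([enumerateWindows()]), score every pair against every patient allele
#' with the primary predictor, keep the best register and allele (minimum
#' mutant IC50; ties broken by allele name, then peptide, then length),
#' fetch the wildtype and consensus predictions for that choice, and apply
#' the six-criterion filter ([applyFilters()]). One candidate is emitted per
#' variant.
#'
#' @param variants variant table as returned by [parseVariants()] or
#'   [cohortVariants()] (columns `id`, `gene`, `protein_pos`, `wt_aa`,
#'   `mt_aa`, `dna_depth`, `dna_alt`, `rna_depth`, `rna_alt`).
#' @param expression `data.frame` with `gene_id` and `fpkm`. Genes without a
#'   record fail the expression criterion and are flagged.
#' @param proteome named [Biostrings::AAStringSet-class] (or named character
#'   vector) keyed by gene.
#' @param alleles patient HLA class I alleles.
#' @param source prediction source function (see [cachePredictionSource()]).
#' @param panel a [PredictorPanel-class].
#' @param thresholds a [FilterThresholds-class].
#' @param lengths peptide window lengths.
#' @return A [CandidateSet-class].
#' @export
screenNeoantigens <- function(variants, expression, proteome, alleles,
                              source, panel = PredictorPanel(),
                              thresholds = FilterThresholds(),
                              lengths = 8:12) {
  stopifnot(is(panel, "PredictorPanel"), is(thresholds, "FilterThresholds"),
            is.function(source))
  .checkAllele(alleles)
  prot <- as.character(proteome)
  if (is.null(names(prot))) stop("proteome must be named by gene", call. = FALSE)

  rows <- vector("list", nrow(variants))
  missingFpkm <- character()
  for (i in seq_len(nrow(variants))) {
    v <- as.data.frame(variants[i, , drop = FALSE])
    if (!v$gene %in% names(prot))
      stop(sprintf("no protein sequence for gene %s", v$gene), call. = FALSE)
    pairs <- enumerateWindows(prot[[v$gene]], v$protein_pos, v$wt_aa, v$mt_aa,
                              lengths = lengths, gene = v$gene)
    if (nrow(pairs) == 0L) next

    # best register: minimum primary MT IC50 over (pair, allele); determinism
    # via allele name, peptide, then length on ties
    grid <- expand.grid(pair = seq_len(nrow(pairs)), allele = alleles,
                        stringsAsFactors = FALSE)
    grid$ic50 <- source(pairs$mt_seq[grid$pair], grid$allele,
                        rep(panel@primary, nrow(grid)))
    ord <- order(grid$ic50, grid$allele, pairs$mt_seq[grid$pair],
                 pairs$length[grid$pair])
    top <- grid[ord[1L], ]
    bp <- pairs[top$pair, ]
    cons <- vapply(panel@consensus,
                   function(pr) source(bp$mt_seq, top$allele, pr), numeric(1))
    wtIC50 <- source(bp$wt_seq, top$allele, panel@primary)

    fpkm <- expression$fpkm[match(v$gene, expression$gene_id)]
    res <- applyFilters(v$dna_depth, v$rna_depth,
                        computeVAF(v$dna_alt, v$dna_depth),
                        computeVAF(v$rna_alt, v$rna_depth),
                        fpkm, top$ic50, wtIC50, cons, thresholds)
    if (res$fpkm_missing) missingFpkm <- c(missingFpkm, v$gene)
    rows[[i]] <- data.frame(
      id = v$id, gene = v$gene, substitution = bp$substitution,
      allele = top$allele, length = bp$length, mut_offset = bp$mut_offset,
      mt_seq = bp$mt_seq, wt_seq = bp$wt_seq,
      mt_ic50 = top$ic50, wt_ic50 = wtIC50, fold_change = res$fold_change,
      as.list(res$flags), passed = res$passed)
  }
  if (length(missingFpkm))
    warning(sprintf("no expression record for gene(s) %s; expression criterion failed",
                    paste(unique(missingFpkm), collapse = ", ")), call. = FALSE)
  kept <- rows[!vapply(rows, is.null, logical(1))]
  cd <- if (length(kept)) S4Vectors::DataFrame(do.call(rbind, kept)) else
    S4Vectors::DataFrame(
      id = character(), gene = character(), substitution = character(),
      allele = character(), length = integer(), mut_offset = integer(),
      mt_seq = character(), wt_seq = character(), mt_ic50 = numeric(),
      wt_ic50 = numeric(), fold_change = numeric(),
      crit1 = logical(), crit2 = logical(), crit3 = logical(),
      crit4 = logical(), crit5 = logical(), crit6 = logical(),
      passed = logical())
  new("CandidateSet", candidates = cd, thresholds = thresholds, panel = panel)
}

#' Rank candidates by fold change
#'
#' Orders candidates by descending wildtype/mutant fold change; ties are
#' broken by lower mutant IC50, then lexicographic mutant peptide, so the
#' order is deterministic and invariant to input permutation.
#'
#' @param candidates candidate table (`data.frame` or `DataFrame`) with
#'   columns `fold_change`, `mt_ic50`, `mt_seq`.
#' @return The same table, reordered.
#' @export
rankCandidates <- function(candidates) {
  stopifnot(all(c("fold_change", "mt_ic50", "mt_seq") %in% colnames(candidates)))
  candidates[order(-candidates$fold_change, candidates$mt_ic50,
                   candidates$mt_seq), , drop = FALSE]
}

#' Build a ranked candidate report
#'
#' Formats the top candidates the way published candidate tables are laid
#' out: gene, amino-acid substitution, HLA allele, mutant peptide with its
#' IC50, wildtype peptide with its IC50, and the fold change. IC50s are
#' printed at three decimals and fold changes at two, both rounded half-up.
#' The unformatted per-criterion flags travel alongside as the `flags`
#' attribute (long form: candidate id, criterion, pass).
#'
#' @param ranked ranked candidate table (see [rankCandidates()]).
#' @param topN number of rows to keep; fewer rows are returned unpadded when
#'   the input is shorter.
#' @return `data.frame` report; attribute `flags` holds the long-form flag
#'   table when flag columns are present.
#' @export
buildReport <- function(ranked, topN = 3L) {
  topN <- .checkCount(topN, "topN", min = 1L)
  ranked <- as.data.frame(ranked)
  n <- min(topN, nrow(ranked))
  head <- ranked[seq_len(n), , drop = FALSE]
  report <- data.frame(
    gene = character(n), substitution = character(n), allele = character(n),
    mt_peptide = character(n), mt_ic50_nM = character(n),
    wt_peptide = character(n), wt_ic50_nM = character(n),
    fold_change = character(n))
  if (n) {
    report$gene <- head$gene
    report$substitution <- head$substitution
    report$allele <- head$allele
    report$mt_peptide <- head$mt_seq
    report$mt_ic50_nM <- sprintf("%.3f", .roundHalfUp(head$mt_ic50, 3L))
    report$wt_peptide <- head$wt_seq
    report$wt_ic50_nM <- sprintf("%.3f", .roundHalfUp(head$wt_ic50, 3L))
    report$fold_change <- sprintf("%.2f", .roundHalfUp(head$fold_change, 2L))
  }
  critCols <- grep("^crit[1-6]$", names(ranked), value = TRUE)
  if (length(critCols) && nrow(ranked)) {
    attr(report, "flags") <- data.frame(
      id = rep(if ("id" %in% names(ranked)) ranked$id else ranked$gene,
               each = length(critCols)),
      criterion = rep(seq_along(critCols), times = nrow(ranked)),
      pass = as.vector(t(as.matrix(ranked[critCols]))))
  }
  report
}

#' Published candidate neoantigen table
#'
#' The six candidate neoantigens reported for the two primary breast cancer
#' cell lines (PC-B-142CA, PC-B-148CA), as printed: gene, amino-acid
#' substitution, restricting HLA allele, mutant and wildtype peptides with
#' their predicted IC50s (nM), the printed wildtype/mutant fold change, and
#' the nucleotide change type confirmed by Sanger sequencing. Useful as a
#' worked input for [foldChange()] and [rankCandidates()].
#'
#' @return `data.frame` with one row per candidate.
#' @examples
#' pc <- publishedCandidates()
#' foldChange(pc$wt_ic50_nM, pc$mt_ic50_nM)
#' @export
publishedCandidates <- function() {
  utils::read.delim(system.file("extdata", "published_candidates.tsv",
                                package = "neoscreen", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Stage counts of a screen (mutations -> candidates funnel)
#'
#' @param candidateSet a [CandidateSet-class].
#' @return Named integer vector: variants screened, candidates passing all
#'   six criteria.
#' @export
screenFunnel <- function(candidateSet) {
  cd <- candidates(candidateSet)
  c(screened = nrow(cd), passed = sum(cd$passed))
}
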