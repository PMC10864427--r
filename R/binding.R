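# position-weight hash in [0,1], deterministic in (predictor, allele,
# position, residue); drives the built-in toy predictor
.unitHash <- function(key) {
  h <- 7
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 1048573
  h / 1048572
}

#' Deterministic built-in binding predictor
#'
#' A self-contained stand-in with the interface of an external MHC class I
#' predictor, for offline runs and tests. Each (allele, position, residue)
#' carries a weight w in \[0, 1\] (by default a deterministic hash keyed also
#' by the predictor name, so distinct panel members disagree); the peptide
#' score is the mean weight over its positions and
#' `IC50 = 50000^(1 - score)` nM, strictly decreasing in the score and always
#' in \[1, 50000\].
#'
#' @param peptide peptide over the 20 canonical letters.
#' @param allele HLA class I allele name, e.g. `"HLA-A*11:01"`.
#' @param predictor predictor label entering the default weight hash.
#' @param weights optional `function(allele, position, aa)` returning a
#'   weight in \[0, 1\]; overrides the hash (test hook).
#' @return IC50 in nM.
#' @examples
#' toyPredict("KTDIDLAVDK", "HLA-A*11:01")
#' toyPredict("KTDIDLAVDK", "HLA-A*11:01", weights = function(a, p, aa) 0.5)
#' @export
toyPredict <- function(peptide, allele, predictor = "toy", weights = NULL) {
  .checkPeptide(peptide)
  .checkAllele(allele)
  aa <- strsplit(peptide, "")[[1]]
  w <- if (is.null(weights)) {
    vapply(seq_along(aa), function(i)
      .unitHash(paste(predictor, allele, i, aa[i], sep = "|")), numeric(1))
  } else {
    vapply(seq_along(aa), function(i) weights(allele, i, aa[i]), numeric(1))
  }
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  unname(50000^(1 - mean(w)))
}

#' Consensus vote over a predictor panel
#'
#' TRUE when at least `minSupport` of the supplied IC50s are at or below
#' `threshold` (the boundary is inclusive: an IC50 of exactly 500 nM counts
#' as a binder).
#'
#' @param ic50s positive IC50 values (nM), one per predictor.
#' @param threshold binder cutoff in nM.
#' @param minSupport minimum number of predictors at or below the cutoff.
#' @return Logical scalar.
#' @examples
#' consensusVote(c(100, 200, 300, 600, 700))  # TRUE, 3 of 5
#' @export
consensusVote <- function(ic50s, threshold = 500, minSupport = 3) {
  if (length(ic50s) < 1L) stop("ic50s must be non-empty", call. = FALSE)
  if (any(!is.finite(ic50s)) || any(ic50s <= 0))
    stop("all IC50 values must be positive", call. = FALSE)
  sum(ic50s <= threshold) >= minSupport
}

#' Wildtype/mutant IC50 fold change (agretopicity)
#'
#' `IC50(WT) / IC50(MT)`; values above 1 mean the mutant peptide is the
#' stronger predicted binder.
#'
#' @param ic50Wt,ic50Mt positive IC50 values in nM, vectorized.
#' @return Positive numeric.
#' @examples
#' foldChange(2110.72, 13.346)  # ~158.15
#' @export
foldChange <- function(ic50Wt, ic50Mt) {
  if (any(!is.finite(ic50Wt)) || any(!is.finite(ic50Mt)) ||
      any(ic50Wt <= 0) || any(ic50Mt <= 0))
    stop("IC50 values must be positive and finite", call. = FALSE)
  ic50Wt / ic50Mt
}

#' Prediction sources
#'
#' A prediction source is a `function(peptide, allele, predictor)` returning
#' an IC50 in nM; it is how the screen consumes binding predictions without
#' caring whether they came from an external adapter cache or the built-in
#' predictor.
#'
#' `cachePredictionSource()` wraps a cache table (columns `peptide`,
#' `allele`, `predictor`, `ic50_nM`, as written by external adapters or
#' [simulateCohort()]); an unresolvable triple is an error naming it.
#' `toyPredictionSource()` routes every query to [toyPredict()], keyed by
#' predictor name so panel members differ.
#'
#' @param cache `data.frame` cache table.
#' @return A prediction source function.
#' @rdname predictionSources
#' @export
cachePredictionSource <- function(cache) {
  stopifnot(all(c("peptide", "allele", "predictor", "ic50_nM") %in% names(cache)))
  keys <- paste(cache$peptide, cache$allele, cache$predictor, sep = "|")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)]
    bad <- keys %in% dup
    if (any(abs(cache$ic50_nM[bad] - stats::ave(cache$ic50_nM, keys, FUN = function(x) x[1])[bad]) > 1e-9))
      stop("binding cache holds conflicting IC50s for the same (peptide, allele, predictor)", call. = FALSE)
  }
  values <- cache$ic50_nM
  function(peptide, allele, predictor) {
    i <- match(paste(peptide, allele, predictor, sep = "|"), keys)
    if (anyNA(i))
      stop(sprintf("no cached prediction for (%s, %s, %s)",
                   peptide[which(is.na(i))[1]], allele[which(is.na(i))[1]],
                   predictor[which(is.na(i))[1]]), call. = FALSE)
    values[i]
  }
}

#' @rdname predictionSources
#' @export
toyPredictionSource <- function() {
  function(peptide, allele, predictor) {
    mapply(function(p, a, pr) toyPredict(p, a, predictor = pr),
           peptide, allele, predictor, USE.NAMES = FALSE)
  }
}

#' Read or write a binding-prediction cache
#'
#' Tab-separated with header `peptide`, `allele`, `predictor`, `ic50_nM`;
#' the dialect external predictor adapters are expected to emit.
#'
#' @param file path to the TSV.
#' @param cache cache `data.frame` to write.
#' @return `readBindingCache` returns the cache `data.frame`;
#'   `writeBindingCache` returns `file` invisibly.
#' @rdname bindingCacheIO
#' @export
readBindingCache <- function(file) {
  cache <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "predictor", "ic50_nM")
  if (!all(need %in% names(cache)))
    stop("binding cache needs columns peptide, allele, predictor, ic50_nM", call. = FALSE)
  if (any(!is.finite(cache$ic50_nM)) || any(cache$ic50_nM <= 0))
    stop("cached IC50s must be positive", call. = FALSE)
  cache[need]
}

#' @rdname bindingCacheIO
#' @export
writeBindingCache <- function(cache, file) {
  utils::write.table(cache[c("peptide", "allele", "predictor", "ic50_nM")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Best-binding allele for a mutant/wildtype peptide pair
#'
#' Scores the mutant peptide against every patient allele with the primary
#' predictor and selects the allele minimizing the mutant IC50 (ties broken
#' by lexicographically smaller allele name, so results are deterministic).
#' The wildtype IC50 and the consensus-panel mutant IC50s are then computed
#' for that same allele and register.
#'
#' @param mtSeq,wtSeq the mutant and wildtype peptides of one pair.
#' @param alleles patient HLA class I alleles (at least one).
#' @param panel a [PredictorPanel-class].
#' @param source a prediction source (see [cachePredictionSource()]).
#' @return List with `allele`, `mt_ic50`, `wt_ic50` (primary predictor) and
#'   `consensus` (named mutant IC50s, one per consensus predictor).
#' @export
bestAlleleBinding <- function(mtSeq, wtSeq, alleles, panel = PredictorPanel(),
                              source) {
  stopifnot(is(panel, "PredictorPanel"), is.function(source))
  if (length(alleles) < 1L) stop("at least one HLA allele is required", call. = FALSE)
  .checkAllele(alleles)
  mtPrimary <- vapply(alleles, function(a) source(mtSeq, a, panel@primary), numeric(1))
  best <- alleles[order(mtPrimary, alleles)][1L]
  cons <- vapply(panel@consensus, function(pr) source(mtSeq, best, pr), numeric(1))
  list(allele = best,
       mt_ic50 = unname(mtPrimary[match(best, alleles)]),
       wt_ic50 = source(wtSeq, best, panel@primary),
       consensus = cons)
}
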