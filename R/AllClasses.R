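#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Filter thresholds for the six-criterion neoantigen screen
#'
#' Holds the numeric cutoffs applied by [applyFilters()]. Defaults follow the
#' pVAC-Seq-derived screen: tumor DNA and RNA depth >= 10 reads, DNA and RNA
#' variant allele fraction >= 0.4, expression FPKM > 1 (strict), primary
#' predictor mutant IC50 <= 500 nM (inclusive), mutant IC50 <= 500 nM in at
#' least 3 of the 5 consensus predictors (inclusive), and wildtype/mutant
#' fold change > 1 (strict).
#'
#' @slot minDepth minimum read depth, applied to both the DNA and RNA sample.
#' @slot minVAF minimum variant allele fraction, both samples.
#' @slot minFPKM expression cutoff in FPKM; the comparison is strict (>).
#' @slot maxIC50Primary maximum mutant IC50 (nM) from the primary predictor;
#'   inclusive (<=).
#' @slot consensusIC50 IC50 cutoff (nM) used in the consensus vote; inclusive.
#' @slot consensusMinSupport minimum number of consensus predictors at or
#'   below `consensusIC50`.
#' @slot minFoldChange minimum wildtype/mutant IC50 ratio; strict (>).
#' @export
setClass("FilterThresholds", representation(
  minDepth = "numeric",
  minVAF = "numeric",
  minFPKM = "numeric",
  maxIC50Primary = "numeric",
  consensusIC50 = "numeric",
  consensusMinSupport = "numeric",
  minFoldChange = "numeric"
))

setValidity("FilterThresholds", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@minDepth <= 0) msg <- c(msg, "minDepth must be positive")
  if (object@minVAF <= 0 || object@minVAF > 1) msg <- c(msg, "minVAF must lie in (0, 1]")
  if (object@minFPKM <= 0) msg <- c(msg, "minFPKM must be positive")
  if (object@maxIC50Primary <= 0) msg <- c(msg, "maxIC50Primary must be positive")
  if (object@consensusIC50 <= 0) msg <- c(msg, "consensusIC50 must be positive")
  if (object@consensusMinSupport < 1) msg <- c(msg, "consensusMinSupport must be >= 1")
  if (object@minFoldChange <= 0) msg <- c(msg, "minFoldChange must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterThresholds-class Constructor with the default screen
#'   cutoffs.
#' @param minDepth,minVAF,minFPKM,maxIC50Primary,consensusIC50,consensusMinSupport,minFoldChange
#'   see the corresponding slots.
#' @return A `FilterThresholds` object.
#' @examples
#' FilterThresholds()
#' FilterThresholds(minVAF = 0.2)  # relaxed VAF screen
#' @export
FilterThresholds <- function(minDepth = 10, minVAF = 0.4, minFPKM = 1,
                             maxIC50Primary = 500, consensusIC50 = 500,
                             consensusMinSupport = 3, minFoldChange = 1) {
  new("FilterThresholds", minDepth = minDepth, minVAF = minVAF,
      minFPKM = minFPKM, maxIC50Primary = maxIC50Primary,
      consensusIC50 = consensusIC50, consensusMinSupport = consensusMinSupport,
      minFoldChange = minFoldChange)
}

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds (six-criterion neoantigen screen)\n")
  cat(sprintf("  (1) DNA/RNA depth       >= %g\n", object@minDepth))
  cat(sprintf("  (2) DNA/RNA VAF         >= %g\n", object@minVAF))
  cat(sprintf("  (3) FPKM                >  %g\n", object@minFPKM))
  cat(sprintf("  (4) primary MT IC50     <= %g nM\n", object@maxIC50Primary))
  cat(sprintf("  (5) consensus vote      >= %g of panel at <= %g nM\n",
              object@consensusMinSupport, object@consensusIC50))
  cat(sprintf("  (6) fold change WT/MT   >  %g\n", object@minFoldChange))
})

#' Binding-predictor panel
#'
#' Names the primary predictor, whose mutant IC50 feeds the primary-IC50
#' criterion and whose wildtype/mutant ratio feeds the fold-change criterion,
#' and the consensus predictors that vote on the consensus criterion. The
#' default panel mirrors the published screen: NetMHC as primary, with
#' MHCflurry, MHCnuggetsI, SMM, SMMPMBEC and Pickpocket voting.
#'
#' @slot primary single predictor name.
#' @slot consensus character vector of consensus predictor names (5 by
#'   default); must not contain the primary.
#' @export
setClass("PredictorPanel", representation(
  primary = "character",
  consensus = "character"
))

setValidity("PredictorPanel", function(object) {
  msg <- character()
  if (length(object@primary) != 1L || is.na(object@primary) || !nzchar(object@primary))
    msg <- c(msg, "primary must be a single non-empty predictor name")
  if (length(object@consensus) < 1L) msg <- c(msg, "consensus panel must have at least one member")
  if (anyDuplicated(object@consensus)) msg <- c(msg, "consensus predictor names must be distinct")
  if (object@primary %in% object@consensus)
    msg <- c(msg, "primary predictor must not sit on the consensus panel")
  if (length(msg)) msg else TRUE
})

#' @describeIn PredictorPanel-class Constructor; defaults to the published
#'   six-predictor panel.
#' @param primary,consensus see the corresponding slots.
#' @return A `PredictorPanel` object.
#' @examples
#' PredictorPanel()
#' @export
PredictorPanel <- function(primary = "NetMHC",
                           consensus = c("MHCflurry", "MHCnuggetsI", "SMM",
                                         "SMMPMBEC", "Pickpocket")) {
  new("PredictorPanel", primary = primary, consensus = consensus)
}

setMethod("show", "PredictorPanel", function(object) {
  cat("PredictorPanel\n")
  cat("  primary  :", object@primary, "\n")
  cat("  consensus:", paste(object@consensus, collapse = ", "), "\n")
})

#' Ground truth of a simulated cohort
#'
#' Records which planted variants are guaranteed to survive all six filter
#' criteria and, for each decoy, the single criterion (1--6) it was built to
#' violate.
#'
#' @slot plantedPass variant identifiers built to pass every criterion with
#'   margin.
#' @slot plantedFail named integer vector: names are decoy variant
#'   identifiers, values the violated criterion index in 1..6.
#' @slot seed integer master seed the cohort was generated from.
#' @export
setClass("CohortTruth", representation(
  plantedPass = "character",
  plantedFail = "integer",
  seed = "integer"
))

setValidity("CohortTruth", function(object) {
  msg <- character()
  if (length(object@plantedFail) &&
      (is.null(names(object@plantedFail)) || any(!nzchar(names(object@plantedFail)))))
    msg <- c(msg, "plantedFail must be named by variant identifier")
  if (length(object@plantedFail) && !all(object@plantedFail %in% 1:6))
    msg <- c(msg, "plantedFail criterion indices must lie in 1..6")
  if (any(object@plantedPass %in% names(object@plantedFail)))
    msg <- c(msg, "plantedPass and plantedFail identifiers must be disjoint")
  if (anyDuplicated(c(object@plantedPass, names(object@plantedFail))))
    msg <- c(msg, "variant identifiers must be unique")
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf("CohortTruth: %d planted passers, %d decoys (seed %d)\n",
              length(object@plantedPass), length(object@plantedFail), object@seed))
  if (length(object@plantedFail)) {
    tab <- table(factor(object@plantedFail, levels = 1:6))
    cat("  decoys per criterion:", paste(sprintf("(%s)=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' Per-frame MM/GBSA energy components over a trajectory
#'
#' One row per trajectory frame with the free energies (kcal/mol) of the
#' peptide--HLA complex, the receptor alone and the ligand alone. The binding
#' free energy of a frame is `g_complex - g_receptor - g_ligand`.
#'
#' @slot frames `data.frame` with columns `time_ns`, `g_complex`,
#'   `g_receptor`, `g_ligand`; times strictly increasing.
#' @export
setClass("EnergySeries", representation(frames = "data.frame"))

setValidity("EnergySeries", function(object) {
  fr <- object@frames
  need <- c("time_ns", "g_complex", "g_receptor", "g_ligand")
  if (!all(need %in% names(fr)))
    return(paste("frames must have columns", paste(need, collapse = ", ")))
  if (nrow(fr) < 1L) return("frames must contain at least one row")
  if (!all(vapply(fr[need], function(x) all(is.finite(x)), logical(1))))
    return("all energy components and times must be finite")
  if (any(fr$time_ns < 0)) return("times must be non-negative")
  if (is.unsorted(fr$time_ns, strictly = TRUE))
    return("times must be strictly increasing")
  TRUE
})

#' @describeIn EnergySeries-class Constructor from component vectors.
#' @param time_ns,g_complex,g_receptor,g_ligand equal-length numeric vectors.
#' @return An `EnergySeries` object.
#' @export
EnergySeries <- function(time_ns, g_complex, g_receptor, g_ligand) {
  new("EnergySeries", frames = data.frame(
    time_ns = as.numeric(time_ns), g_complex = as.numeric(g_complex),
    g_receptor = as.numeric(g_receptor), g_ligand = as.numeric(g_ligand)))
}

#' @describeIn EnergySeries-class Per-frame binding free energies
#'   (`g_complex - g_receptor - g_ligand`), in frame order.
#' @param series an `EnergySeries`.
#' @export
bindingEnergy <- function(series) {
  stopifnot(is(series, "EnergySeries"))
  with(series@frames, g_complex - g_receptor - g_ligand)
}

#' @describeIn EnergySeries-class Frame table accessor.
#' @export
energyFrames <- function(series) {
  stopifnot(is(series, "EnergySeries"))
  series@frames
}

setMethod("show", "EnergySeries", function(object) {
  fr <- object@frames
  dg <- bindingEnergy(object)
  cat(sprintf("EnergySeries: %d frames, %.1f-%.1f ns, dG mean %.2f kcal/mol\n",
              nrow(fr), min(fr$time_ns), max(fr$time_ns), mean(dg)))
})

#' A simulated tumor cohort with planted ground truth
#'
#' Container returned by [simulateCohort()]: the annotated missense variants,
#' the expression table, a deterministic binding-prediction cache covering
#' every peptide/allele/predictor triple the screen will query, the proteome
#' the peptides derive from, the patient HLA allele list, and the
#' [CohortTruth-class] record of which variants were planted to pass or to
#' fail a specific criterion.
#'
#' @slot variants `DataFrame` of somatic missense variants (one per row).
#' @slot expression `data.frame` with `gene_id` and `fpkm`.
#' @slot bindingCache `data.frame` with `peptide`, `allele`, `predictor`,
#'   `ic50_nM`.
#' @slot truth a [CohortTruth-class].
#' @slot proteome an [Biostrings::AAStringSet-class] keyed by gene.
#' @slot alleles patient HLA class I allele names.
#' @export
setClass("SyntheticCohort", representation(
  variants = "DFrame",
  expression = "data.frame",
  bindingCache = "data.frame",
  truth = "CohortTruth",
  proteome = "AAStringSet",
  alleles = "character"
))

#' @describeIn SyntheticCohort-class Variant table accessor.
#' @param cohort a `SyntheticCohort`.
#' @export
cohortVariants <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@variants }

#' @describeIn SyntheticCohort-class Expression table accessor.
#' @export
cohortExpression <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@expression }

#' @describeIn SyntheticCohort-class Binding-prediction cache accessor.
#' @export
cohortBindingCache <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@bindingCache }

#' @describeIn SyntheticCohort-class Ground-truth accessor.
#' @export
cohortTruth <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@truth }

#' @describeIn SyntheticCohort-class Proteome accessor.
#' @export
cohortProteome <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@proteome }

#' @describeIn SyntheticCohort-class Patient HLA allele accessor.
#' @export
cohortAlleles <- function(cohort) { stopifnot(is(cohort, "SyntheticCohort")); cohort@alleles }

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d variants over %d proteins, %d alleles\n",
              nrow(object@variants), length(object@proteome), length(object@alleles)))
  show(object@truth)
  cat(sprintf("  binding cache: %d predictions\n", nrow(object@bindingCache)))
})

#' Screened neoantigen candidates
#'
#' Result of [screenNeoantigens()]: one row per variant holding its best
#' peptide register and allele, the primary and consensus IC50s, the fold
#' change, the six per-criterion flags and the overall pass verdict, together
#' with the thresholds and predictor panel used.
#'
#' @slot candidates `DataFrame`, one candidate per variant.
#' @slot thresholds the [FilterThresholds-class] applied.
#' @slot panel the [PredictorPanel-class] used.
#' @export
setClass("CandidateSet", representation(
  candidates = "DFrame",
  thresholds = "FilterThresholds",
  panel = "PredictorPanel"
))

setValidity("CandidateSet", function(object) {
  cd <- object@candidates
  need <- c("id", "gene", "substitution", "allele", "length", "mut_offset",
            "mt_seq", "wt_seq", "mt_ic50", "wt_ic50", "fold_change",
            paste0("crit", 1:6), "passed")
  if (!all(need %in% colnames(cd)))
    return(paste("candidates must have columns", paste(setdiff(need, colnames(cd)), collapse = ", ")))
  flags <- as.matrix(as.data.frame(cd[, paste0("crit", 1:6)]))
  if (nrow(cd) && !identical(unname(cd$passed), unname(apply(flags, 1L, all))))
    return("passed must equal the conjunction of the six criterion flags")
  TRUE
})

#' @describeIn CandidateSet-class Full candidate table (passers and
#'   failures, with per-criterion flags).
#' @param x a `CandidateSet`.
#' @export
candidates <- function(x) { stopifnot(is(x, "CandidateSet")); x@candidates }

#' @describeIn CandidateSet-class Candidates passing all six criteria,
#'   ranked by descending fold change (see [rankCandidates()]).
#' @export
passingCandidates <- function(x) {
  stopifnot(is(x, "CandidateSet"))
  rankCandidates(x@candidates[x@candidates$passed, , drop = FALSE])
}

#' @describeIn CandidateSet-class Thresholds accessor.
#' @export
screenThresholds <- function(x) { stopifnot(is(x, "CandidateSet")); x@thresholds }

setMethod("show", "CandidateSet", function(object) {
  cd <- object@candidates
  cat(sprintf("CandidateSet: %d variants screened, %d passed all six criteria\n",
              nrow(cd), sum(cd$passed)))
  if (nrow(cd)) {
    fails <- vapply(1:6, function(k) sum(!cd[[paste0("crit", k)]]), integer(1))
    cat("  failures per criterion:",
        paste(sprintf("(%d)=%d", 1:6, fails), collapse = " "), "\n")
  }
})
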