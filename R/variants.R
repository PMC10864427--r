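#' Variant allele fraction
#'
#' VAF is the fraction of reads at a site supporting the alternate allele,
#' `alt / depth`, with depth taken as the total depth at the site (the DP
#' convention) rather than ref + alt, so that the depth and VAF criteria see
#' the same denominator at multi-allelic sites.
#'
#' @param alt alternate-supporting read count(s).
#' @param depth total read depth(s) at the site; must be >= 1.
#' @return Numeric in \[0, 1\], vectorized over its arguments.
#' @examples
#' computeVAF(4, 10)   # 0.4
#' computeVAF(7, 20)   # 0.35
#' @export
computeVAF <- function(alt, depth) {
  if (any(!is.finite(depth)) || any(depth < 1))
    stop("depth must be >= 1 to compute a VAF (zero-depth sites are undefined, not below threshold)",
         call. = FALSE)
  if (any(!is.finite(alt)) || any(alt < 0) || any(alt > depth))
    stop("alt counts must satisfy 0 <= alt <= depth", call. = FALSE)
  alt / depth
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `FPKM = fragments * 1e9 / (gene_length_bp * total_mapped)`: the fragment
#' count normalized by transcript length in kilobases and library size in
#' millions of mapped fragments.
#'
#' @param fragments fragment count(s) assigned to the gene.
#' @param geneLengthBp transcript length(s) in base pairs; must be >= 1.
#' @param totalMapped total mapped fragments in the library; must be >= 1.
#' @return Non-negative numeric, vectorized.
#' @examples
#' computeFPKM(10, 1000, 1e6)    # 10
#' computeFPKM(500, 2000, 1e7)   # 25
#' @export
computeFPKM <- function(fragments, geneLengthBp, totalMapped) {
  if (any(!is.finite(geneLengthBp)) || any(geneLengthBp < 1))
    stop("geneLengthBp must be >= 1", call. = FALSE)
  if (any(!is.finite(totalMapped)) || any(totalMapped < 1))
    stop("totalMapped must be >= 1 (empty library has no FPKM)", call. = FALSE)
  if (any(!is.finite(fragments)) || any(fragments < 0))
    stop("fragments must be non-negative", call. = FALSE)
  fragments * 1e9 / (geneLengthBp * totalMapped)
}

#' Classify a codon change as missense, synonymous or nonsense
#'
#' Translates reference and alternate codons with the standard genetic code.
#' A change is `missense` when both translations are standard amino acids and
#' they differ; `synonymous` when they agree; `nonsense` when either codon is
#' a stop.
#'
#' @param codonRef,codonAlt 3-letter nucleotide strings over A/C/G/T,
#'   vectorized; each pair must differ in at least one base.
#' @return `data.frame` with columns `class` ("missense", "synonymous",
#'   "nonsense"), `wt_aa`, `mt_aa` (amino acids are `NA` unless missense).
#' @examples
#' classifySubstitution("GAG", "AAG")  # E -> K missense (G-A change)
#' classifySubstitution("CTG", "TTG")  # synonymous (L)
#' @export
classifySubstitution <- function(codonRef, codonAlt) {
  codonRef <- toupper(codonRef); codonAlt <- toupper(codonAlt)
  ok <- function(x) grepl("^[ACGT]{3}$", x)
  if (any(!ok(codonRef)) || any(!ok(codonAlt)))
    stop("codons must be 3-letter strings over A, C, G, T", call. = FALSE)
  if (any(codonRef == codonAlt))
    stop("codon_ref and codon_alt must differ", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  wt <- unname(code[codonRef]); mt <- unname(code[codonAlt])
  class <- ifelse(wt == "*" | mt == "*", "nonsense",
                  ifelse(wt == mt, "synonymous", "missense"))
  data.frame(class = class,
             wt_aa = ifelse(class == "missense", wt, NA_character_),
             mt_aa = ifelse(class == "missense", mt, NA_character_))
}

#' Parse annotated somatic missense variants from a VCF
#'
#' Reads a VCF (v4.x) carrying per-sample `AD`/`DP` FORMAT fields for a tumor
#' DNA and a tumor RNA sample, plus a protein-level annotation in a single
#' INFO key formatted as
#' `gene|transcript|protein_pos|wt_aa|mt_aa|codon_ref|codon_alt|class`.
#' One variant is returned per missense record; records that are not missense
#' or that lack the required fields are skipped, counted and reported in a
#' single warning. When `checkCodon` is `TRUE` the annotated amino-acid change
#' is re-derived from the codons with [classifySubstitution()] and any
#' disagreement is a hard error (annotation and sequence out of sync).
#'
#' @param vcfFile path to the VCF.
#' @param sampleNames names of the DNA and RNA sample columns, in that order.
#' @param infoKey INFO key holding the protein annotation.
#' @param checkCodon verify codon translation against the annotated amino
#'   acids.
#' @return A [S4Vectors::DataFrame-class] with one row per missense variant:
#'   `id`, `gene`, `transcript`, `protein_pos`, `wt_aa`, `mt_aa`,
#'   `codon_ref`, `codon_alt`, `dna_depth`, `dna_alt`, `rna_depth`,
#'   `rna_alt`. The number of skipped records is in `metadata()$n_skipped`.
#' @export
parseVariants <- function(vcfFile, sampleNames = c("TUMOR_DNA", "TUMOR_RNA"),
                          infoKey = "PANN", checkCodon = TRUE) {
  stopifnot(length(sampleNames) == 2L)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcfFile)),
    error = function(e) stop(sprintf("malformed VCF '%s': %s", vcfFile, conditionMessage(e)),
                             call. = FALSE))
  empty <- S4Vectors::DataFrame(
    id = character(), gene = character(), transcript = character(),
    protein_pos = integer(), wt_aa = character(), mt_aa = character(),
    codon_ref = character(), codon_alt = character(),
    dna_depth = integer(), dna_alt = integer(),
    rna_depth = integer(), rna_alt = integer())
  if (nrow(vcf) == 0L) {
    S4Vectors::metadata(empty)$n_skipped <- 0L
    return(empty)
  }
  if (!all(sampleNames %in% colnames(vcf)))
    stop(sprintf("VCF lacks sample column(s): %s",
                 paste(setdiff(sampleNames, colnames(vcf)), collapse = ", ")), call. = FALSE)
  if (!infoKey %in% names(VariantAnnotation::info(vcf)))
    stop(sprintf("VCF INFO lacks the annotation key '%s'", infoKey), call. = FALSE)

  ann <- as.character(VariantAnnotation::info(vcf)[[infoKey]])
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  ids <- rownames(vcf)

  rows <- vector("list", nrow(vcf))
  skipped <- character()
  for (i in seq_len(nrow(vcf))) {
    fields <- strsplit(ann[i], "|", fixed = TRUE)[[1]]
    if (is.na(ann[i]) || length(fields) != 8L) {
      skipped <- c(skipped, sprintf("%s (missing/short %s annotation)", ids[i], infoKey)); next
    }
    if (fields[8] != "missense") {
      skipped <- c(skipped, sprintf("%s (%s)", ids[i], fields[8])); next
    }
    adDna <- ad[[i, sampleNames[1]]]; adRna <- ad[[i, sampleNames[2]]]
    dpDna <- dp[i, sampleNames[1]];   dpRna <- dp[i, sampleNames[2]]
    if (length(adDna) < 2L || length(adRna) < 2L ||
        anyNA(adDna) || anyNA(adRna) || is.na(dpDna) || is.na(dpRna)) {
      skipped <- c(skipped, sprintf("%s (missing AD/DP)", ids[i])); next
    }
    if (checkCodon) {
      cls <- classifySubstitution(fields[6], fields[7])
      if (cls$class != "missense" || cls$wt_aa != fields[4] || cls$mt_aa != fields[5])
        stop(sprintf("variant %s: codon change %s>%s does not encode annotated %s%s%s",
                     ids[i], fields[6], fields[7], fields[4], fields[3], fields[5]),
             call. = FALSE)
    }
    rows[[i]] <- data.frame(
      id = ids[i], gene = fields[1], transcript = fields[2],
      protein_pos = as.integer(fields[3]), wt_aa = fields[4], mt_aa = fields[5],
      codon_ref = fields[6], codon_alt = fields[7],
      dna_depth = as.integer(dpDna), dna_alt = as.integer(adDna[2]),
      rna_depth = as.integer(dpRna), rna_alt = as.integer(adRna[2]))
  }
  if (length(skipped))
    warning(sprintf("skipped %d non-missense/incomplete record(s): %s",
                    length(skipped), paste(skipped, collapse = "; ")), call. = FALSE)
  kept <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(kept)) S4Vectors::DataFrame(do.call(rbind, kept)) else empty
  S4Vectors::metadata(out)$n_skipped <- length(skipped)
  out
}

#' Read a gene expression table
#'
#' Tab-separated file with columns `gene_id` and `fpkm` (header required).
#'
#' @param file path to the TSV.
#' @return `data.frame` with `gene_id` and non-negative `fpkm`.
#' @export
readExpression <- function(file) {
  expr <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(expr)))
    stop("expression table needs columns 'gene_id' and 'fpkm'", call. = FALSE)
  if (any(!is.finite(expr$fpkm)) || any(expr$fpkm < 0))
    stop("fpkm values must be finite and non-negative", call. = FALSE)
  expr[c("gene_id", "fpkm")]
}
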