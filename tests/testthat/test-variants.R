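test_that("VAF is alt over total depth, bounded and monotone", {
  expect_identical(computeVAF(4, 10), 0.4)
  expect_identical(computeVAF(0, 10), 0)
  expect_identical(computeVAF(7, 20), 0.35)
  expect_error(computeVAF(1, 0), "depth")
  expect_error(computeVAF(5, 4), "alt")
  for (depth in c(1, 7, 33)) {
    v <- computeVAF(0:depth, depth)
    expect_true(all(v >= 0 & v <= 1))
    expect_false(is.unsorted(v))
  }
})

test_that("FPKM follows fragments * 1e9 / (length * library) and scales linearly", {
  expect_equal(computeFPKM(10, 1000, 1e6), 10)
  expect_equal(computeFPKM(0, 1234, 5e6), 0)
  expect_equal(computeFPKM(500, 2000, 1e7), 25)
  expect_error(computeFPKM(10, 0, 1e6), "geneLengthBp")
  expect_error(computeFPKM(10, 1000, 0), "totalMapped")
  base <- computeFPKM(37, 1500, 2e6)
  expect_equal(computeFPKM(2 * 37, 1500, 2e6), 2 * base)
  expect_equal(computeFPKM(37, 3 * 1500, 2e6), base / 3)
  expect_equal(computeFPKM(37, 1500, 4 * 2e6), base / 4)
})

test_that("codon classification reproduces the published substitutions", {
  ek <- classifySubstitution("GAG", "AAG")  # G-A change, as for ADGRL1/PARP1 E->K
  expect_identical(ek$class, "missense")
  expect_identical(ek$wt_aa, "E")
  expect_identical(ek$mt_aa, "K")
  expect_identical(classifySubstitution("CTG", "TTG")$class, "synonymous")
  expect_identical(classifySubstitution("TAC", "TAA")$class, "nonsense")
  # I->F, V->M, I->T as in the candidate table
  expect_identical(classifySubstitution("ATT", "TTT")[, c("wt_aa", "mt_aa")],
                   data.frame(wt_aa = "I", mt_aa = "F"))
  expect_identical(classifySubstitution("GTG", "ATG")[, c("wt_aa", "mt_aa")],
                   data.frame(wt_aa = "V", mt_aa = "M"))
  expect_identical(classifySubstitution("ATA", "ACA")[, c("wt_aa", "mt_aa")],
                   data.frame(wt_aa = "I", mt_aa = "T"))
  expect_error(classifySubstitution("AXG", "AAG"), "A, C, G, T")
  expect_error(classifySubstitution("AAG", "AAG"), "differ")
})

test_that("codon classification agrees with an independent codon-table oracle on all ordered pairs", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  grid <- expand.grid(ref = codons, alt = codons, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  got <- classifySubstitution(grid$ref, grid$alt)
  oracle <- setNames(toupper(seqinrTranslate(codons)), codons)
  wt <- unname(oracle[grid$ref]); mt <- unname(oracle[grid$alt])
  expClass <- ifelse(wt == "*" | mt == "*", "nonsense",
                     ifelse(wt == mt, "synonymous", "missense"))
  expect_identical(got$class, expClass)
  miss <- expClass == "missense"
  expect_identical(got$wt_aa[miss], wt[miss])
  expect_identical(got$mt_aa[miss], mt[miss])
})

test_that("VCF parsing keeps missense records and counts skips", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PANN,Number=1,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR_DNA", "TUMOR_RNA", sep = "\t"),
    paste("chr1", 100, "v1", "G", "A", ".", "PASS",
          "PANN=G1|tx1|274|E|K|GAG|AAG|missense", "DP:AD", "40:16,24", "30:12,18", sep = "\t"),
    paste("chr1", 200, "v2", "C", "T", ".", "PASS",
          "PANN=G2|tx2|10|L|L|CTG|TTG|synonymous", "DP:AD", "40:16,24", "30:12,18", sep = "\t"),
    paste("chr1", 300, "v3", "G", "A", ".", "PASS",
          "PANN=G3|tx3|5|E|K|GAG|AAG|missense", "DP", "40", "30", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_warning(v <- parseVariants(f), "skipped 2")
  expect_identical(nrow(v), 1L)
  expect_identical(v$id, "v1")
  expect_identical(v$dna_alt, 24L)
  expect_identical(v$rna_depth, 30L)
  expect_identical(S4Vectors::metadata(v)$n_skipped, 2L)

  # annotation/codon disagreement is a hard error
  bad <- sub("274\\|E\\|K\\|GAG\\|AAG", "274|E|Q|GAG|AAG", vcf)
  writeLines(bad, f)
  expect_error(suppressWarnings(parseVariants(f)), "does not encode")
})

test_that("empty VCF with a valid header parses to an empty table", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PANN,Number=1,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR_DNA", "TUMOR_RNA", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  v <- parseVariants(f)
  expect_identical(nrow(v), 0L)
  expect_identical(S4Vectors::metadata(v)$n_skipped, 0L)
})

test_that("variants written by the cohort generator parse back equal", {
  cohort <- simulateCohort(simulateProteome(5, c(40, 60), 3), nPass = 2,
                           nFailPerCriterion = 0, seed = 3)
  dir <- withr::local_tempdir()
  paths <- writeCohort(cohort, dir)
  parsed <- parseVariants(paths[["vcf"]])
  orig <- as.data.frame(cohortVariants(cohort))
  cols <- c("id", "gene", "transcript", "protein_pos", "wt_aa", "mt_aa",
            "codon_ref", "codon_alt", "dna_depth", "dna_alt", "rna_depth", "rna_alt")
  got <- as.data.frame(parsed)[cols]
  want <- orig[cols]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expr <- readExpression(paths[["expression"]])
  expect_equal(expr$fpkm, cohortExpression(cohort)$fpkm, tolerance = 1e-6)
  cache <- readBindingCache(paths[["cache"]])
  expect_identical(nrow(cache), nrow(cohortBindingCache(cohort)))
})
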