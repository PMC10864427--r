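test_that("proteome simulation is deterministic with validated lengths", {
  one <- simulateProteome(1, c(13, 13), seed = 7)
  expect_identical(Biostrings::width(one), 13L)
  expect_identical(as.character(one), as.character(simulateProteome(1, c(13, 13), seed = 7)))
  expect_error(simulateProteome(0, c(50, 60), 1), "nProteins")
  expect_error(simulateProteome(5, c(12, 40), 1), "13")

  many <- simulateProteome(100, c(50, 500), seed = 1)
  expect_identical(length(many), 100L)
  w <- Biostrings::width(many)
  expect_true(all(w >= 50 & w <= 500))
  letters <- unique(strsplit(paste(as.character(many), collapse = ""), "")[[1]])
  expect_identical(sort(letters), sort(Biostrings::AA_STANDARD))
  expect_false(identical(as.character(many), as.character(simulateProteome(100, c(50, 500), seed = 2))))
})

test_that("cohort construction plants the requested truth structure", {
  cohort <- simulateCohort(simulateProteome(11, c(40, 80), 1), nPass = 5,
                           nFailPerCriterion = 1, seed = 42)
  tr <- cohortTruth(cohort)
  expect_identical(length(tr@plantedPass), 5L)
  expect_identical(length(tr@plantedFail), 6L)
  expect_identical(sort(unname(tr@plantedFail)), 1:6)
  expect_length(intersect(tr@plantedPass, names(tr@plantedFail)), 0)
  v <- cohortVariants(cohort)
  expect_identical(nrow(v), 11L)
  expect_true(all(v$dna_alt <= v$dna_depth))
  expect_true(all(v$rna_alt <= v$rna_depth))
  # planted codons are genuine single-nucleotide missense edits
  cls <- classifySubstitution(v$codon_ref, v$codon_alt)
  expect_identical(unique(cls$class), "missense")
  expect_identical(cls$wt_aa, v$wt_aa)
  expect_identical(cls$mt_aa, v$mt_aa)
  nDiff <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  v$codon_ref, v$codon_alt)
  expect_true(all(nDiff == 1L))

  expect_error(simulateCohort(simulateProteome(3, c(40, 60), 1), nPass = 5,
                              nFailPerCriterion = 1, seed = 1),
               "3 proteins but 11")
})

test_that("cohort generation is a pure function of its seed", {
  prot <- simulateProteome(8, c(40, 60), 4)
  a <- simulateCohort(prot, nPass = 2, nFailPerCriterion = 1, seed = 5)
  b <- simulateCohort(prot, nPass = 2, nFailPerCriterion = 1, seed = 5)
  expect_equal(as.data.frame(cohortVariants(a)), as.data.frame(cohortVariants(b)))
  expect_equal(cohortBindingCache(a), cohortBindingCache(b))
  expect_equal(cohortExpression(a), cohortExpression(b))
  c2 <- simulateCohort(prot, nPass = 2, nFailPerCriterion = 1, seed = 6)
  expect_false(identical(cohortBindingCache(a)$ic50_nM,
                         cohortBindingCache(c2)$ic50_nM))
})

test_that("an all-decoy cohort screens to an empty pass set", {
  cohort <- simulateCohort(simulateProteome(6, c(40, 60), 2), nPass = 0,
                           nFailPerCriterion = 1, seed = 8)
  cs <- screenCohort(cohort)
  expect_identical(nrow(passingCandidates(cs)), 0L)
  expect_identical(unname(screenFunnel(cs)), c(6L, 0L))
})

test_that("restoring a decoy's single violated field makes it pass", {
  cohort <- simulateCohort(simulateProteome(7, c(40, 70), 6), nPass = 1,
                           nFailPerCriterion = 1, seed = 11)
  tr <- cohortTruth(cohort)
  for (id in names(tr@plantedFail)) {
    crit <- tr@plantedFail[[id]]
    fixed <- restoreDecoy(cohort, id, crit)
    cd <- as.data.frame(candidates(screenCohort(fixed)))
    expect_true(cd$passed[cd$id == id],
                label = sprintf("decoy %s (criterion %d) after restore", id, crit))
  }
})

test_that("energy series plant the requested binding free energy", {
  exact <- simulateEnergySeries(50, meanDG = -30, noiseSD = 0, seed = 1)
  expect_equal(bindingEnergy(exact), rep(-30, 50))
  fr <- energyFrames(exact)
  expect_identical(nrow(fr), 50L)
  expect_equal(range(fr$time_ns), c(0, 100))
  expect_false(is.unsorted(fr$time_ns, strictly = TRUE))

  again <- simulateEnergySeries(50, meanDG = -30, noiseSD = 0, seed = 1)
  expect_equal(energyFrames(again), fr)

  noisy <- simulateEnergySeries(2000, meanDG = -30, noiseSD = 1, seed = 3)
  win <- mmgbsaWindow(noisy, c(80, 100))
  expect_lt(abs(win$mean - (-30)), 3 / sqrt(win$n_frames))  # CLT bound
  expect_error(simulateEnergySeries(1, -30, 0, 1), "nFrames")
  expect_error(simulateEnergySeries(10, -30, -1, 1), "noiseSD")
})

test_that("cohorts serialize to the documented on-disk formats", {
  cohort <- simulateCohort(simulateProteome(7, c(40, 60), 5), nPass = 1,
                           nFailPerCriterion = 1, seed = 13)
  dir <- withr::local_tempdir()
  paths <- writeCohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  prot <- Biostrings::readAAStringSet(paths[["proteome"]])
  expect_identical(as.character(prot), as.character(cohortProteome(cohort)))
  expect_identical(readLines(paths[["alleles"]]), cohortAlleles(cohort))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  tr <- cohortTruth(cohort)
  expect_identical(truth$planted_pass, tr@plantedPass)
  expect_identical(sort(names(truth$planted_fail)), sort(names(tr@plantedFail)))
  expect_identical(truth$seed, 13L)
})

test_that("assay plate simulation is seeded and shaped as documented", {
  plate <- simulateAssayPlate(seed = 21)
  expect_identical(nrow(plate), 9L)
  expect_identical(unique(plate$condition), c("MT", "WT", "UP"))
  expect_true(all(plate$value >= 0))
  expect_equal(plate, simulateAssayPlate(seed = 21))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(plate, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readPlate(f)$value, plate$value, tolerance = 1e-6)
})
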