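test_that("anchor distance is the C-alpha separation of the two positions", {
  frame <- atomFrame(
    list("P", 1, "CA", "C", 5, 5, 5),
    list("P", 2, "CA", "C", 0, 0, 0),
    list("P", 9, "CA", "C", 16, 0, 0),
    list("A", 1, "CA", "C", 1, 1, 1))
  for (r in 3:8) frame <- rbind(frame, atomFrame(list("P", r, "CA", "C", r, 0, 0)))
  frame <- frame[order(frame$chain, frame$resno), ]
  expect_equal(anchorDistance(frame, "P"), 16)
  # 3-4-5 triangle and degenerate zero distance
  tri <- atomFrame(list("P", 2, "CA", "C", 0, 0, 0),
                   list("P", 9, "CA", "C", 3, 4, 0))
  expect_equal(anchorDistance(tri, "P", 1, 2), 5)  # positions index residues in order
  same <- atomFrame(list("P", 2, "CA", "C", 1, 2, 3),
                    list("P", 9, "CA", "C", 1, 2, 3))
  expect_equal(anchorDistance(same, "P", 1, 2), 0)

  noCa <- atomFrame(list("P", 2, "N", "N", 0, 0, 0),
                    list("P", 9, "CA", "C", 3, 4, 0))
  expect_error(anchorDistance(noCa, "P", 1, 2), "lacks a CA")
  expect_error(anchorDistance(tri, "Q"), "not present")
})

test_that("the peptide chain is auto-detected as the shortest 8-12-residue chain", {
  frame <- simulateComplexFrame(nPeptide = 9, nReceptor = 30, seed = 2)
  d <- anchorDistance(frame)
  expect_identical(d, anchorDistance(frame, "P"))
  onlyLong <- frame[frame$chain == "A", ]
  expect_error(anchorDistance(onlyLong), "8-12")
})

test_that("contact counting matches the all-pairs oracle and its boundary is inclusive", {
  two <- atomFrame(list("A", 1, "CA", "C", 0, 0, 0),
                   list("P", 1, "CA", "C", 4, 0, 0))
  expect_identical(countContacts(two, "A", "P", cutoff = 4.5), 1L)
  expect_identical(countContacts(two, "A", "P", cutoff = 3.5), 0L)
  expect_identical(countContacts(two, "A", "P", cutoff = 4.0), 1L)  # inclusive

  withH <- rbind(two, atomFrame(list("P", 1, "H", "H", 0.5, 0, 0)))
  expect_identical(countContacts(withH, "A", "P"), 1L)       # H excluded
  expect_identical(countContacts(withH, "A", "P", heavyOnly = FALSE), 2L)

  for (seed in 1:3) {
    frame <- simulateComplexFrame(nPeptide = 10, nReceptor = 10,
                                  boxSize = 12, seed = seed)
    got <- countContacts(frame, "A", "P")
    expect_identical(as.integer(got), as.integer(bruteContacts(frame, "A", "P")))
    # monotone non-decreasing in the cutoff
    cuts <- c(2, 3.5, 4.5, 6, 8)
    counts <- vapply(cuts, function(cc)
      countContacts(frame, "A", "P", cutoff = cc), integer(1))
    expect_false(is.unsorted(counts))
  }
})

test_that("hydrogen bonds require distance and angle; hydrogen-free frames need the fallback", {
  mk <- function(dax, hx, hy) rbind(
    atomFrame(list("A", 1, "N", "N", 0, 0, 0),       # donor heavy
              list("A", 1, "H", "H", hx, hy, 0),     # attached H
              list("P", 1, "O", "O", dax, 0, 0)))    # acceptor
  # D-A 2.9 A, linear D-H...A (angle 180): one bond
  expect_identical(countHbonds(mk(2.9, 1.0, 0), "A", "P"), 1L)
  # D-A 4.0 A: none regardless of geometry
  expect_identical(countHbonds(mk(4.0, 1.0, 0), "A", "P"), 0L)
  # right-angle D-H...A (H off-axis so that the angle is ~90): none
  expect_identical(countHbonds(mk(2.9, 0, 1.0), "A", "P"), 0L)

  noH <- atomFrame(list("A", 1, "N", "N", 0, 0, 0),
                   list("P", 1, "O", "O", 2.9, 0, 0))
  expect_error(countHbonds(noH, "A", "P"), "distanceOnly")
  expect_identical(countHbonds(noH, "A", "P", distanceOnly = TRUE), 1L)

  for (seed in 4:6) {
    frame <- simulateComplexFrame(nPeptide = 10, nReceptor = 10,
                                  boxSize = 10, seed = seed)
    expect_identical(as.integer(countHbonds(frame, "A", "P")),
                     as.integer(bruteHbonds(frame, "A", "P")))
  }
})

test_that("geometric metrics are invariant under rigid motion", {
  frame <- simulateComplexFrame(nPeptide = 9, nReceptor = 12, boxSize = 12,
                                seed = 7)
  moved <- rigidMove(frame)
  expect_equal(anchorDistance(moved, "P"), anchorDistance(frame, "P"))
  expect_identical(countContacts(moved, "A", "P"), countContacts(frame, "A", "P"))
  expect_identical(countHbonds(moved, "A", "P"), countHbonds(frame, "A", "P"))
})

test_that("MM/GBSA window averages the closed 80-100 ns window only", {
  s <- simulateEnergySeries(101, meanDG = -30, noiseSD = 0, seed = 1)
  win <- mmgbsaWindow(s)
  expect_equal(win$mean, -30)
  expect_equal(win$sd, 0)
  expect_identical(win$n_frames, sum(energyFrames(s)$time_ns >= 80))

  # constant components reproduce their difference exactly
  const <- EnergySeries(seq(0, 100, by = 10), -100, -40, -30)
  w <- mmgbsaWindow(const)
  expect_equal(w$mean, -30)
  expect_equal(w$sd, 0)
  expect_identical(w$n_frames, 3L)  # 80, 90, 100: closed on both ends

  # frames before 80 ns may change arbitrarily without affecting the window
  fr <- energyFrames(s)
  fr$g_complex[fr$time_ns < 80] <- fr$g_complex[fr$time_ns < 80] + 500
  tampered <- EnergySeries(fr$time_ns, fr$g_complex, fr$g_receptor, fr$g_ligand)
  expect_equal(mmgbsaWindow(tampered)$mean, win$mean)

  # order within the window does not matter beyond time sorting (validity
  # enforces sorted times; a permuted construction is rejected)
  expect_error(EnergySeries(c(0, 2, 1), 1:3, 1:3, 1:3), "strictly increasing")
  expect_error(mmgbsaWindow(s, c(200, 300)), "no frames")
})

test_that("energy series round-trip through TSV", {
  s <- simulateEnergySeries(25, meanDG = -12.5, noiseSD = 0.5, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEnergySeries(s, f)
  back <- readEnergySeries(f)
  expect_equal(energyFrames(back), energyFrames(s), tolerance = 1e-6)
})

test_that("PDB models map to frames with chains, residues and elements intact", {
  pep <- do.call(rbind, lapply(1:9, function(r)
    atomFrame(list("P", r, "CA", "C", 2 * (r - 1), 0, 0))))
  rec <- atomFrame(list("A", 1, "CA", "C", 0, 5, 0),
                   list("A", 2, "CA", "C", 2, 5, 0))
  frame1 <- rbind(rec, pep)
  frame2 <- frame1
  frame2$x <- frame2$x + 1  # second model, rigidly shifted
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(list(frame1, frame2), f)
  frames <- readStructureFrames(f)
  expect_length(frames, 2L)
  expect_identical(sort(unique(frames[[1]]$chain)), c("A", "P"))
  # P2-P9 distance: CA atoms 2 A apart along x -> 14 A; shift-invariant
  expect_equal(anchorDistance(frames[[1]], "P"), 14)
  expect_equal(anchorDistance(frames[[2]], "P"), 14)
})
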