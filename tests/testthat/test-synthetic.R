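profiles <- hasTypeProfiles()

test_that("profile invariants hold for all shipped types", {
  expect_setequal(names(profiles), c("0", "1A", "1A*", "1B", "1C", "1D", "2"))
  for (p in profiles) {
    for (f in p@motifFreqs) expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(methods::validObject(p))
  }
  expect_equal(profiles[["1A"]]@nTM, 4L)
  expect_setequal(profiles[["1B"]]@cysLoops, c("ECL1", "ECL3"))
  expect_equal(profiles[["1C"]]@cysLoops, "ECL1")
  expect_length(profiles[["2"]]@cysLoops, 0)
})

test_that("generated records realize their type architecture", {
  r1b <- genSequence(profiles[["1B"]], 101)
  loops <- r1b$loops
  cp <- detectCysPairs(loops, r1b$sequence)
  expect_setequal(cp$ecl, c(1, 3))       # pairs in ECL1 and ECL3
  expect_true(all(cp$spacing >= 4 & cp$spacing <= 8))

  r1a <- genSequence(profiles[["1A"]], 102)
  expect_equal(tmCount(r1a$topology), 4)
  expect_lt(nchar(r1a$sequence), 200)
  cp1a <- detectCysPairs(r1a$loops, r1a$sequence)
  expect_equal(cp1a$ecl, 1)              # ECL1 only

  # cys-free types carry no stray periplasmic cysteines
  for (t in c("0", "1D", "2")) {
    r <- genSequence(profiles[[t]], 103)
    expect_equal(nrow(detectCysPairs(r$loops, r$sequence)), 0)
    peri <- r$loops[r$loops$side == "out", ]
    res <- strsplit(r$sequence, "")[[1]]
    periRes <- unlist(lapply(seq_len(nrow(peri)), function(i)
      res[seq(peri$start[i], peri$end[i])]))
    expect_false("C" %in% periRes)
  }
})

test_that("generation is deterministic in profile and seed", {
  a <- genSequence(profiles[["1C"]], 55)
  b <- genSequence(profiles[["1C"]], 55)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$cysPairs, b$cysPairs)
  c <- genSequence(profiles[["1C"]], 56)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("the TM predictor recovers planted topology on clean records", {
  for (t in names(profiles)) {
    for (i in 1:5) {
      r <- genSequence(profiles[[t]], 200 + i)
      pred <- predictTM(r$sequence)
      expect_equal(tmCount(pred), profiles[[t]]@nTM)
      expect_equal(nTermSide(pred), "in")
      dev <- abs(rbind(
        IRanges::start(tmSegments(pred)) - IRanges::start(tmSegments(r$topology)),
        IRanges::end(tmSegments(pred)) - IRanges::end(tmSegments(r$topology))))
      expect_lte(max(dev), 3)
    }
  }
})

test_that("planted motif frequencies converge to the profile", {
  n <- 2000
  x1 <- vapply(seq_len(n), function(i)
    genSequence(profiles[["1A"]], 30000 + i)$motif$residues[["X1"]],
    character(1))
  expect_lt(abs(100 * mean(x1 == "W") - 85), 2)
})

test_that("degenerate loop-length profiles fail with a clear error", {
  p <- profiles[["2"]]
  p@loopLengths$mean <- c(-50, -50)
  p@loopLengths$sd <- c(0.1, 0.1)
  expect_error(genSequence(p, 1), "degenerate")
})

test_that("ECL lengths are ordered type 2 above type 0 on average", {
  e2 <- vapply(1:40, function(i)
    eclLengths(genSequence(profiles[["2"]], 400 + i)$loops)$ecl1, numeric(1))
  e0 <- vapply(1:40, function(i)
    eclLengths(genSequence(profiles[["0"]], 400 + i)$loops)$ecl1, numeric(1))
  expect_gt(mean(e2), mean(e0))
})

test_that("genomes place planted genes, neighbors and fillers correctly", {
  g <- genGenome(11, data.frame(type = "1B", position = 6), seed = 9)
  expect_equal(nrow(g$genes), 11)
  expect_true(all(diff(g$genes$start) > 0))
  expect_true(all(g$genes$end >= g$genes$start))
  expect_match(g$genes$annotation[6], "^HAS_1B")
  expect_error(genGenome(11, data.frame(type = c("1B", "2"),
                                        position = c(6, 6)), seed = 1),
               "same position")
  expect_error(genGenome(5, data.frame(type = "1B", position = 9),
                         seed = 1), "positions")
  # p = 1 and p = 0 neighbor placement
  m1 <- defaultNeighborModel(); m1$perType[["1B"]] <- c(HOS = 1)
  g1 <- genGenome(11, data.frame(type = "1B", position = 6),
                  model = m1, seed = 10)
  expect_true("HOS" %in% g1$genes$annotation[1:11][-6] ||
                grepl("HOS", g1$genes$annotation[6]))
  m0 <- defaultNeighborModel(); m0$perType[["1B"]] <- c(HOS = 0)
  g0 <- genGenome(11, data.frame(type = "1B", position = 6),
                  model = m0, seed = 11)
  expect_false("HOS" %in% g0$genes$annotation)
})

test_that("window co-occurrence converges to the configured probability", {
  # binomial check against the default HOS probability for type 1B
  pTrue <- defaultNeighborModel()$perType[["1B"]][["HOS"]]
  n <- 3000
  hits <- vapply(seq_len(n), function(i) {
    g <- genGenome(11, data.frame(type = "1B", position = 6),
                   seed = 60000 + i, emitProteins = FALSE)
    w <- extractWindow(g$genes, g$genes$gene_id[6])
    "HOS" %in% w$neighbors$annotation
  }, logical(1))
  expect_lt(abs(100 * mean(hits) - 100 * pTrue), 2)
})

test_that("corpora honor requested counts and emit consistent files", {
  dir <- tempfile()
  cc <- genCorpus(c("1A" = 10, "1B" = 10), seed = 77, outDir = dir)
  expect_equal(as.vector(table(cc$truth$type)[c("1A", "1B")]), c(10L, 10L))
  fa <- Biostrings::readAAStringSet(cc$files$fasta)
  truth <- read.delim(cc$files$truth)
  expect_equal(length(fa), nrow(truth))   # truth rows = FASTA records
  expect_setequal(names(fa), truth$record_id)
  topo <- readTopologyTSV(cc$files$topology)
  expect_setequal(names(topo), truth$record_id)
  expect_error(genCorpus(c("1A" = 0), seed = 1), "zero total")
  expect_error(genCorpus(c(ZZ = 5), seed = 1), "no profile")
})

test_that("labelled trees realize clean and intercalated scenarios", {
  asg <- setNames(c("1D", "1D", "1D", "2", "2", "1B", "1B"),
                  paste0("x", 1:7))
  g <- genLabeledTree(asg, "clean", seed = 5)
  expect_true(isMonophyletic(g$tree, paste0("x", 1:3))$monophyletic)
  expect_error(genLabeledTree(asg, "weird"), "arg")
  expect_error(genLabeledTree(asg[1], "clean"), "2 leaves")
  # single shared type: zero transitions
  one <- setNames(rep("1B", 5), paste0("y", 1:5))
  g1 <- genLabeledTree(one, "clean", seed = 6)
  expect_equal(minTransitions(g1$tree, one)$count, 0)
  # intercalated: Fitch minimum equals the planted k
  asg2 <- setNames(c(rep("1B", 10), rep("1C", 6)), paste0("z", 1:16))
  for (k in 2:4) {
    gi <- genLabeledTree(asg2, "intercalated", k = k, seed = 40 + k)
    mt <- minTransitions(gi$tree, asg2, focal = "1C")
    expect_equal(mt$count, k)
    expect_false(isMonophyletic(gi$tree,
                                names(asg2)[asg2 == "1C"])$monophyletic)
  }
})
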