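profiles <- hasTypeProfiles()
panels <- referencePanels()

test_that("cysteine pairs are detected with the spacing window", {
  # loop "ACDEFGCK" as loop content: Cys at offsets 2 and 7, spacing 4
  seq <- paste0(strrep("L", 20), "ACDEFGCK", strrep("L", 20))
  topo <- Topology(cbind(c(1, 29), c(20, 48)), "in", 48)
  loops <- extractLoops(topo)
  cp <- detectCysPairs(loops, seq)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$spacing, 4)
  # exemplar spacing 6 (positions 35 and 42 of a synthetic layout)
  seq2 <- paste0(strrep("L", 20), "DDDDDDDDDDDDDDCDDDDDDCD", strrep("L", 20))
  topo2 <- Topology(cbind(c(1, 44), c(20, 63)), "in", 63)
  cp2 <- detectCysPairs(extractLoops(topo2), seq2)
  expect_equal(cp2$j - cp2$i, 7)  # Cys35/Cys42-like spacing
  expect_equal(cp2$spacing, 6)
  # single Cys: nothing
  seq3 <- paste0(strrep("L", 20), "DDDCDDDD", strrep("L", 20))
  cp3 <- detectCysPairs(extractLoops(topo), seq3)
  expect_equal(nrow(cp3), 0)
})

test_that("the classifier cascade follows the type definitions", {
  r1b <- genSequence(profiles[["1B"]], 301)
  a <- assignType(r1b$sequence, r1b$topology, panels)
  expect_equal(a$type, "1B")
  expect_true(a$cys_ecl1 && a$cys_ecl3)

  r1a <- genSequence(profiles[["1A"]], 302)
  a1a <- assignType(r1a$sequence, r1a$topology, panels)
  expect_equal(a1a$type, "1A")
  expect_equal(a1a$tm_count, 4)

  # partial sequences are never assigned
  short <- substr(r1b$sequence, 1, 90)
  topoShort <- Topology(cbind(c(9, 48), c(32, 79)), "in", 90)
  ap <- assignType(short, topoShort, panels)
  expect_equal(ap$type, "unassigned")
  expect_match(ap$flags, "partial")

  # empty panels are an error when the cascade needs them
  r0 <- genSequence(profiles[["0"]], 303)
  expect_error(assignType(r0$sequence, r0$topology, list()), "panels")
})

test_that("classification is deterministic", {
  r <- genSequence(profiles[["1C"]], 304)
  a1 <- assignType(r$sequence, r$topology, panels)
  a2 <- assignType(r$sequence, r$topology, panels)
  expect_identical(a1, a2)
})

test_that("motif location reads planted residues and reports absence", {
  r <- genSequence(profiles[["1A"]], 310)
  m <- locateMotifs(r$sequence, r$topology)
  expect_true(m$found)
  expect_identical(unname(m$residues[c("E57", "H1", "R")][c(1, 3)]),
                   c("E", "R"))
  expect_true(m$residues[["H1"]] %in% c("H", "N"))
  expect_identical(m$residues[["X1"]], r$motif$residues[["X1"]])
  expect_equal(m$e57_pos, unname(r$motif$positions["E57"]))
  # type-1C records may carry Asn at H1; the pattern accepts it
  found <- FALSE
  for (i in 1:30) {
    rc <- genSequence(profiles[["1C"]], 320 + i)
    if (rc$motif$residues[["H1"]] == "N") {
      mc <- locateMotifs(rc$sequence, rc$topology)
      expect_true(mc$found)
      expect_identical(mc$residues[["H1"]], "N")
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # scrambled non-HAS sequence: not found, not fabricated
  scram <- paste(rep(c("G", "A", "S"), 70), collapse = "")
  topo <- Topology(cbind(c(10, 60), c(35, 85)), "in", 210)
  ms <- locateMotifs(scram, topo)
  expect_false(ms$found)
})

test_that("reference-alignment motif reading agrees with the anchored read", {
  ref <- genSequence(profiles[["1B"]], 330)
  refAnno <- list(sequence = ref$sequence, positions = ref$motif$positions)
  for (i in 1:5) {
    r <- genSequence(profiles[["1B"]], 340 + i)
    m1 <- locateMotifs(r$sequence, r$topology)
    m2 <- locateMotifs(r$sequence, r$topology, reference = refAnno)
    expect_equal(m2$method, "reference_alignment")
    expect_identical(m1$residues[c("E57", "X1", "X2", "H1", "R")],
                     m2$residues[c("E57", "X1", "X2", "H1", "R")])
  }
})

test_that("motif frequency tables are exact on small inputs", {
  m1 <- list(found = TRUE, residues = c(E57 = "E", X1 = "W"))
  tab <- motifFrequencyTable(list(m1), "1A")
  expect_true(all(tab$percent == 100))
  # two types with disjoint residues stay independent
  m2 <- list(found = TRUE, residues = c(E57 = "E", X1 = "H"))
  tab2 <- motifFrequencyTable(list(m1, m2), c("1A", "1D"))
  expect_equal(tab2$percent[tab2$type == "1A" & tab2$slot == "X1"], 100)
  expect_equal(tab2$residue[tab2$type == "1D" & tab2$slot == "X1"], "H")
  # rows per slot sum to 100 within rounding
  sums <- tapply(tab2$percent, paste(tab2$type, tab2$slot), sum)
  expect_true(all(abs(sums - 100) <= 1))
  expect_error(motifFrequencyTable(list(), character()), "no located")
})

test_that("alignment trimming drops sparse columns and honors the floor", {
  msa <- c(a = "A-AAAA-AAA", b = "A-AAAA-AAA", c = "A-AAAA-AAA")
  tr <- trimMSA(msa)
  expect_equal(tr$columnMap, c(1, 3:6, 8:10))  # all-gap columns dropped
  gapFree <- c(a = "AAAA", b = "CCCC")
  expect_identical(trimMSA(gapFree)$msa, gapFree)
  expect_error(trimMSA(c(a = "AA-", b = "AAAA")), "ragged")
  # 10 columns, 3 at 4% occupancy (1 of 25 rows): 7 kept, floor (6) not
  # binding
  rows <- c(paste0("AAA", "---", "AAAA"),
            replicate(24, paste0("AAA", "---", "AAAA")))
  rows[1] <- paste0("AAA", "CCC", "AAAA")
  names(rows) <- paste0("r", 1:25)
  tr2 <- trimMSA(rows, gapFractionKeep = 0.05, conservationKeep = 0.60)
  expect_equal(tr2$columnMap, c(1:3, 7:10))
})

test_that("the conservation floor restores the fullest dropped columns", {
  # every non-anchor column is sparse, so the floor must add columns back
  msa <- c(a = "AC----", b = "A-----", c = "A-----", d = "A----G")
  tr <- trimMSA(msa, gapFractionKeep = 0.5, conservationKeep = 0.5)
  expect_equal(length(tr$columnMap), 3)
  expect_true(1 %in% tr$columnMap)
})

test_that("fusion detection separates fusions, singles and noise", {
  hosPan <- vapply(1:3, function(i)
    genSequence(hosProfile(), 400 + i)$sequence, character(1))
  fus <- genFusionSequence(profiles[["1A"]], seed = 410)
  expect_equal(detectFusion(fus$sequence, panels[["1A"]], hosPan), "fusion")
  plain <- genSequence(profiles[["1B"]], 411)
  expect_equal(detectFusion(plain$sequence, panels[["1B"]], hosPan),
               "single")
  withr::with_seed(12, {
    rnd <- paste(sample(rownames(blosum62)[1:20], 150, TRUE), collapse = "")
    expect_equal(detectFusion(rnd, panels[["1B"]], hosPan), "neither")
  })
})

test_that("the classifier recovers all planted types on a clean corpus", {
  # 20 records per type with truth topologies (the acceptance suite runs
  # the full-size version)
  ok <- TRUE
  for (t in names(profiles)) {
    for (i in 1:20) {
      r <- genSequence(profiles[[t]], 500 + i)
      a <- assignType(r$sequence, r$topology, panels)
      if (a$type != t) ok <- FALSE
    }
  }
  expect_true(ok)
})
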