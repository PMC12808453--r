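# Default generative profiles for the seven HAS types, plus stand-in
# profiles for the heme o synthase (HOS) fusion partner and a DUF420-like
# decoy family.
#
# The generator is stylized, not an evolutionary simulator: transmembrane
# (TM) helices are drawn from a strongly hydrophobic pool and loops from a
# strongly polar pool so that hydropathy-based TM detection is guaranteed by
# construction; each type carries a deterministic scaffold sequence so that
# within-type identity is high and between-type identity moderate, which is
# what makes reference-panel classification and cluster merging meaningful.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# residue pools (see the methods vignette for the detectability argument)
TM_POOL <- c(I = 0.5, V = 0.5)
LOOP_POOL_PERI <- c(D = 0.25, E = 0.25, N = 0.25, Q = 0.25)
LOOP_POOL_CYTO <- c(D = 0.175, E = 0.175, N = 0.175, Q = 0.175, K = 0.3)
TAIL_LEN <- 8L

# helix geometry: the two motif-bearing helices are long enough that every
# hydropathy window overlapping a loop excludes the planted polar motif
# block, and vice versa
MOTIF_HELIX_LEN <- 32L   # TM II (E57 block) and TM VI (mirror block)
ANCHOR_HELIX_LEN <- 28L  # TM IV (H2) and TM VIII (H4)
PLAIN_HELIX_LEN <- c(21L, 24L)
MOTIF_BLOCK_OFFSET <- 14L  # block occupies helix offsets 14..18
ANCHOR_OFFSET <- 14L       # H2/H4 single-histidine offset

HAS_TYPES <- c("0", "1A", "1A*", "1B", "1C", "1D", "2")

# frequency vector over AA20: named residues get their stated mass, the
# residual is uniform over the remaining residues
makeFreq <- function(named = NULL) {
  f <- stats::setNames(rep(0, length(AA20)), AA20)
  used <- 0
  if (length(named)) {
    f[names(named)] <- named
    used <- sum(named)
  }
  rest <- setdiff(AA20, names(named))
  f[rest] <- (1 - used) / length(rest)
  f
}

# per-type motif frequency tables; percentages transcribed from the observed
# per-type conservation of the helix-II E57-X1-X2-H1-R block and the
# helix-VI mirror block. Slots without a stated value fall back to uniform.
motifTableFor <- function(label) {
  u <- makeFreq()
  tab <- list(E57 = makeFreq(c(E = 1)), X1 = u, X2 = u,
              H1 = makeFreq(c(H = 1)), R = makeFreq(c(R = 1)),
              mX1 = u, mX2 = u, mX3 = u, H3 = makeFreq(c(H = 1)), mX4 = u)
  switch(label,
    "1A" = {
      tab$X1 <- makeFreq(c(W = 0.85))
      tab <- tab[c("E57", "X1", "X2", "H1", "R")]  # mirror absent (4 TM)
    },
    "1A*" = {
      tab$X1 <- makeFreq(c(W = 0.96))
      tab$X2 <- makeFreq(c(F = 0.87))
      tab$H3 <- makeFreq(c(F = 0.55, H = 0.45))
      tab$mX1 <- makeFreq(c(Q = 0.93))
      tab$mX2 <- makeFreq(c(A = 0.59))
      tab$mX4 <- makeFreq(c(Y = 0.78))
    },
    "1B" = {
      tab$mX1 <- makeFreq(c(Q = 0.6))
      tab$mX4 <- makeFreq(c(R = 0.7))
    },
    "1C" = {
      tab$X1 <- makeFreq(c(F = 0.6, Y = 0.25))
      tab$H1 <- makeFreq(c(H = 0.66, N = 0.34))
      tab$mX1 <- makeFreq(c(R = 0.6))
    },
    "1D" = {
      tab$X1 <- makeFreq(c(H = 0.98))
      tab$mX1 <- makeFreq(c(H = 0.6))
      tab$mX2 <- makeFreq(c(F = 0.63))
      tab$mX4 <- makeFreq(c(R = 0.7))
    },
    "2" = {
      tab$X1 <- makeFreq(c(W = 0.74))
      tab$mX1 <- makeFreq(c(Q = 0.6))
      tab$mX2 <- makeFreq(c(F = 0.91))
      tab$mX4 <- makeFreq(c(R = 0.7))
    },
    "0" = {
      tab$X1 <- makeFreq(c(A = 0.75))
      tab$mX1 <- makeFreq(c(W = 0.55, F = 0.15))
    })
  tab
}

sampleFrom <- function(pool, n) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

# loop side plan for an nTM-helix protein with cytoplasmic N-terminus:
# internal loop after TM k is periplasmic ("out") iff k is odd; ECL ordinals
# count the periplasmic internal loops N->C
loopPlan <- function(nTM) {
  k <- seq_len(nTM - 1L)
  side <- ifelse(k %% 2L == 1L, "out", "in")
  ecl <- rep(NA_integer_, nTM - 1L)
  ecl[side == "out"] <- seq_len(sum(side == "out"))
  data.frame(after_tm = k, side = side, ecl_index = ecl)
}

buildScaffold <- function(label, nTM, cysLoops, loopLengths, seed) {
  withSeed(seed, {
    special <- if (nTM == 4L) {
      c("2" = MOTIF_HELIX_LEN, "4" = ANCHOR_HELIX_LEN)
    } else {
      c("2" = MOTIF_HELIX_LEN, "6" = MOTIF_HELIX_LEN,
        "4" = ANCHOR_HELIX_LEN, "8" = ANCHOR_HELIX_LEN)
    }
    tmLengths <- sample(seq(PLAIN_HELIX_LEN[1], PLAIN_HELIX_LEN[2]),
                        nTM, replace = TRUE)
    tmLengths[as.integer(names(special))] <- special
    tmSeqs <- lapply(tmLengths, function(L) sampleFrom(TM_POOL, L))
    plan <- loopPlan(nTM)
    loopBase <- lapply(seq_len(nTM - 1L), function(k) {
      pool <- if (plan$side[k] == "out") LOOP_POOL_PERI else LOOP_POOL_CYTO
      base <- loopLengths$mean[match(plan$side[k], loopLengths$side)]
      sampleFrom(pool, as.integer(round(base)))
    })
    tails <- list(N = sampleFrom(LOOP_POOL_CYTO, TAIL_LEN),
                  C = sampleFrom(LOOP_POOL_CYTO, TAIL_LEN))
    list(tmLengths = tmLengths, tmSeqs = tmSeqs, loopBase = loopBase,
         tails = tails, plan = plan,
         motifHelix = 2L, mirrorHelix = if (nTM >= 6L) 6L else NA_integer_,
         h2Helix = 4L, h4Helix = if (nTM >= 8L) 8L else NA_integer_)
  })
}

profileFor <- function(label, scaffoldSeed = NULL) {
  nTM <- if (label == "1A") 4L else 8L
  cysLoops <- switch(label,
    "1B" = c("ECL1", "ECL3"),
    "1A" = , "1A*" = , "1C" = "ECL1",
    character())
  periMean <- switch(label, "2" = 18, "0" = 10, 12)
  loopLengths <- data.frame(
    side = c("out", "in"),
    mean = c(periMean, 10),
    sd = c(switch(label, "2" = 3, "0" = 1.5, 2.5), 2),
    min = c(9, 9))
  lengthRange <- if (nTM == 4L) c(120, 200) else c(240, 380)
  if (is.null(scaffoldSeed)) scaffoldSeed <- labelSeed(label)
  methods::new("TypeProfile", typeLabel = label, nTM = nTM,
               cysLoops = cysLoops, motifFreqs = motifTableFor(label),
               loopLengths = loopLengths, lengthRange = lengthRange,
               scaffold = buildScaffold(label, nTM, cysLoops, loopLengths,
                                        scaffoldSeed))
}

#' Default generative profiles for the seven HAS types
#'
#' Returns one [TypeProfile-class] per HAS type (`0`, `1A`, `1A*`, `1B`,
#' `1C`, `1D`, `2`). Type 1A is the short 4-helix form; all others have 8 TM
#' helices. Cysteine-pair placement follows the type definitions (1B: ECL1
#' and ECL3; 1A, 1A*, 1C: ECL1 only; 0, 1D, 2: none), and the motif
#' frequency tables encode the observed per-type conservation at the
#' E57-X1-X2-H1-R block (helix II) and its helix-VI mirror. Each profile
#' carries a deterministic type-specific scaffold sequence (derived from the
#' type label) from which individual records are mutated.
#'
#' @return Named list of [TypeProfile-class] objects.
#' @examples
#' p <- hasTypeProfiles()
#' p[["1B"]]
#' @export
hasTypeProfiles <- function() {
  out <- lapply(HAS_TYPES, profileFor)
  names(out) <- HAS_TYPES
  out
}

#' Stand-in profile for the heme o synthase fusion partner
#'
#' HOS appears in the analysis only as a syntenic neighbor and as the fusion
#' partner of type-1A records; the profile is a stylized 8-segment protein
#' drawn from residue pools disjoint from the HAS pools, so that local
#' alignments against HOS references stop at the HAS/HOS domain boundary.
#'
#' @return A [TypeProfile-class] labelled `"HOS"`.
#' @export
hosProfile <- function() {
  loopLengths <- data.frame(side = c("out", "in"), mean = c(12, 10),
                            sd = c(2.5, 2), min = c(9, 9))
  scaffold <- withSeed(labelSeed("HOS"), {
    tmLengths <- sample(21:24, 8L, replace = TRUE)
    pool <- c(G = 0.25, P = 0.25, S = 0.25, T = 0.25)
    tmSeqs <- lapply(tmLengths, function(L) sampleFrom(pool, L))
    plan <- loopPlan(8L)
    loopBase <- lapply(seq_len(7L), function(k) sampleFrom(pool, 11L))
    list(tmLengths = tmLengths, tmSeqs = tmSeqs, loopBase = loopBase,
         tails = list(N = sampleFrom(pool, TAIL_LEN),
                      C = sampleFrom(pool, TAIL_LEN)),
         plan = plan, motifHelix = NA_integer_, mirrorHelix = NA_integer_,
         h2Helix = NA_integer_, h4Helix = NA_integer_)
  })
  methods::new("TypeProfile", typeLabel = "HOS", nTM = 8L,
               cysLoops = character(), motifFreqs = list(),
               loopLengths = loopLengths, lengthRange = c(200, 320),
               scaffold = scaffold)
}

#' Stand-in profile for a DUF420-like decoy family
#'
#' A synthetic 4-segment family that is deliberately sub-homologous to every
#' HAS profile (disjoint residue pools), used to exercise the identity-based
#' exclusion argument: its mean and median global identity to any HAS type
#' panel falls well below the 25% homology floor.
#'
#' @return A [TypeProfile-class] labelled `"DUF420"`.
#' @export
duf420Profile <- function() {
  loopLengths <- data.frame(side = c("out", "in"), mean = c(10, 10),
                            sd = c(2, 2), min = c(7, 7))
  scaffold <- withSeed(labelSeed("DUF420"), {
    tmLengths <- sample(21:24, 4L, replace = TRUE)
    tmPool <- c(F = 0.4, M = 0.3, L = 0.3)
    loopPool <- c(S = 0.3, T = 0.3, G = 0.2, P = 0.2)
    tmSeqs <- lapply(tmLengths, function(L) sampleFrom(tmPool, L))
    plan <- loopPlan(4L)
    loopBase <- lapply(seq_len(3L), function(k) sampleFrom(loopPool, 10L))
    list(tmLengths = tmLengths, tmSeqs = tmSeqs, loopBase = loopBase,
         tails = list(N = sampleFrom(loopPool, TAIL_LEN),
                      C = sampleFrom(loopPool, TAIL_LEN)),
         plan = plan, motifHelix = NA_integer_, mirrorHelix = NA_integer_,
         h2Helix = NA_integer_, h4Helix = NA_integer_)
  })
  methods::new("TypeProfile", typeLabel = "DUF420", nTM = 4L,
               cysLoops = character(), motifFreqs = list(),
               loopLengths = loopLengths, lengthRange = c(100, 180),
               scaffold = scaffold)
}

#' Default syntenic neighbor model
#'
#' Per-type probabilities that a given neighbor family occurs at least once
#' inside the +/-5-gene window around a HAS gene, plus the probability that
#' a type-1A record is a HAS-HOS fusion (154/273). The HOS and cytochrome c
#' oxidase (COX) probabilities reproduce the reported per-type co-occurrence
#' fractions; the remaining families are set to qualitative levels.
#'
#' @return List with elements `perType` (named list of named probability
#'   vectors) and `fusionProb`.
#' @export
defaultNeighborModel <- function() {
  perType <- list(
    "0"   = c(HOS = 0.164, COX = 0.247, MazG = 0.3, GGT = 0.3),
    "1A"  = c(HOS = 0.02, COX = 0.352, MDH = 0.3, SelW = 0.3),
    "1A*" = c(HOS = 0.02, COX = 0.05, MDH = 0.3, DUF5814 = 0.3),
    "1B"  = c(HOS = 0.915, COX = 0.586, SCO1 = 0.4, DUF1507 = 0.3,
              PYC = 0.3, FtsW = 0.3),
    "1C"  = c(HOS = 0.752, COX = 0.121, DUF1507 = 0.3, PYC = 0.3,
              FtsW = 0.3),
    "1D"  = c(HOS = 0.881, COX = 0.786, SCO1 = 0.4),
    "2"   = c(HOS = 0.05, COX = 0.007, SCO1 = 0.15, RPS9 = 0.4,
              RPL13 = 0.4))
  list(perType = perType, fusionProb = 154 / 273)
}

# filler-gene annotation vocabulary: the modelled neighbor families plus
# decoy labels
FILLER_VOCAB <- c("hypothetical", "ABC_transporter", "MFS_permease",
                  "GNAT_acetyltransferase", "tRNA_ligase", "GTPase",
                  "peptidase", "kinase", "dehydrogenase", "oxidoreductase")
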