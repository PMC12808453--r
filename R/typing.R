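# HAS type classification: cysteine-pair detection, the rule-cascade
# classifier with reference panels, motif extraction and conservation
# tables, MSA trimming, and fusion detection.

#' Detect cysteine pairs in periplasmic loops
#'
#' For each periplasmic (side `"out"`) loop, reports the first (most
#' N-terminal) pair of cysteines whose spacing (residues between the two
#' cysteines) lies within `[minGap, maxGap]`; at most one pair per loop.
#' The default window [2, 12] brackets the two classical exemplar pairs
#' (Cys35/Cys42 and Cys191/Cys197, spacings 6 and 5).
#'
#' @param loops Loop table from [extractLoops()].
#' @param seq Protein sequence.
#' @param minGap,maxGap Spacing bounds (defaults 2 and 12).
#' @return data.frame with columns `ecl`, `i`, `j`, `spacing` (protein
#'   coordinates, 1-based); zero rows when no pair is found.
#' @export
detectCysPairs <- function(loops, seq, minGap = 2, maxGap = 12) {
  res <- splitResidues(toupper(seq))
  out <- data.frame(ecl = integer(), i = integer(), j = integer(),
                    spacing = integer())
  peri <- loops[loops$side == "out" & !is.na(loops$ecl_index), , drop = FALSE]
  for (r in seq_len(nrow(peri))) {
    if (peri$length[r] <= 0) next
    pos <- seq(peri$start[r], peri$end[r])
    cys <- pos[res[pos] == "C"]
    if (length(cys) < 2) next
    found <- NULL
    for (a in seq_len(length(cys) - 1L)) {
      sp <- cys[a + 1L] - cys[a] - 1L
      if (sp >= minGap && sp <= maxGap) {
        found <- c(cys[a], cys[a + 1L])
        break
      }
    }
    if (!is.null(found))
      out <- rbind(out, data.frame(ecl = peri$ecl_index[r], i = found[1],
                                   j = found[2],
                                   spacing = found[2] - found[1] - 1L))
  }
  out
}

#' Build reference panels from the default type profiles
#'
#' Generates `n` exemplar sequences per HAS type from the shipped profiles.
#' These serve as the nearest-reference panels of [assignType()]; real
#' curated references can be supplied in the same shape (named list of
#' named character vectors of sequences).
#'
#' @param n Exemplars per type (default 3).
#' @param seed Seed for the exemplar streams.
#' @param profiles Profiles list.
#' @return Named list (type -> named character vector of sequences).
#' @export
referencePanels <- function(n = 3L, seed = 991L,
                            profiles = hasTypeProfiles()) {
  out <- lapply(names(profiles), function(type) {
    seqs <- vapply(seq_len(n), function(i)
      genSequence(profiles[[type]], seed + labelSeed(type) + i)$sequence,
      character(1))
    names(seqs) <- sprintf("ref_%s_%d", gsub("\\*", "s", type), seq_len(n))
    seqs
  })
  names(out) <- names(profiles)
  out
}

meanPanelIdentity <- function(seq, panel, matrix = NULL) {
  ids <- vapply(panel, function(ref)
    globalIdentity(nwAlign(seq, ref, matrix = matrix)), numeric(1))
  mean(ids)
}

#' Classify a HAS record
#'
#' The rule cascade: (1) records shorter than 100 residues are flagged
#' partial and left unassigned; (2) a 4-helix record (TM count in the
#' tolerance band 3-5) with a cysteine pair in ECL1 is type 1A; (3) for
#' 8-helix records (band 7-9): pairs in both ECL1 and ECL3 give 1B; a pair
#' in ECL1 only gives 1C or 1A*, resolved by the nearest reference panel
#' (mean global identity), with a tie toward 1A* when the record's H3 motif
#' slot holds phenylalanine; no pairs gives 0, 1D or 2 by nearest panel,
#' flagged ambiguous when the best panel beats the runner-up by less than
#' `margin` identity points; (4) other TM counts fall back to the nearest
#' panel and are flagged `tm_atypical`.
#'
#' @param seq Protein sequence.
#' @param topology A [Topology-class] (truth or predicted).
#' @param panels Reference panels, see [referencePanels()].
#' @param minGap,maxGap Cysteine spacing window.
#' @param margin Ambiguity margin in identity points (default 2).
#' @param matrix Substitution matrix for panel identities.
#' @param id Optional record id.
#' @return One-row data.frame: `record_id`, `type`, `tm_count`, `cys_ecl1`,
#'   `cys_ecl3`, `nearest_ref`, `mean_id`, `h3`, `flags`.
#' @export
assignType <- function(seq, topology, panels, minGap = 2, maxGap = 12,
                       margin = 2, matrix = NULL, id = NA_character_) {
  n <- nchar(seq)
  loops <- extractLoops(topology)
  pairs <- detectCysPairs(loops, seq, minGap = minGap, maxGap = maxGap)
  tm <- tmCount(topology)
  inE1 <- 1L %in% pairs$ecl
  inE3 <- 3L %in% pairs$ecl
  flags <- character(0)
  nearest <- NA_character_
  meanId <- NA_real_
  h3 <- NA_character_

  panelNearest <- function(types) {
    if (!length(panels) || !all(types %in% names(panels)))
      stop("reference panels required for types ",
           paste(types, collapse = ", "))
    ids <- vapply(types, function(t)
      meanPanelIdentity(seq, panels[[t]], matrix = matrix), numeric(1))
    ord <- order(-ids, types)
    list(best = types[ord[1]], meanId = ids[ord[1]],
         gap = if (length(ids) > 1) ids[ord[1]] - ids[ord[2]] else Inf)
  }

  if (n < 100) {
    type <- "unassigned"
    flags <- "partial"
  } else if (tm >= 3 && tm <= 5 && inE1) {
    type <- "1A"
  } else if (tm >= 7 && tm <= 9) {
    if (inE1 && inE3) {
      type <- "1B"
    } else if (inE1) {
      mot <- locateMotifs(seq, topology)
      h3 <- if (isTRUE(mot$found)) unname(mot$residues["H3"]) else NA
      pn <- panelNearest(c("1A*", "1C"))
      nearest <- pn$best; meanId <- pn$meanId
      type <- if (pn$gap < margin && identical(h3, "F")) "1A*" else pn$best
      if (pn$gap < margin) flags <- c(flags, "ambiguous")
    } else {
      pn <- panelNearest(c("0", "1D", "2"))
      nearest <- pn$best; meanId <- pn$meanId
      type <- pn$best
      if (pn$gap < margin) flags <- c(flags, "ambiguous")
    }
  } else {
    pn <- panelNearest(names(panels))
    nearest <- pn$best; meanId <- pn$meanId
    type <- pn$best
    flags <- c(flags, "tm_atypical")
  }
  data.frame(record_id = id, type = type, tm_count = tm,
             cys_ecl1 = inE1, cys_ecl3 = inE3, nearest_ref = nearest,
             mean_id = meanId, h3 = if (is.null(h3)) NA_character_ else h3,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Classify a corpus of records
#'
#' Vectorized driver over [assignType()].
#'
#' @param seqs Named character vector of sequences.
#' @param topologies Named list of [Topology-class] (same names).
#' @param panels,... Passed to [assignType()].
#' @return data.frame, one row per record.
#' @export
assignTypes <- function(seqs, topologies, panels, ...) {
  stopifnot(all(names(seqs) %in% names(topologies)))
  do.call(rbind, lapply(names(seqs), function(id)
    assignType(seqs[[id]], topologies[[id]], panels, id = id, ...)))
}

# anchored motif-block start within a helix: the block center is
# shift-invariant under the +/-3-residue boundary wobble of the hydropathy
# predictor, so anchor on the segment center
blockAnchor <- function(tmStart, tmEnd) {
  center <- floor((tmStart + tmEnd) / 2)
  center - 2L  # block = anchor..anchor+4, centered on the helix middle
}

#' Locate the helix-II and helix-VI conserved motifs
#'
#' The helix-II block E57-X1-X2-H1-R is located by the pattern
#' `E..[HN]R` searched around the expected anchor inside TM II (+/- 8
#' residues); among multiple matches the one closest to the anchor wins.
#' The helix-VI mirror block (mX1-mX2-mX3-H3-mX4) carries no invariant
#' residues, so its five residues are read positionally around the TM VI
#' center. When an annotated `reference` is supplied (a record aligned
#' once against which motif columns are known), the record is globally
#' aligned to it and residues are read under the marked columns instead.
#' Absence is reported (`found = FALSE`), never fabricated.
#'
#' @param seq Protein sequence.
#' @param topology [Topology-class] with at least 2 TM segments (6 for the
#'   mirror block).
#' @param reference Optional list `(sequence, positions)` where `positions`
#'   is a named vector of motif positions in the reference's coordinates.
#' @param matrix Substitution matrix for the reference-alignment strategy.
#' @return List: `found`, `method`, `e57_pos`, `residues` (named: E57, X1,
#'   X2, H1, R and, when available, mX1, mX2, mX3, H3, mX4).
#' @export
locateMotifs <- function(seq, topology, reference = NULL, matrix = NULL) {
  res <- splitResidues(toupper(seq))
  seg <- tmSegments(topology)
  notFound <- list(found = FALSE, method = "none", e57_pos = NA_integer_,
                   residues = NULL)
  if (!is.null(reference)) {
    al <- nwAlign(seq, reference$sequence, matrix = matrix)
    ga <- splitResidues(al@alignedA)
    gb <- splitResidues(al@alignedB)
    bpos <- cumsum(gb != "-")
    apos <- cumsum(ga != "-")
    resid <- vapply(reference$positions, function(p) {
      col <- match(p, bpos)
      if (is.na(col) || ga[col] == "-") NA_character_ else ga[col]
    }, character(1))
    e57col <- match(reference$positions[["E57"]], bpos)
    e57 <- if (!is.na(e57col)) apos[e57col] else NA_integer_
    if (anyNA(resid[c("E57", "X1", "X2", "H1", "R")])) return(notFound)
    return(list(found = TRUE, method = "reference_alignment",
                e57_pos = as.integer(e57), residues = resid))
  }
  if (length(seg) < 2) return(notFound)
  s2 <- IRanges::start(seg)[2]; e2 <- IRanges::end(seg)[2]
  anchor <- blockAnchor(s2, e2)
  lo <- max(1L, anchor - 8L)
  hi <- min(length(res) - 4L, anchor + 8L)
  if (hi < lo) return(notFound)
  windowStr <- paste(res[lo:(hi + 4L)], collapse = "")
  m <- gregexpr("(?=E..[HN]R)", windowStr, perl = TRUE)[[1]]
  if (m[1] == -1) return(notFound)
  starts <- lo + as.integer(m) - 1L
  e57 <- starts[which.min(abs(starts - anchor))]
  resid <- stats::setNames(res[e57 + 0:4],
                           c("E57", "X1", "X2", "H1", "R"))
  if (length(seg) >= 6) {
    s6 <- IRanges::start(seg)[6]; e6 <- IRanges::end(seg)[6]
    a6 <- blockAnchor(s6, e6)
    if (a6 >= 1 && a6 + 4 <= length(res))
      resid <- c(resid, stats::setNames(res[a6 + 0:4],
                                        c("mX1", "mX2", "mX3", "H3", "mX4")))
  }
  list(found = TRUE, method = "regex", e57_pos = e57, residues = resid)
}

#' Per-type motif conservation table
#'
#' Percentages of each residue at each motif slot within each assigned
#' type: `100 * count / total`, rounded half-up to integers (the printed
#' precision of motif tables). Types with fewer than `minN` located motifs
#' are marked low-support.
#'
#' @param motifs List of [locateMotifs()] results.
#' @param types Character vector of type labels, parallel to `motifs`.
#' @param minN Low-support threshold (default 10).
#' @return data.frame: `type`, `slot`, `residue`, `n`, `total`, `percent`,
#'   `low_support`.
#' @export
motifFrequencyTable <- function(motifs, types, minN = 10L) {
  stopifnot(length(motifs) == length(types))
  keep <- vapply(motifs, function(m) isTRUE(m$found), logical(1))
  if (!any(keep)) stop("no located motifs to tabulate")
  motifs <- motifs[keep]
  types <- types[keep]
  rows <- list()
  for (type in unique(types)) {
    sel <- motifs[types == type]
    slots <- unique(unlist(lapply(sel, function(m) names(m$residues))))
    for (slot in slots) {
      obs <- vapply(sel, function(m)
        if (slot %in% names(m$residues)) m$residues[[slot]]
        else NA_character_, character(1))
      obs <- obs[!is.na(obs)]
      if (!length(obs)) next
      tab <- table(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, slot = slot, residue = names(tab),
        n = as.integer(tab), total = length(obs),
        percent = roundHalfUp(100 * as.integer(tab) / length(obs)),
        low_support = length(obs) < minN, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trim alignment columns by occupancy with a conservation floor
#'
#' Columns whose non-gap fraction is below `gapFractionKeep` are dropped;
#' if that leaves fewer than `conservationKeep` of the original columns,
#' dropped columns are restored in order of decreasing occupancy until the
#' floor is met. The returned column map gives the original index of every
#' retained column.
#'
#' @param msa Named character vector of equal-length aligned rows (`-` =
#'   gap).
#' @param gapFractionKeep Minimum non-gap fraction (default 0.05).
#' @param conservationKeep Minimum retained fraction of columns (default
#'   0.60).
#' @return List `msa` (trimmed rows), `columnMap` (integer vector of
#'   original column indices).
#' @export
trimMSA <- function(msa, gapFractionKeep = 0.05, conservationKeep = 0.60) {
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  occ <- colMeans(mat != "-")
  keep <- occ >= gapFractionKeep
  floorCols <- ceiling(conservationKeep * ncol(mat))
  if (sum(keep) < floorCols) {
    dropped <- which(!keep)
    addBack <- dropped[order(-occ[dropped], dropped)]
    need <- floorCols - sum(keep)
    keep[addBack[seq_len(need)]] <- TRUE
  }
  cols <- which(keep)
  trimmed <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
  names(trimmed) <- names(msa)
  list(msa = trimmed, columnMap = cols)
}

#' Detect HAS-HOS fusion records
#'
#' A record is a fusion when local alignments against the HAS panel and the
#' HOS panel each cover at least `minSpan` residues of the record with
#' footprints overlapping by fewer than `maxOverlap` residues; it is
#' `"single"` when only one panel reaches the span (or both do on the same
#' stretch), and `"neither"` otherwise. Fusions are excluded from
#' MSA-bound sequence sets but retained in all counts.
#'
#' @param seq Record sequence.
#' @param hasPanel,hosPanel Character vectors of reference sequences.
#' @param minSpan Minimum footprint length (default 100).
#' @param maxOverlap Maximum footprint overlap for a fusion call (default
#'   30).
#' @param matrix Substitution matrix.
#' @return `"fusion"`, `"single"` or `"neither"`.
#' @export
detectFusion <- function(seq, hasPanel, hosPanel, minSpan = 100,
                         maxOverlap = 30, matrix = NULL) {
  footprint <- function(panel) {
    best <- NULL
    for (ref in panel) {
      al <- swAlign(seq, ref, matrix = matrix)
      core <- gsub("-", "", al@alignedA, fixed = TRUE)
      if (!nzchar(core)) next
      st <- regexpr(core, seq, fixed = TRUE)
      if (st < 0) next
      cand <- c(start = as.integer(st),
                end = as.integer(st) + nchar(core) - 1L,
                score = al@score)
      if (is.null(best) || cand["score"] > best["score"]) best <- cand
    }
    best
  }
  fa <- footprint(hasPanel)
  fb <- footprint(hosPanel)
  spanA <- if (is.null(fa)) 0 else fa["end"] - fa["start"] + 1
  spanB <- if (is.null(fb)) 0 else fb["end"] - fb["start"] + 1
  okA <- spanA >= minSpan
  okB <- spanB >= minSpan
  if (okA && okB) {
    ov <- min(fa["end"], fb["end"]) - max(fa["start"], fb["start"]) + 1
    if (ov < maxOverlap) return("fusion")
    return("single")
  }
  if (okA || okB) return("single")
  "neither"
}

#' Recover a motif-slot residue percentage on a seeded synthetic corpus
#'
#' Generates `n` records of one type from its default profile, locates the
#' motifs on each (truth topologies, anchored read), tabulates them with
#' [motifFrequencyTable()], and returns the percentage of `residue` at
#' `slot`. This is the package's parameter-recovery experiment: the
#' profile's configured frequency should be recovered within binomial
#' noise (about +/-2 points at n = 2000).
#'
#' @param type HAS type label.
#' @param slot Motif slot (e.g. `"X1"`, `"H1"`, `"H3"`).
#' @param residue One-letter residue code.
#' @param n Corpus size (default 2000).
#' @param seed Base seed for the corpus stream (default 42).
#' @param profiles Profiles list.
#' @return List: `percent`, `n_located`, `n`.
#' @export
motifRecoveryPercent <- function(type, slot, residue, n = 2000, seed = 42,
                                 profiles = hasTypeProfiles()) {
  recSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  motifs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- genSequence(profiles[[type]], recSeeds[i])
    motifs[[i]] <- locateMotifs(r$sequence, r$topology)
  }
  tab <- motifFrequencyTable(motifs, rep(type, n))
  row <- tab[tab$slot == slot & tab$residue == residue, , drop = FALSE]
  list(percent = if (nrow(row)) row$percent else 0,
       n_located = sum(vapply(motifs, function(m) isTRUE(m$found),
                              logical(1))),
       n = n)
}
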