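# Kyte-Doolittle hydropathy values
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Construct a Topology
#'
#' @param segments Two-column matrix / data.frame of 1-based inclusive
#'   `(start, end)` TM segments, or an [IRanges::IRanges].
#' @param nTermSide `"in"` or `"out"`.
#' @param seqLength Protein length.
#' @return A validated [Topology-class].
#' @export
Topology <- function(segments, nTermSide, seqLength) {
  if (!methods::is(segments, "IRanges")) {
    segments <- as.matrix(segments)
    segments <- IRanges::IRanges(start = as.integer(segments[, 1]),
                                 end = as.integer(segments[, 2]))
  }
  methods::new("Topology", segments = segments,
               nTermSide = nTermSide, seqLength = as.integer(seqLength))
}

#' Parse one topology-table record
#'
#' The topology TSV dialect stores, per protein, the N-terminal side and a
#' comma-separated list of 1-based inclusive `start-end` TM segments, e.g.
#' `"out;10-30,45-65"` split into two fields.
#'
#' @param nTermSide `"in"` or `"out"`.
#' @param segmentString Comma-separated `start-end` pairs (empty string for
#'   a TM-free protein).
#' @param seqLength Protein length.
#' @return A [Topology-class]; malformed, overlapping or out-of-bounds
#'   segments are errors.
#' @export
parseTopology <- function(nTermSide, segmentString, seqLength) {
  segmentString <- trimws(segmentString)
  if (!nzchar(segmentString)) {
    return(Topology(matrix(numeric(0), ncol = 2), nTermSide, seqLength))
  }
  parts <- strsplit(segmentString, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)-(\\d+)\\s*$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed segment(s): ", paste(parts[bad], collapse = ", "))
  seg <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2)))
  if (any(seg[, 2] < seg[, 1])) stop("segment end before start")
  Topology(seg, nTermSide, seqLength)
}

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' A light-weight stand-in for an HMM-based TM predictor: the mean
#' Kyte-Doolittle hydropathy in a sliding window is assigned to the window's
#' central residue; maximal runs of positions above the threshold are merged
#' across short gaps, extended by `extend` residues per side (central
#' scoring systematically understates a helix's extent by a few residues at
#' each end), and kept when at least `minLen` long. The N-terminal side is
#' set by the positive-inside rule: the loop side-class with the larger
#' lysine+arginine content (counting the first 15 residues toward the
#' N-terminal side) is called cytoplasmic (`"in"`).
#'
#' @param seq Protein sequence (single string).
#' @param window Sliding-window width (odd; default 19).
#' @param threshold Window-mean hydropathy threshold (default 1.6).
#' @param minLen Minimum run length kept as a TM segment (default 15).
#' @param mergeGap Runs separated by at most this many positions are merged
#'   (default 3).
#' @param extend Per-side run extension in residues (default 2; never more
#'   than `mergeGap / 2` would keep extended segments from overlapping).
#' @param nTermSide Optional override (`"in"`/`"out"`) skipping the
#'   positive-inside heuristic.
#' @return A [Topology-class].
#' @export
predictTM <- function(seq, window = 19, threshold = 1.6, minLen = 15,
                      mergeGap = 3, extend = 2, nTermSide = NULL) {
  res <- splitResidues(toupper(seq))
  n <- length(res)
  if (n < window) stop("sequence shorter than the hydropathy window")
  kd <- KD_SCALE[res]
  kd[is.na(kd)] <- 0
  half <- (window - 1L) / 2L
  means <- as.numeric(stats::filter(kd, rep(1 / window, window),
                                    sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  seg <- runsFromPositions(centers, mergeGap)
  if (nrow(seg)) {
    seg[, 1] <- pmax(1L, seg[, 1] - as.integer(extend))
    seg[, 2] <- pmin(n, seg[, 2] + as.integer(extend))
    seg <- seg[seg[, 2] - seg[, 1] + 1 >= minLen, , drop = FALSE]
  }
  side <- if (!is.null(nTermSide)) nTermSide
          else positiveInsideSide(res, seg)
  Topology(seg, side, n)
}

# maximal runs from sorted integer positions, merging gaps <= mergeGap
runsFromPositions <- function(pos, mergeGap) {
  if (length(pos) == 0L) return(matrix(integer(0), ncol = 2))
  brk <- which(diff(pos) > mergeGap + 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  cbind(starts, ends)
}

# positive-inside rule: compare K+R content of the two alternating loop side
# classes; the class containing the N-terminal tail also counts the first 15
# residues. Returns the side ("in"/"out") of the N-terminus.
positiveInsideSide <- function(res, seg) {
  if (nrow(seg) == 0L) return("in")
  isKR <- res %in% c("K", "R")
  nTailClass <- sum(isKR[seq_len(min(15L, seg[1, 1] - 1L))])
  otherClass <- 0
  bounds <- rbind(seg, c(length(res) + 1L, NA))
  if (nrow(seg) >= 1L) {
    for (k in seq_len(nrow(seg))) {
      from <- seg[k, 2] + 1L
      to <- if (k < nrow(seg)) seg[k + 1L, 1] - 1L else length(res)
      if (from > to) next
      cnt <- sum(isKR[from:to])
      # loop after TM k is on the N-terminal side-class iff k is even
      if (k %% 2L == 0L) nTailClass <- nTailClass + cnt
      else otherClass <- otherClass + cnt
    }
  }
  if (nTailClass >= otherClass) "in" else "out"
}

#' Extract sided loops from a topology
#'
#' Loops are the inter-TM stretches plus both termini; sides alternate
#' strictly starting from the N-terminal side. Extracellular (periplasmic)
#' ordinals `ECL1, ECL2, ...` are assigned to internal `out` loops in
#' N-to-C order, matching the convention that for an 8-TM protein with a
#' cytoplasmic N-terminus the loop after TM I is ECL1 (L1) and the loop
#' after TM V is ECL3 (L5).
#'
#' @param topology A [Topology-class].
#' @return data.frame with columns `ordinal`, `side`, `ecl_index` (NA for
#'   cytoplasmic/terminal loops), `start`, `end`, `length`, `terminal`.
#'   Zero-length loops are retained as rows with `length = 0`.
#' @export
extractLoops <- function(topology) {
  seg <- topology@segments
  n <- topology@seqLength
  k <- length(seg)
  if (k == 0L) {
    return(data.frame(ordinal = 1L, side = topology@nTermSide,
                      ecl_index = NA_integer_, start = 1L, end = n,
                      length = n, terminal = TRUE))
  }
  starts <- c(1L, IRanges::end(seg) + 1L)
  ends <- c(IRanges::start(seg) - 1L, n)
  sides <- rep(c(topology@nTermSide,
                 setdiff(c("in", "out"), topology@nTermSide)),
               length.out = k + 1L)
  terminal <- c(TRUE, rep(FALSE, max(0L, k - 1L)), TRUE)
  out <- data.frame(ordinal = seq_len(k + 1L), side = sides,
                    ecl_index = NA_integer_, start = starts, end = ends,
                    length = pmax(0L, ends - starts + 1L),
                    terminal = terminal, stringsAsFactors = FALSE)
  internalOut <- which(out$side == "out" & !out$terminal)
  out$ecl_index[internalOut] <- seq_along(internalOut)
  out
}

#' First and third extracellular loop lengths
#'
#' @param loops Loop table from [extractLoops()].
#' @return Named list `ecl1`, `ecl3` (residue counts; `NA` when the topology
#'   has no such loop, e.g. ECL3 for a 4-TM protein).
#' @export
eclLengths <- function(loops) {
  pick <- function(i) {
    r <- loops$length[!is.na(loops$ecl_index) & loops$ecl_index == i]
    if (length(r)) r[1] else NA_integer_
  }
  list(ecl1 = pick(1L), ecl3 = pick(3L))
}

#' Read / write topology tables
#'
#' Tab-separated with columns `gene_id`, `n_term_side`, `segments`
#' (comma-separated 1-based inclusive `start-end`), `seq_length`.
#'
#' @param path File path.
#' @return For the reader, a named list of [Topology-class] objects.
#' @export
readTopologyTSV <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         n_term_side = "character",
                                         segments = "character"))
  out <- lapply(seq_len(nrow(df)), function(i)
    parseTopology(df$n_term_side[i], df$segments[i], df$seq_length[i]))
  names(out) <- df$gene_id
  out
}

#' @rdname readTopologyTSV
#' @param topologies Named list of [Topology-class] objects.
#' @export
writeTopologyTSV <- function(topologies, path) {
  rows <- vapply(names(topologies), function(id) {
    t <- topologies[[id]]
    segs <- paste(sprintf("%d-%d", IRanges::start(t@segments),
                          IRanges::end(t@segments)), collapse = ",")
    paste(id, t@nTermSide, segs, t@seqLength, sep = "\t")
  }, character(1))
  writeLines(c("gene_id\tn_term_side\tsegments\tseq_length", rows), path)
  invisible(path)
}

#' Parse TMHMM 2.0 long-format output
#'
#' Reads the per-protein prediction blocks of TMHMM's long output (lines
#' `<id> TMHMM2.0 inside/outside/TMhelix <from> <to>`) into the package's
#' topology representation.
#'
#' @param path Path to a TMHMM long-format file.
#' @return Named list of [Topology-class] objects.
#' @export
parseTMHMM <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\\s+")
  ok <- vapply(f, length, integer(1)) >= 5L
  f <- f[ok]
  ids <- vapply(f, `[`, character(1), 1)
  out <- lapply(split(f, factor(ids, levels = unique(ids))), function(rows) {
    lab <- vapply(rows, `[`, character(1), 3)
    from <- as.integer(vapply(rows, `[`, character(1), 4))
    to <- as.integer(vapply(rows, `[`, character(1), 5))
    tm <- lab == "TMhelix"
    side <- if (lab[1] == "inside") "in" else "out"
    Topology(cbind(from[tm], to[tm]), side, max(to))
  })
  out
}
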