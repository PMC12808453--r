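#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width
NULL

#' Transmembrane topology of a membrane protein
#'
#' Ordered transmembrane (TM) segments plus the sidedness of the N-terminus.
#' Coordinates are 1-based inclusive throughout (TMHMM convention). Loop
#' sides strictly alternate along the chain, so the N-terminal side fixes the
#' side of every loop.
#'
#' @slot segments An [IRanges::IRanges] of TM segments, sorted, non-overlapping.
#' @slot nTermSide `"in"` (cytoplasmic) or `"out"` (periplasmic).
#' @slot seqLength Length of the underlying protein sequence.
#'
#' @seealso [predictTM()], [extractLoops()], [parseTopology()]
#' @export
setClass("Topology",
  representation(segments = "IRanges", nTermSide = "character",
                 seqLength = "integer"))

setValidity("Topology", function(object) {
  seg <- object@segments
  msgs <- character()
  if (!object@nTermSide %in% c("in", "out"))
    msgs <- c(msgs, "nTermSide must be 'in' or 'out'")
  if (length(seg) > 0) {
    if (any(IRanges::width(seg) < 15))
      msgs <- c(msgs, "each TM segment must be >= 15 residues")
    if (is.unsorted(IRanges::start(seg)))
      msgs <- c(msgs, "TM segments must be sorted by start")
    if (length(seg) > 1 &&
        any(IRanges::start(seg)[-1] <= IRanges::end(seg)[-length(seg)]))
      msgs <- c(msgs, "TM segments must not overlap")
    if (min(IRanges::start(seg)) < 1 ||
        max(IRanges::end(seg)) > object@seqLength)
      msgs <- c(msgs, "TM segments out of sequence bounds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Generative profile of a HAS type
#'
#' Everything the synthetic-data generator needs to emit sequences of one
#' heme a synthase (HAS) type: the TM-helix count (4 for type 1A, 8
#' otherwise), which periplasmic loops carry a conserved cysteine pair,
#' per-position residue frequency distributions at the ten motif slots
#' (E57, X1, X2, H1, R in helix II; mX1, mX2, mX3, H3, mX4 in helix VI),
#' loop-length distributions, and a deterministic type-specific scaffold
#' sequence that individual records are mutated from.
#'
#' @slot typeLabel One of `"0"`, `"1A"`, `"1A*"`, `"1B"`, `"1C"`, `"1D"`, `"2"`
#'   (or another label for decoy profiles).
#' @slot nTM Number of TM helices (4 or 8).
#' @slot cysLoops Character vector, subset of `c("ECL1", "ECL3")`.
#' @slot motifFreqs Named list (slot -> named numeric frequency vector
#'   summing to 1).
#' @slot loopLengths data.frame with columns `loop`, `mean`, `sd`, `min`.
#' @slot lengthRange Numeric length-2 amino-acid length bounds.
#' @slot scaffold List with the realized template architecture (see
#'   [hasTypeProfiles()]).
#'
#' @export
setClass("TypeProfile",
  representation(typeLabel = "character", nTM = "integer",
                 cysLoops = "character", motifFreqs = "list",
                 loopLengths = "data.frame", lengthRange = "numeric",
                 scaffold = "list"))

setValidity("TypeProfile", function(object) {
  msgs <- character()
  for (slot in names(object@motifFreqs)) {
    f <- object@motifFreqs[[slot]]
    if (abs(sum(f) - 1) > 1e-9)
      msgs <- c(msgs, sprintf("motif frequencies at %s do not sum to 1", slot))
    if (any(f < 0)) msgs <- c(msgs, sprintf("negative frequency at %s", slot))
  }
  expected <- switch(object@typeLabel,
    "1B" = c("ECL1", "ECL3"),
    "1A" = , "1A*" = , "1C" = "ECL1",
    "0" = , "1D" = , "2" = character(),
    NULL)
  if (!is.null(expected) && !setequal(object@cysLoops, expected))
    msgs <- c(msgs, sprintf("cysLoops for type %s must be {%s}",
                            object@typeLabel, paste(expected, collapse = ",")))
  if (object@typeLabel %in% c("0", "1A", "1A*", "1B", "1C", "1D", "2")) {
    if ((object@nTM == 4L) != (object@typeLabel == "1A"))
      msgs <- c(msgs, "nTM must be 4 iff typeLabel is 1A")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a pairwise sequence alignment
#'
#' @slot alignedA,alignedB Gapped sequences (equal length; `-` = gap).
#' @slot score Alignment score in substitution-matrix units.
#' @slot identityPct Percent identity; for global alignments the denominator
#'   is the full alignment length including gap columns (EMBOSS needle
#'   convention).
#' @slot mode `"global"` or `"local"`.
#'
#' @seealso [nwAlign()], [swAlign()], [globalIdentity()]
#' @export
setClass("AlignmentResult",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", identityPct = "numeric",
                 mode = "character"))

setValidity("AlignmentResult", function(object) {
  msgs <- character()
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msgs <- c(msgs, "gapped sequences must have equal length")
  if (object@identityPct < 0 || object@identityPct > 100)
    msgs <- c(msgs, "identityPct must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' A partition of sequence identifiers into clusters
#'
#' @slot members List of character vectors; the clusters partition the id
#'   universe (no duplicates across clusters).
#' @slot representatives Character vector, one id per cluster, each a member
#'   of its cluster.
#'
#' @seealso [greedyReduce()], [mclCluster()], [mergeClusters()]
#' @export
setClass("ClusterSet",
  representation(members = "list", representatives = "character"))

setValidity("ClusterSet", function(object) {
  msgs <- character()
  ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(ids))
    msgs <- c(msgs, "clusters must not share members")
  if (length(object@representatives) != length(object@members))
    msgs <- c(msgs, "one representative per cluster required")
  ok <- mapply(function(rep, mem) rep %in% mem,
               object@representatives, object@members)
  if (length(ok) && !all(ok))
    msgs <- c(msgs, "each representative must belong to its cluster")
  if (length(msgs)) msgs else TRUE
})
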