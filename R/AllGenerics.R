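#' @rdname Topology-class
#' @param object,x A `Topology`, `TypeProfile`, `AlignmentResult` or
#'   `ClusterSet` object, as documented per method.
#' @export
setGeneric("tmSegments", function(x) standardGeneric("tmSegments"))

#' @rdname Topology-class
#' @export
setGeneric("tmCount", function(x) standardGeneric("tmCount"))

#' @rdname Topology-class
#' @export
setGeneric("nTermSide", function(x) standardGeneric("nTermSide"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname ClusterSet-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @export
#' @rdname Topology-class
setMethod("tmSegments", "Topology", function(x) x@segments)

#' @export
#' @rdname Topology-class
setMethod("tmCount", "Topology", function(x) length(x@segments))

#' @export
#' @rdname Topology-class
setMethod("nTermSide", "Topology", function(x) x@nTermSide)

#' @export
#' @rdname ClusterSet-class
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @export
#' @rdname ClusterSet-class
setMethod("representatives", "ClusterSet", function(x) x@representatives)

#' @export
#' @rdname AlignmentResult-class
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @export
#' @rdname AlignmentResult-class
setMethod("alignedSeqs", "AlignmentResult",
          function(x) c(a = x@alignedA, b = x@alignedB))

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d TM segment(s), N-terminus '%s', length %d\n",
              length(object@segments), object@nTermSide, object@seqLength))
  if (length(object@segments))
    cat("  ", paste(sprintf("%d-%d", IRanges::start(object@segments),
                            IRanges::end(object@segments)), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "TypeProfile", function(object) {
  cat(sprintf("TypeProfile '%s': %d TM, cys pairs in {%s}\n",
              object@typeLabel, object@nTM,
              paste(object@cysLoops, collapse = ",")))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("%s alignment: score %.1f, identity %.1f%%, %d columns\n",
              object@mode, object@score, object@identityPct,
              nchar(object@alignedA)))
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- lengths(object@members)
  cat(sprintf("ClusterSet: %d cluster(s), %d member(s)\n",
              length(sizes), sum(sizes)))
})

#' Number of clusters
#' @param x A `ClusterSet`.
#' @export
#' @rdname ClusterSet-class
setMethod("length", "ClusterSet", function(x) length(x@members))
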