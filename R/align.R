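#' @useDynLib HAStyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Map a sequence to 1-based indices into the substitution-matrix alphabet.
# Case-insensitive only as a fallback (3Di-style alphabets are lower case);
# residues still unmapped go to the neutral symbol 'X' when the matrix has
# one, otherwise they are an error.
encodeSeq <- function(seq, alphabet, what = "sequence") {
  res <- splitResidues(seq)
  if (length(res) == 0L) stop("empty ", what)
  idx <- match(res, alphabet)
  if (anyNA(idx)) {
    na <- is.na(idx)
    idx[na] <- match(toupper(res[na]), alphabet)
  }
  if (anyNA(idx)) {
    if ("X" %in% alphabet) {
      idx[is.na(idx)] <- match("X", alphabet)
    } else {
      bad <- unique(res[is.na(idx)])
      stop("symbols outside the matrix alphabet in ", what, ": ",
           paste(bad, collapse = ", "))
    }
  }
  idx
}

defaultMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

alignCore <- function(a, b, matrix, gapOpen, gapExt, local) {
  if (is.null(matrix)) matrix <- defaultMatrix()
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  alpha <- rownames(matrix)
  ai <- encodeSeq(a, alpha, "sequence a")
  bi <- encodeSeq(b, alpha, "sequence b")
  r <- .alignAffineCpp(ai, bi, matrix, gapOpen, gapExt, local)
  ra <- splitResidues(a)
  rb <- splitResidues(b)
  # reconstruct gapped strings from the consume masks; local alignments use
  # only the residues inside the optimal footprint
  fill <- function(consume, residues, offset) {
    out <- rep("-", length(consume))
    hit <- consume == 1L
    out[hit] <- residues[offset + cumsum(consume)[hit]]
    out
  }
  ga <- fill(r$consumeA, ra, r$startA)
  gb <- fill(r$consumeB, rb, r$startB)
  cols <- length(ga)
  ident <- if (cols > 0) {
    100 * sum(r$consumeA == 1L & r$consumeB == 1L & ga == gb) / cols
  } else 0
  methods::new("AlignmentResult",
               alignedA = paste(ga, collapse = ""),
               alignedB = paste(gb, collapse = ""),
               score = r$score, identityPct = ident,
               mode = if (local) "local" else "global")
}

#' Global (Needleman-Wunsch) pairwise alignment with affine gaps
#'
#' True global alignment: end gaps are penalized. Gap costs follow the EMBOSS
#' needle convention (`gapOpen` for the first gapped residue, `gapExt` for
#' each further one); the defaults are the needle defaults for proteins.
#' Ties are broken deterministically (diagonal, then up, then left). Any
#' square substitution matrix over any alphabet is accepted, so e.g. 3Di
#' structural-state strings can be aligned with their dedicated matrix.
#'
#' @param a,b Protein (or other-alphabet) sequences as single strings.
#' @param matrix Substitution matrix with identical row/column names;
#'   `NULL` (default) uses BLOSUM62.
#' @param gapOpen,gapExt Gap opening / extension penalties (positive).
#' @return An [AlignmentResult-class] object.
#' @examples
#' r <- nwAlign("HEAGAWGHEE", "PAWHEAE")
#' alignmentScore(r)
#' @export
nwAlign <- function(a, b, matrix = NULL, gapOpen = 10, gapExt = 0.5) {
  alignCore(a, b, matrix, gapOpen, gapExt, local = FALSE)
}

#' Local (Smith-Waterman) pairwise alignment with affine gaps
#'
#' Same scoring conventions as [nwAlign()], but the optimal positive-scoring
#' local footprint is reported.
#'
#' @inheritParams nwAlign
#' @return An [AlignmentResult-class] object (mode `"local"`).
#' @export
swAlign <- function(a, b, matrix = NULL, gapOpen = 10, gapExt = 0.5) {
  alignCore(a, b, matrix, gapOpen, gapExt, local = TRUE)
}

#' Percent identity of a global alignment
#'
#' Identity is counted over all alignment columns, gaps included in the
#' denominator (EMBOSS needle convention). With
#' `denominator = "shorter"`, the length of the shorter input is used
#' instead.
#'
#' @param r An [AlignmentResult-class].
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Percent identity in `[0, 100]`.
#' @export
globalIdentity <- function(r, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ga <- splitResidues(r@alignedA)
  gb <- splitResidues(r@alignedB)
  ident <- sum(ga != "-" & gb != "-" & ga == gb)
  den <- switch(denominator,
    alignment = length(ga),
    shorter = min(sum(ga != "-"), sum(gb != "-")))
  100 * ident / den
}

#' Identity statistics between (or within) sequence groups
#'
#' Computes mean, median, minimum and maximum percent identity over all
#' cross-group pairs (or all within-group pairs when `groupB` is `NULL`),
#' using global (Needleman-Wunsch) or local (Smith-Waterman) alignments.
#'
#' @param groupA,groupB Named character vectors of sequences; `groupB = NULL`
#'   requests within-group statistics (requires `length(groupA) >= 2`).
#' @param mode `"global"` or `"local"`.
#' @param matrix,gapOpen,gapExt Passed to the aligner.
#' @return data.frame with one row: `mean`, `median`, `min`, `max`,
#'   `n_pairs`, `mode`.
#' @export
groupIdentityStats <- function(groupA, groupB = NULL,
                               mode = c("global", "local"),
                               matrix = NULL, gapOpen = 10, gapExt = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(groupA) >= 1)
  alignFun <- if (mode == "global") nwAlign else swAlign
  idFun <- function(x, y) {
    r <- alignFun(x, y, matrix = matrix, gapOpen = gapOpen, gapExt = gapExt)
    if (mode == "global") globalIdentity(r) else r@identityPct
  }
  if (is.null(groupB)) {
    if (length(groupA) < 2)
      stop("within-group statistics require at least 2 sequences")
    pairs <- utils::combn(length(groupA), 2)
    ids <- apply(pairs, 2, function(p) idFun(groupA[p[1]], groupA[p[2]]))
  } else {
    stopifnot(length(groupB) >= 1)
    ids <- as.vector(outer(seq_along(groupA), seq_along(groupB),
      Vectorize(function(i, j) idFun(groupA[i], groupB[j]))))
  }
  data.frame(mean = mean(ids), median = stats::median(ids),
             min = min(ids), max = max(ids), n_pairs = length(ids),
             mode = mode, stringsAsFactors = FALSE)
}

#' Homology gate on group identity statistics
#'
#' A candidate group is retained as homologous only when both the mean and
#' the median identity exceed the threshold (strictly). 25% is the canonical
#' comparative-genomics homology floor; below it, alignment-based phylogeny
#' is unreliable.
#'
#' @param stats One-row data.frame from [groupIdentityStats()].
#' @param threshold Percent identity threshold (default 25).
#' @return `"include"` or `"exclude"`.
#' @export
homologyGate <- function(stats, threshold = 25) {
  stopifnot(all(c("mean", "median") %in% names(stats)))
  if (stats$mean > threshold && stats$median > threshold) "include"
  else "exclude"
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated square matrix format used by BLAST and
#' EMBOSS (`#` comment lines, one header row of symbols, one labelled row per
#' symbol).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with symbol row/column names.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a substitution matrix: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  rownames(vals) <- labels
  colnames(vals) <- header
  if (!identical(sort(labels), sort(header)))
    stop("matrix rows and columns disagree in ", path)
  vals[header, header, drop = FALSE]
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param r An [AlignmentResult-class].
#' @param path Output file.
#' @param names Sequence names (length 2).
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(r, path, names = c("a", "b")) {
  writeLines(c(paste0(">", names[1]), r@alignedA,
               paste0(">", names[2]), r@alignedB), path)
  invisible(path)
}
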