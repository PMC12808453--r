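# Filtering cascade and clustering: hit-table gates, greedy redundancy
# reduction, Markov clustering, and identity-based cluster merging.

#' Read a 12-column blast-tab hit table
#'
#' The standard tabular dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to the TSV (no header).
#' @return data.frame with typed columns; malformed rows are errors naming
#'   the row number.
#' @export
readBlastTab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1))
  if (any(nf != 12L))
    stop("malformed hit-table row(s): ",
         paste(which(nf != 12L), collapse = ", "))
  df <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(df) <- c("query_id", "subject_id", "local_identity_pct",
                 "alignment_length", "mismatch", "gapopen", "qstart",
                 "qend", "sstart", "send", "evalue", "bitscore")
  num <- c("local_identity_pct", "alignment_length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop("non-numeric ", cn, " in row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    df[[cn]] <- v
  }
  df
}

#' Filter local-alignment hits on identity and E-value
#'
#' Keeps hits with identity strictly above `minIdentity` percent and E-value
#' at or below `maxEvalue` (strict `>`, inclusive `<=`): a hit at exactly
#' 25% identity is removed, a hit at exactly the E-value ceiling is kept.
#' Idempotent.
#'
#' @param hits data.frame with columns `local_identity_pct` and `evalue`
#'   (as from [readBlastTab()]).
#' @param minIdentity Identity gate in percent (default 25).
#' @param maxEvalue E-value ceiling (default 1e-10).
#' @return The retained rows.
#' @export
filterHits <- function(hits, minIdentity = 25, maxEvalue = 1e-10) {
  stopifnot(all(c("local_identity_pct", "evalue") %in% names(hits)))
  hits[hits$local_identity_pct > minIdentity & hits$evalue <= maxEvalue, ,
       drop = FALSE]
}

#' Greedy redundancy reduction at an identity cut-off
#'
#' Incremental greedy clustering in the CD-HIT style, but with exact global
#' identities: sequences are visited by decreasing length (ties by id,
#' ascending); each sequence joins the first existing representative with
#' global identity at or above the threshold, otherwise it founds a new
#' cluster. Every member is therefore within the threshold of its
#' representative.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity fraction (default 0.90).
#' @param matrix,gapOpen,gapExt Passed to [nwAlign()].
#' @return A [ClusterSet-class].
#' @export
greedyReduce <- function(seqs, threshold = 0.90, matrix = NULL,
                         gapOpen = 10, gapExt = 0.5) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      al <- nwAlign(seqs[[reps[r]]], seqs[[i]], matrix = matrix,
                    gapOpen = gapOpen, gapExt = gapExt)
      if (globalIdentity(al) >= threshold * 100) {
        members[[r]] <- c(members[[r]], names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  methods::new("ClusterSet", members = members, representatives = reps)
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Classic MCL on a non-negative symmetric similarity matrix: self-loops are
#' added, columns normalized to a stochastic matrix, then expansion (matrix
#' squaring) alternates with inflation (entrywise power and column
#' renormalization) and pruning of small entries until the matrix change
#' falls below `tol`. Clusters are the connected components of the converged
#' matrix's support.
#'
#' @param similarity Square symmetric numeric matrix (dimnames used as ids),
#'   non-negative.
#' @param inflation Inflation exponent (default 2).
#' @param prune Entries below this are zeroed each iteration (default 1e-5).
#' @param maxIter Iteration cap (default 100).
#' @param tol Convergence threshold on the max absolute change (default
#'   1e-6).
#' @param addSelfLoops Add unit self-loops before normalization (default
#'   TRUE).
#' @param details When `TRUE`, return a list with the `ClusterSet`, the
#'   iteration count, the worst column-sum deviation from 1 observed after
#'   any inflation step, and the converged matrix.
#' @return A [ClusterSet-class] (or the detail list); representatives are
#'   each cluster's attractor (largest converged diagonal), ties by id.
#' @export
mclCluster <- function(similarity, inflation = 2, prune = 1e-5,
                       maxIter = 100, tol = 1e-6, addSelfLoops = TRUE,
                       details = FALSE) {
  m <- as.matrix(similarity)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (any(m < 0)) stop("similarity entries must be non-negative")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (addSelfLoops) diag(m) <- pmax(diag(m), 1)
  normalize <- function(x) {
    cs <- colSums(x)
    cs[cs == 0] <- 1
    sweep(x, 2, cs, "/")
  }
  m <- normalize(m)
  colSumDev <- 0
  it <- 0L
  for (it in seq_len(maxIter)) {
    prev <- m
    m <- m %*% m                 # expansion
    m <- m^inflation             # inflation
    m[m < prune] <- 0            # pruning
    m <- normalize(m)
    colSumDev <- max(colSumDev, abs(colSums(m) - 1))
    if (max(abs(m - prev)) < tol) break
  }
  support <- (m > 0) | t(m > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(ids, comp)
  reps <- vapply(members, function(mem) {
    d <- diag(m)[match(mem, ids)]
    mem[order(-d, mem)][1]
  }, character(1))
  cs <- methods::new("ClusterSet", members = unname(members),
                     representatives = unname(reps))
  if (details) list(clusters = cs, iterations = it,
                    colSumDev = colSumDev, matrix = m)
  else cs
}

#' Merge clusters whose inter-cluster identities exceed a threshold
#'
#' For every cluster pair, the mean and median global identity over all
#' cross pairs of member sequences is computed; a merge edge requires BOTH
#' to exceed the threshold (strictly). Merged clusters are the connected
#' components of the merge graph, so merging is transitive even when a
#' distant pair fails the test directly. With `rule = "any"`, one of the two
#' statistics above threshold suffices.
#'
#' @param cs A [ClusterSet-class].
#' @param seqs Named character vector covering all members.
#' @param minIdentity Percent threshold (default 25).
#' @param rule `"both"` (default) or `"any"`.
#' @param matrix,gapOpen,gapExt Passed to the aligner.
#' @return A merged [ClusterSet-class] (representative = first
#'   representative among the merged parts, by cluster order).
#' @export
mergeClusters <- function(cs, seqs, minIdentity = 25,
                          rule = c("both", "any"), matrix = NULL,
                          gapOpen = 10, gapExt = 0.5) {
  rule <- match.arg(rule)
  k <- length(cs@members)
  if (k <= 1L) return(cs)
  adj <- diag(k) > 0
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      st <- groupIdentityStats(seqs[cs@members[[a]]], seqs[cs@members[[b]]],
                               mode = "global", matrix = matrix,
                               gapOpen = gapOpen, gapExt = gapExt)
      pass <- if (rule == "both") {
        st$mean > minIdentity && st$median > minIdentity
      } else {
        st$mean > minIdentity || st$median > minIdentity
      }
      if (pass) adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- lapply(split(seq_len(k), comp), function(ix)
    unlist(cs@members[ix], use.names = FALSE))
  reps <- vapply(split(seq_len(k), comp), function(ix)
    cs@representatives[ix[1]], character(1))
  methods::new("ClusterSet", members = unname(members),
               representatives = unname(reps))
}

#' Write cluster membership as TSV
#'
#' Columns: `cluster_id`, `member_id`, `is_representative`.
#'
#' @param cs A [ClusterSet-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeClusterTSV <- function(cs, path) {
  rows <- unlist(lapply(seq_along(cs@members), function(i) {
    vapply(cs@members[[i]], function(m)
      paste(i, m, tolower(m == cs@representatives[i]), sep = "\t"),
      character(1))
  }))
  writeLines(c("cluster_id\tmember_id\tis_representative", rows), path)
  invisible(path)
}
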