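# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: score-only dynamic programming in plain R,
# exhaustive enumeration of alignments and internal labelings, and a dense
# grid scan for root placement.

# --- affine-gap global alignment, score only (plain R Gotoh) -------------
# gap of length L costs open + (L-1) * ext, end gaps penalized
oracleGlobalScore <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  Ia <- matrix(-Inf, n + 1, m + 1)
  Ib <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ia[i + 1, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m)) Ib[1, j + 1] <- -(open + (j - 1) * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ia[i, j], Ib[i, j]) + s
      Ia[i + 1, j + 1] <- max(M[i, j + 1] - open, Ia[i, j + 1] - ext,
                              Ib[i, j + 1] - open)
      Ib[i + 1, j + 1] <- max(M[i + 1, j] - open, Ia[i + 1, j] - open,
                              Ib[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# --- full enumeration over all global alignments (tiny inputs only) ------
oracleEnumScore <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  gapCost <- function(L) if (L == 0) 0 else open + (L - 1) * ext
  rec <- function(i, j, score, lastGap) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, score + sub[A[i], B[j]], 0L)
    if (i <= length(A))
      rec(i + 1, j, score - (if (lastGap == 1L) ext else open), 1L)
    if (j <= length(B))
      rec(i, j + 1, score - (if (lastGap == 2L) ext else open), 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# --- minimum label changes by enumeration over internal labelings --------
oracleMinChanges <- function(tree, labels) {
  states <- sort(unique(labels))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tipState <- match(labels[tree$tip.label], states)
  grids <- do.call(expand.grid, rep(list(seq_along(states)), nint))
  edges <- tree$edge
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    full <- c(tipState, as.integer(grids[r, ]))
    changes <- sum(full[edges[, 1]] != full[edges[, 2]])
    best <- min(best, changes)
  }
  best
}

# --- MAD score by dense per-branch grid scan -----------------------------
# deviation of pair (i,j) for a root with leaf distances dr:
# |dr_i - dr_j| / d_ij  (the pair's ancestor is the path point nearest
# the root)
oracleMadScan <- function(tree, gridN = 400) {
  tree <- ape::unroot(tree)
  D <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  tips <- seq_len(ntip)
  prs <- utils::combn(tips, 2)
  dij <- D[cbind(prs[1, ], prs[2, ])]
  # child-side tip sets per edge
  post <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in tips) desc[[i]] <- i
  for (r in seq_len(nrow(post)))
    desc[[post[r, 1]]] <- c(desc[[post[r, 1]]], desc[[post[r, 2]]])
  best <- list(score = Inf)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    inB <- tips %in% desc[[b]]
    for (x in seq(0, len, length.out = gridN)) {
      dr <- ifelse(inB, D[cbind(tips, rep(b, ntip))] + x,
                   D[cbind(tips, rep(a, ntip))] + len - x)
      dev <- abs(dr[prs[1, ]] - dr[prs[2, ]]) / dij
      sc <- sqrt(mean(dev^2))
      if (sc < best$score) best <- list(score = sc, edge = e, x = x)
    }
  }
  best
}

# random binary tree with branch lengths, via recursive splitting
randomTestTree <- function(nLeaves, seed) {
  withr::with_seed(seed, {
    labels <- sample(paste0("t", seq_len(nLeaves)))
    build <- function(lab) {
      if (length(lab) == 1)
        return(sprintf("%s:%.4f", lab, runif(1, 0.1, 2)))
      k <- sample(seq_len(length(lab) - 1), 1)
      sprintf("(%s,%s):%.4f", build(lab[seq_len(k)]),
              build(lab[-seq_len(k)]), runif(1, 0.1, 2))
    }
    k <- sample(seq_len(nLeaves - 1), 1)
    ape::read.tree(text = paste0("(", build(labels[seq_len(k)]), ",",
                                 build(labels[-seq_len(k)]), ");"))
  })
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
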