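# Phylogeny-side verification: Newick I/O, minimal-ancestor-deviation
# rooting, monophyly assessment, minimum-transition counting, and
# placement-based checking of type assignments. Trees are ape `phylo`
# objects throughout.

#' Read / write Newick trees with validation
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that reject
#' unbalanced parentheses and duplicated leaf labels, and preserve branch
#' lengths and internal (support) labels round-trip.
#'
#' @param text Newick string (or a file path for `file`).
#' @param file Optional path to read from instead of `text`.
#' @return An `ape::phylo`.
#' @export
readNewickTree <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("need text or file")
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes) stop("unbalanced parentheses in Newick input")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' @rdname readNewickTree
#' @param tree An `ape::phylo`.
#' @export
writeNewickTree <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

# distance matrix over all nodes (tips + internals) from edge lengths
nodeDistances <- function(tree) {
  ape::dist.nodes(tree)
}

#' Root a tree by minimal ancestor deviation (MAD)
#'
#' For every branch and the optimal root position on it, the relative
#' ancestor deviation of each leaf pair (i, j) is
#' `|2 * d(anc, i) / d(i, j) - 1|`, where `anc` is the point of the i-j
#' path nearest the candidate root; the branch score is the root-mean-
#' square over all pairs, the position on each branch is optimized in
#' closed form (the objective is quadratic in the position), and the tree
#' is rooted at the global minimizer. Zero-length branches are perturbed
#' by `eps`.
#'
#' @param tree Unrooted (or arbitrarily rooted) `ape::phylo` with branch
#'   lengths; at least 3 leaves.
#' @param eps Perturbation for zero-length branches (default 1e-8).
#' @return List: `tree` (rooted `phylo`; the root subdivides the winning
#'   branch at the optimal position), `scores` (data.frame per branch:
#'   `node_a`, `node_b`, `score`, `rho`), `minScore`.
#' @export
madRoot <- function(tree, eps = 1e-8) {
  if (length(tree$tip.label) < 3) stop("MAD rooting needs >= 3 leaves")
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) stop("branch lengths required")
  tree$edge.length[tree$edge.length <= 0] <- eps
  D <- nodeDistances(tree)
  ntip <- length(tree$tip.label)
  tips <- seq_len(ntip)
  pairIdx <- utils::combn(tips, 2)
  dij <- D[cbind(pairIdx[1, ], pairIdx[2, ])]
  npairs <- ncol(pairIdx)

  # leaf bipartition per edge via postorder accumulation of descendants
  desc <- vector("list", ntip + tree$Nnode)
  for (i in tips) desc[[i]] <- i
  edgeOrd <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edgeOrd))) {
    p <- edgeOrd[r, 1]; ch <- edgeOrd[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  scores <- data.frame(node_a = tree$edge[, 1], node_b = tree$edge[, 2],
                       score = NA_real_, rho = NA_real_)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    inB <- tips %in% desc[[b]]
    sideB <- inB[pairIdx[1, ]] & inB[pairIdx[2, ]]
    sideA <- !inB[pairIdx[1, ]] & !inB[pairIdx[2, ]]
    cross <- !(sideA | sideB)
    dev2 <- numeric(npairs)
    # same-side pairs: ancestor = projection of the pair path toward the
    # edge; with reference point r on the root side of both leaves,
    # d(anc, i) = (d(i,j) + d(i,r) - d(j,r)) / 2
    for (side in list(list(mask = sideB, ref = a),
                      list(mask = sideA, ref = b))) {
      if (!any(side$mask)) next
      i <- pairIdx[1, side$mask]; j <- pairIdx[2, side$mask]
      danc <- (dij[side$mask] + D[cbind(i, rep(side$ref, length(i)))] -
                 D[cbind(j, rep(side$ref, length(j)))]) / 2
      dev2[side$mask] <- (2 * danc / dij[side$mask] - 1)^2
    }
    # cross pairs: ancestor is the root point itself; with x measured from
    # node b toward a, d(root, i) = d(b, i) + x for i on the b side
    if (any(cross)) {
      i <- pairIdx[1, cross]; j <- pairIdx[2, cross]
      bi <- ifelse(inB[i], i, j)   # the b-side member of each pair
      dbi <- D[cbind(bi, rep(b, length(bi)))]
      dcr <- dij[cross]
      # minimize sum over cross pairs of (2 (dbi + x)/dij - 1)^2
      cc <- 2 / dcr
      kk <- 2 * dbi / dcr - 1
      x <- -sum(cc * kk) / sum(cc * cc)
      x <- min(max(x, 0), len)
      dev2[cross] <- (kk + cc * x)^2
      scores$rho[e] <- x / len
    } else {
      scores$rho[e] <- 0.5
    }
    scores$score[e] <- sqrt(mean(dev2))
  }
  bestE <- order(scores$score, scores$node_a, scores$node_b)[1]
  rooted <- rootAtEdge(tree, bestE, scores$rho[bestE])
  list(tree = rooted, scores = scores, minScore = scores$score[bestE])
}

# root a tree on edge e, at fraction rho of the way from the child node b
# toward the parent a
rootAtEdge <- function(tree, e, rho) {
  a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
  len <- tree$edge.length[e]
  bTipsOld <- extractCladeTips(tree, b)
  out <- ape::root(tree, outgroup = bTipsOld, resolve.root = TRUE)
  # the two root children are the b subtree and the rest; redistribute the
  # split branch: x from b upward, len - x on the far side
  rootNode <- length(out$tip.label) + 1L
  kids <- which(out$edge[, 1] == rootNode)
  stopifnot(length(kids) == 2L)
  x <- rho * len
  for (k in kids) {
    child <- out$edge[k, 2]
    tipsK <- extractCladeTips(out, child)
    if (setequal(tipsK, bTipsOld)) out$edge.length[k] <- x
    else out$edge.length[k] <- len - x
  }
  out
}

extractCladeTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Is a leaf set monophyletic?
#'
#' TRUE when some clade of the rooted tree contains exactly the given
#' leaves. Also reports the size of the smallest clade containing the set
#' (the MRCA clade).
#'
#' @param tree Rooted `ape::phylo`.
#' @param leaves Character vector of leaf labels (unknown labels are an
#'   error).
#' @return List: `monophyletic` (logical), `cladeSize` (leaf count of the
#'   MRCA clade).
#' @export
isMonophyletic <- function(tree, leaves) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  if (length(leaves) == length(tree$tip.label))
    return(list(monophyletic = TRUE, cladeSize = length(leaves)))
  if (length(leaves) == 1L)
    return(list(monophyletic = TRUE, cladeSize = 1L))
  mrca <- ape::getMRCA(tree, leaves)
  cladeTips <- ape::extract.clade(tree, mrca)$tip.label
  list(monophyletic = setequal(cladeTips, leaves),
       cladeSize = length(cladeTips))
}

#' Minimum number of label transitions on a tree (small parsimony)
#'
#' Unit-cost Sankoff dynamic programming over the rooted tree (equivalent
#' to Fitch counting on binary trees, and valid on multifurcations); the
#' count is root-invariant for this symmetric cost. With `focal`, labels
#' are binarized to focal / other first, giving the minimum number of
#' gains+losses of the focal state. One optimal internal labeling is
#' returned.
#'
#' @param tree `ape::phylo`.
#' @param labels Named character vector, leaf label -> state; every leaf
#'   must be labeled.
#' @param focal Optional state to binarize on.
#' @return List: `count`, `labels` (optimal states for all nodes, tips
#'   first).
#' @export
minTransitions <- function(tree, labels, focal = NULL) {
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing))
    stop("unlabeled leaves: ", paste(missing, collapse = ", "))
  lab <- labels[tree$tip.label]
  if (!is.null(focal)) lab <- ifelse(lab == focal, focal, "other")
  states <- sort(unique(lab))
  ns <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nrow = nnode, ncol = ns,
                 dimnames = list(NULL, states))
  cost[cbind(seq_len(ntip), match(lab, states))] <- 0
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(edges[, 2], edges[, 1])
  for (p in unique(edges[, 1])) cost[p, ] <- 0
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]; ch <- edges[r, 2]
    trans <- vapply(seq_len(ns), function(s)
      min(cost[ch, ] + (seq_len(ns) != s)), numeric(1))
    cost[p, ] <- cost[p, ] + trans
  }
  root <- ntip + 1L
  count <- min(cost[root, ])
  # backtrace one optimal labeling, preorder
  assign <- character(nnode)
  assign[root] <- states[which.min(cost[root, ])]
  pre <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    opts <- cost[ch, ] + (states != assign[p])
    assign[ch] <- states[which.min(opts)]
  }
  names(assign)[seq_len(ntip)] <- tree$tip.label
  list(count = as.integer(count), labels = assign)
}

#' Verify type assignments by phylogenetic placement
#'
#' For each leaf, the majority type among its `k` nearest leaves by
#' patristic distance is compared with the assigned type. Conflicting
#' leaves are reported; assignments flagged ambiguous are resolved to the
#' neighborhood majority when the vote margin is at least `k - 1`; exact
#' vote ties leave the leaf flagged unresolved with its assignment
#' unchanged.
#'
#' @param tree `ape::phylo` whose tips are assignment record ids.
#' @param assignments data.frame with `record_id`, `type` and optionally
#'   `flags`.
#' @param k Neighborhood size (default 5, must be >= 1).
#' @return data.frame per leaf: `record_id`, `assigned`, `majority`,
#'   `votes`, `conflict`, `resolved`, `unresolved_tie`.
#' @export
verifyTypes <- function(tree, assignments, k = 5) {
  if (k < 1) stop("k must be >= 1")
  ids <- tree$tip.label
  if (!all(ids %in% assignments$record_id))
    stop("assignments missing for some leaves")
  type <- assignments$type[match(ids, assignments$record_id)]
  names(type) <- ids
  flags <- if ("flags" %in% names(assignments))
    assignments$flags[match(ids, assignments$record_id)] else ""
  pd <- ape::cophenetic.phylo(tree)
  out <- lapply(ids, function(leaf) {
    d <- pd[leaf, setdiff(ids, leaf)]
    nn <- names(sort(d))[seq_len(min(k, length(d)))]
    votes <- sort(table(type[nn]), decreasing = TRUE)
    top <- names(votes)[votes == max(votes)]
    tie <- length(top) > 1
    majority <- sort(top)[1]
    margin <- if (length(votes) > 1) votes[1] - votes[2] else votes[1]
    ambiguous <- grepl("ambiguous", flags[match(leaf, ids)])
    resolved <- ambiguous && !tie && margin >= k - 1
    data.frame(record_id = leaf, assigned = type[[leaf]],
               majority = if (tie) NA_character_ else majority,
               votes = max(votes),
               conflict = !tie && majority != type[[leaf]],
               resolved = resolved, unresolved_tie = tie,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a leaf annotation table for tree decoration
#'
#' Flat TSV (leaf, type, plus any extra columns) in the style consumed by
#' tree viewers.
#'
#' @param assignments data.frame with `record_id` and annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLeafAnnotations <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
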