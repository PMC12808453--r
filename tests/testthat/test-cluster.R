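makeHits <- function(id, ev) {
  data.frame(query_id = "q", subject_id = paste0("s", seq_along(id)),
             local_identity_pct = id, evalue = ev)
}

test_that("hit filtering applies strict identity and inclusive E-value", {
  h <- makeHits(c(25, 30, 40, 26), c(1e-12, 1e-10, 1e-9, 1e-20))
  kept <- filterHits(h)
  expect_equal(kept$subject_id, c("s2", "s4"))  # 25% and 1e-9 removed
  expect_equal(nrow(filterHits(kept)), nrow(kept))  # idempotent
  empty <- data.frame(local_identity_pct = numeric(0), evalue = numeric(0))
  expect_equal(nrow(filterHits(empty)), 0)
})

test_that("the blast-tab reader enforces 12 columns and numeric fields", {
  path <- tempfile()
  writeLines(c(
    paste(c("q1", "s1", "35.2", "200", "100", "3", "1", "200", "5", "204",
            "1e-30", "150"), collapse = "\t"),
    paste(c("q1", "s2", "99.0", "50", "0", "0", "1", "50", "1", "50",
            "2e-12", "90"), collapse = "\t")), path)
  df <- readBlastTab(path)
  expect_equal(nrow(df), 2)
  expect_equal(df$local_identity_pct, c(35.2, 99))
  writeLines("q1\ts1\t35.2", path)
  expect_error(readBlastTab(path), "row")
})

test_that("greedy reduction collapses duplicates and separates strangers", {
  p <- hasTypeProfiles()
  a <- genSequence(p[["1B"]], 1)$sequence
  b <- genSequence(duf420Profile(), 2)$sequence
  cs <- greedyReduce(c(x = a, y = a))
  expect_equal(length(cs), 1)
  expect_equal(sort(clusterMembers(cs)[[1]]), c("x", "y"))
  cs2 <- greedyReduce(c(x = a, z = b))
  expect_equal(length(cs2), 2)
})

test_that("greedy reduction matches a best-representative oracle outside
           the ambiguity band", {
  # 3 families of near-duplicates (>95% within, <80% between)
  withr::with_seed(5, {
    aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N")
    bases <- replicate(3, paste(sample(aa, 120, TRUE), collapse = ""))
    mut <- function(s, k) {
      r <- strsplit(s, "")[[1]]
      ix <- sample(length(r), k)
      r[ix] <- sample(aa, k, TRUE)
      paste(r, collapse = "")
    }
    seqs <- c(bases[1], mut(bases[1], 2), mut(bases[1], 3),
              bases[2], mut(bases[2], 2), mut(bases[2], 3),
              bases[3], mut(bases[3], 2), mut(bases[3], 3), mut(bases[3], 1))
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    cs <- greedyReduce(seqs, 0.9)
    # oracle: full identity matrix, assign each non-representative to its
    # best representative at >= 90
    n <- length(seqs)
    idm <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- globalIdentity(nwAlign(seqs[[i]], seqs[[j]]))
    }
    expect_true(all(idm[upper.tri(idm)] < 80 | idm[upper.tri(idm)] > 95))
    oracleMembership <- cutree(hclust(as.dist(100 - idm), "single"),
                               h = 10)
    gotMembership <- integer(n)
    for (k in seq_along(clusterMembers(cs)))
      gotMembership[match(clusterMembers(cs)[[k]], names(seqs))] <- k
    expect_equal(length(unique(gotMembership)), length(unique(oracleMembership)))
    expect_true(all(table(gotMembership, oracleMembership) %in%
                      c(0, table(oracleMembership))))
    # representatives cover members at >= threshold
    for (k in seq_along(clusterMembers(cs))) {
      repSeq <- seqs[[representatives(cs)[k]]]
      for (m in clusterMembers(cs)[[k]])
        expect_gte(globalIdentity(nwAlign(repSeq, seqs[[m]])), 90)
    }
  })
})

test_that("MCL separates disconnected cliques and cuts weak bridges", {
  m <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  cs <- mclCluster(m)
  expect_equal(length(cs), 2)
  expect_setequal(clusterMembers(cs)[[1]], c("a", "b", "c"))
  # barbell: triangles joined by one weak edge
  m[3, 4] <- m[4, 3] <- 0.01
  r <- mclCluster(m, details = TRUE)
  expect_equal(length(r$clusters), 2)
  expect_lte(r$colSumDev, 1e-9)
  # single node
  one <- matrix(1, 1, 1, dimnames = list("z", "z"))
  expect_equal(length(mclCluster(one)), 1)
  expect_error(mclCluster(matrix(0, 2, 3)), "square")
})

test_that("MCL clustering is invariant to node order", {
  withr::with_seed(31, {
    n <- 12
    m <- matrix(runif(n * n) < 0.2, n, n) * 1
    m <- pmax(m, t(m))
    m[1:4, 1:4] <- 1
    m[9:12, 1:8] <- 0; m[1:8, 9:12] <- 0
    m[9:12, 9:12] <- 1
    diag(m) <- 0
    dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
    cs1 <- mclCluster(m)
    perm <- sample(n)
    cs2 <- mclCluster(m[perm, perm])
    part <- function(cs) sort(vapply(clusterMembers(cs), function(x)
      paste(sort(x), collapse = "+"), character(1)))
    expect_equal(part(cs1), part(cs2))
  })
})

test_that("cluster merging is a transitive closure over the both-rule", {
  p <- hasTypeProfiles()
  sA <- genSequence(p[["1B"]], 11)$sequence
  sB <- genSequence(p[["1B"]], 12)$sequence
  cs <- methods::new("ClusterSet", members = list("a", "b"),
                     representatives = c("a", "b"))
  merged <- mergeClusters(cs, c(a = sA, b = sB))
  expect_equal(length(merged), 1)
  # clusters failing one statistic are not merged
  expect_equal(homologyGate(data.frame(mean = 30, median = 20)), "exclude")
  dec <- genSequence(duf420Profile(), 13)$sequence
  cs2 <- methods::new("ClusterSet", members = list("a", "d"),
                      representatives = c("a", "d"))
  expect_equal(length(mergeClusters(cs2, c(a = sA, d = dec))), 2)
})

test_that("A-B and B-C merges pull in A-C transitively", {
  # b is a chimera of a's first half and c's second half, so a-b and b-c
  # clear the 25% gate while a-c (disjoint alphabets) does not
  withr::with_seed(8, {
    x1 <- paste(sample(c("A", "D", "E"), 60, TRUE), collapse = "")
    x2 <- paste(sample(c("A", "D", "E"), 60, TRUE), collapse = "")
    y1 <- paste(sample(c("S", "T", "G"), 60, TRUE), collapse = "")
    y2 <- paste(sample(c("S", "T", "G"), 60, TRUE), collapse = "")
    seqs <- c(a = paste0(x1, x2), b = paste0(x1, y2), c = paste0(y1, y2))
    idAC <- globalIdentity(nwAlign(seqs[["a"]], seqs[["c"]]))
    expect_lt(idAC, 25)  # the direct A-C comparison fails the gate
    cs <- methods::new("ClusterSet", members = list("a", "b", "c"),
                       representatives = c("a", "b", "c"))
    merged <- mergeClusters(cs, seqs)
    expect_equal(length(merged), 1)
    expect_setequal(clusterMembers(merged)[[1]], c("a", "b", "c"))
  })
})
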