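toyGenes <- function(n, assembly = "asmA", contig = "c1") {
  data.frame(assembly = assembly, contig = contig,
             gene_id = sprintf("%s_g%02d", assembly, 1:n),
             start = (0:(n - 1)) * 1200 + 1, end = (0:(n - 1)) * 1200 + 1000,
             strand = "+", annotation = "hypothetical",
             stringsAsFactors = FALSE)
}

test_that("window extraction respects the +/-5 bound and contig edges", {
  g <- toyGenes(11)
  w <- extractWindow(g, "asmA_g06")
  expect_equal(nrow(w$neighbors), 10)
  expect_setequal(w$neighbors$offset, c(-5:-1, 1:5))
  wFirst <- extractWindow(g, "asmA_g01")
  expect_true(all(wFirst$neighbors$offset > 0))
  expect_equal(nrow(wFirst$neighbors), 5)
  w1 <- extractWindow(toyGenes(1), "asmA_g01")
  expect_equal(nrow(w1$neighbors), 0)
  expect_error(extractWindow(g, "nope"), "not in table")
  # offset signs match positional relation
  expect_true(all(g$start[match(w$neighbors$gene_id, g$gene_id)] <
                    w$focal$start | w$neighbors$offset > 0))
})

test_that("co-occurrence counts presence per window with printed rounding", {
  g <- toyGenes(11)
  g$annotation[6] <- "HAS_1B"
  g$annotation[8] <- "HOS"
  ctx <- extractWindow(g, "asmA_g06")
  tab <- cooccurrenceTable(list(ctx), "1B", c("HOS"))
  expect_equal(tab$n_with, 1)
  expect_equal(tab$percent, 100)
  # unknown label: zero row plus warning
  expect_warning(tab0 <- cooccurrenceTable(list(ctx), "1B", "XYZ"),
                 "never observed")
  expect_equal(tab0$n_with, 0)
  # fusion self-containment
  g2 <- toyGenes(11)
  g2$annotation[6] <- "HAS_1A;HOS"
  ctx2 <- extractWindow(g2, "asmA_g06")
  tabF <- cooccurrenceTable(list(ctx2), "1A", "HOS")
  expect_equal(tabF$n_with, 1)
  # monotonicity: adding a matching neighbor never lowers the percent
  g3 <- g; g3$annotation[3] <- "HOS"
  ctx3 <- extractWindow(g3, "asmA_g06")
  tab3 <- cooccurrenceTable(list(ctx, ctx3), c("1B", "1B"), "HOS")
  expect_gte(tab3$percent, tab$percent * 0 + 100 * 2 / 2 - 100)
  expect_equal(tab3$n_with, 2)
})

test_that("co-occurrence percentages reproduce known count pairs", {
  expect_equal(percentHalfUp(2140, 2339, 1), 91.5)
  expect_equal(percentHalfUp(31, 4321, 1), 0.7)
})

test_that("distribution matrices count assemblies per lineage", {
  tax <- data.frame(assembly = c("a1", "a2", "a3", "a4"),
                    domain = "Bacteria", phylum = "Bacillota",
                    class = "Bacilli", stringsAsFactors = FALSE)
  asg <- data.frame(record_id = "r1", assembly = "a1", type = "0",
                    stringsAsFactors = FALSE)
  dm <- distributionMatrix(asg, tax)
  expect_equal(dm$matrix["Bacillota", "0"], 25)
  # one lineage, one assembly, one 1B record -> 100
  dm2 <- distributionMatrix(
    data.frame(record_id = "r", assembly = "a1", type = "1B"),
    tax[1, , drop = FALSE])
  expect_equal(dm2$matrix[1, "1B"], 100)
  expect_error(distributionMatrix(
    data.frame(record_id = "r", assembly = "zz", type = "1B"), tax),
    "missing from taxonomy")
})

test_that("every-assembly-hit lineages read 100 and Euryarchaeota splits
           by class", {
  tax <- data.frame(
    assembly = c("m1", "m2", "h1", "h2"),
    domain = "Archaea",
    phylum = c("Ca_Marsarchaeota", "Ca_Marsarchaeota",
               "Euryarchaeota", "Euryarchaeota"),
    class = c("u", "u", "Halobacteria", "Methanococci"),
    stringsAsFactors = FALSE)
  asg <- data.frame(record_id = c("r1", "r2", "r3"),
                    assembly = c("m1", "m2", "h1"),
                    type = c("1A", "1A", "1A*"), stringsAsFactors = FALSE)
  dm <- distributionMatrix(asg, tax)
  expect_equal(dm$matrix["Ca_Marsarchaeota", "1A"], 100)
  expect_true("Euryarchaeota:Halobacteria" %in% rownames(dm$matrix))
  expect_equal(dm$matrix["Euryarchaeota:Halobacteria", "1A*"], 100)
  expect_equal(dm$matrix["Euryarchaeota:Methanococci", "1A*"], 0)
})

test_that("hit-free lineages can be collapsed into one row", {
  tax <- data.frame(assembly = c("a1", "d1", "d2"), domain = "Archaea",
                    phylum = c("Thermoproteota", "DPANN_1", "DPANN_2"),
                    class = "x", stringsAsFactors = FALSE)
  asg <- data.frame(record_id = "r", assembly = "a1", type = "1A",
                    stringsAsFactors = FALSE)
  dm <- distributionMatrix(asg, tax,
                           collapseRules = list(DPANN = c("DPANN_1",
                                                          "DPANN_2")))
  expect_true("DPANN" %in% rownames(dm$matrix))
  expect_false("DPANN_1" %in% rownames(dm$matrix))
  expect_equal(unname(dm$nAssemblies["DPANN"]), 2L)
})

test_that("distribution cells are order-independent", {
  withr::with_seed(21, {
    tax <- data.frame(assembly = paste0("a", 1:12), domain = "Bacteria",
                      phylum = sample(c("P1", "P2"), 12, TRUE),
                      class = "c", stringsAsFactors = FALSE)
    asg <- data.frame(record_id = paste0("r", 1:20),
                      assembly = sample(tax$assembly, 20, TRUE),
                      type = sample(c("1B", "2"), 20, TRUE),
                      stringsAsFactors = FALSE)
    dm1 <- distributionMatrix(asg, tax)
    perm <- sample(nrow(asg))
    dm2 <- distributionMatrix(asg[perm, ], tax[sample(nrow(tax)), ])
    expect_equal(dm1$matrix, dm2$matrix)
  })
})

test_that("sole-HAS fractions use integer half-up percent", {
  asg <- data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    assembly = c("a1", "a2", "a3", "a3"),
    type = c("1A*", "1A*", "1A*", "1A"), stringsAsFactors = FALSE)
  sf <- soleHasFraction(asg, "1A*")
  expect_equal(sf$n_sole, 2)
  expect_equal(sf$n_total, 3)
  expect_equal(sf$percent, 67)
  # single-record corpus
  one <- data.frame(record_id = "r", assembly = "a", type = "2")
  expect_equal(soleHasFraction(one, "2")$percent, 100)
  # type never alone
  never <- data.frame(record_id = c("x", "y"), assembly = c("a", "a"),
                      type = c("1C", "1B"))
  expect_equal(soleHasFraction(never, "1C")$percent, 0)
})
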