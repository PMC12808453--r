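# End-to-end orchestration: configuration, staged execution with per-stage
# TSV outputs, a run manifest, and a human-readable report.

PIPELINE_DEFAULTS <- list(
  min_identity = 25, max_evalue = 1e-10, reduce_threshold = 0.90,
  inflation = 2, cys_min_gap = 2, cys_max_gap = 12, margin = 2,
  window_k = 5, knn_k = 5, seed = 1,
  stages = c("filter", "reduce", "topology", "typing", "motifs",
             "synteny", "distribution", "phylo"))

#' Read and validate a pipeline configuration
#'
#' YAML with two sections: `inputs` (paths: `fasta`, optionally `hits`,
#' `genes`, `topology`, `taxonomy`, `tree`) and `params` (any subset of
#' the defaults: identity/E-value gates, reduction threshold, inflation,
#' cysteine spacing window, ambiguity margin, window and k-NN sizes,
#' seed, stages). Unknown parameter keys are rejected.
#'
#' @param path YAML file path.
#' @return List with `inputs` and `params` (defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- cfg$params
  unknown <- setdiff(names(params), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(PIPELINE_DEFAULTS, params %||% list())
  list(inputs = cfg$inputs %||% list(), params = merged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order (filter, reduce, topology, typing,
#' motifs, synteny, distribution, phylo), writing one TSV per stage plus a
#' `manifest.tsv` with row counts and the configuration, into `outDir`.
#' Reruns with the same inputs and configuration are byte-identical apart
#' from the manifest timestamp. A failing stage aborts with the stage
#' named; its partial output keeps a `.partial` suffix.
#'
#' @param config List as returned by [readPipelineConfig()], or a path to
#'   a YAML config.
#' @param outDir Output directory.
#' @return Invisible list of per-stage results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  p <- config$params
  inp <- config$inputs
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n) manifest[[stage]] <<- n
  out <- list()
  stage <- function(name, fun) {
    if (!name %in% p$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(inp$fasta)) stop("config inputs must include 'fasta'")
  seqsSet <- Biostrings::readAAStringSet(inp$fasta)
  seqs <- stats::setNames(as.character(seqsSet), names(seqsSet))
  note("input", length(seqs))

  stage("filter", function() {
    if (is.null(inp$hits)) return(NULL)
    hits <- readBlastTab(inp$hits)
    kept <- filterHits(hits, p$min_identity, p$max_evalue)
    writeTSV(kept, file.path(outDir, "hits_filtered.tsv"))
    note("filter_in", nrow(hits)); note("filter_kept", nrow(kept))
    out$hits <<- kept
  })

  stage("reduce", function() {
    cs <- greedyReduce(seqs, p$reduce_threshold)
    writeClusterTSV(cs, file.path(outDir, "reduced_clusters.tsv"))
    note("reduce_clusters", length(cs))
    seqs <<- seqs[representatives(cs)]
    out$reduced <<- cs
  })

  topologies <- NULL
  stage("topology", function() {
    topologies <<- if (!is.null(inp$topology)) readTopologyTSV(inp$topology)
    else {
      tl <- lapply(seqs, predictTM)
      tl
    }
    topologies <<- topologies[intersect(names(topologies), names(seqs))]
    writeTopologyTSV(topologies, file.path(outDir, "topology.tsv"))
    note("topology", length(topologies))
  })

  assignments <- NULL
  stage("typing", function() {
    if (is.null(topologies)) stop("typing requires the topology stage")
    panels <- referencePanels()
    assignments <<- assignTypes(seqs[names(topologies)], topologies,
                                panels, minGap = p$cys_min_gap,
                                maxGap = p$cys_max_gap, margin = p$margin)
    writeTSV(assignments, file.path(outDir, "assignments.tsv"))
    note("typed", nrow(assignments))
    out$assignments <<- assignments
  })

  motifs <- NULL
  stage("motifs", function() {
    if (is.null(assignments)) stop("motifs require the typing stage")
    motifs <<- lapply(assignments$record_id, function(id)
      locateMotifs(seqs[[id]], topologies[[id]]))
    tab <- motifFrequencyTable(motifs, assignments$type)
    writeTSV(tab, file.path(outDir, "motif_table.tsv"))
    note("motif_rows", nrow(tab))
    out$motifTable <<- tab
  })

  contexts <- NULL
  stage("synteny", function() {
    if (is.null(inp$genes) || is.null(assignments)) return(NULL)
    genes <- readGeneTable(inp$genes)
    hasGenes <- genes[grepl("^HAS_", genes$annotation), , drop = FALSE]
    contexts <<- lapply(hasGenes$gene_id, function(g)
      extractWindow(genes, g, k = p$window_k))
    ctypes <- sub("^HAS_([^;]+).*$", "\\1", hasGenes$annotation)
    tab <- cooccurrenceTable(contexts, ctypes,
                             c("HOS", "COX", "SCO1", "DUF1507"))
    writeTSV(tab, file.path(outDir, "cooccurrence.tsv"))
    note("synteny_windows", length(contexts))
    out$cooccurrence <<- tab
  })

  stage("distribution", function() {
    if (is.null(inp$taxonomy) || is.null(assignments)) return(NULL)
    if (is.null(inp$truth)) return(NULL)
    truth <- utils::read.delim(inp$truth, stringsAsFactors = FALSE)
    taxonomy <- utils::read.delim(inp$taxonomy, stringsAsFactors = FALSE)
    asg <- merge(assignments, truth[, c("record_id", "assembly")],
                 by = "record_id")
    dm <- distributionMatrix(asg, taxonomy)
    writeTSV(data.frame(lineage = rownames(dm$matrix), dm$matrix,
                        check.names = FALSE),
             file.path(outDir, "distribution.tsv"))
    note("lineages", nrow(dm$matrix))
    out$distribution <<- dm
  })

  stage("phylo", function() {
    if (is.null(inp$tree) || is.null(assignments)) return(NULL)
    tree <- readNewickTree(file = inp$tree)
    keep <- intersect(tree$tip.label, assignments$record_id)
    if (length(keep) < 3) return(NULL)
    tree <- ape::keep.tip(tree, keep)
    conf <- verifyTypes(tree, assignments, k = p$knn_k)
    writeTSV(conf, file.path(outDir, "phylo_verify.tsv"))
    note("phylo_conflicts", sum(conf$conflict))
    out$verify <<- conf
  })

  mdf <- data.frame(key = c("package_version", "seed", names(manifest)),
                    value = c(as.character(utils::packageVersion("HAStyper")),
                              p$seed, unlist(manifest)))
  writeTSV(mdf, file.path(outDir, "manifest.tsv"))
  invisible(out)
}

#' Summarise a completed pipeline run
#'
#' Digest of the per-stage outputs in `outDir`: per-type counts (with
#' total), the co-occurrence table and the conflict count. Missing stage
#' outputs that the digest needs are an error listing them.
#'
#' @param outDir Directory written by [runPipeline()].
#' @return Character vector of report lines (also printed).
#' @export
pipelineReport <- function(outDir) {
  need <- c("assignments.tsv", "manifest.tsv")
  missing <- need[!file.exists(file.path(outDir, need))]
  if (length(missing))
    stop("incomplete run; missing: ", paste(missing, collapse = ", "))
  asg <- utils::read.delim(file.path(outDir, "assignments.tsv"),
                           stringsAsFactors = FALSE)
  if (!nrow(asg)) stop("empty corpus: no assignments")
  counts <- typeCountSummary(asg)
  lines <- c("HAS typing report",
             sprintf("  %-11s %5d", counts$type, counts$n),
             sprintf("  %-11s %5d", "total", sum(counts$n)))
  cooc <- file.path(outDir, "cooccurrence.tsv")
  if (file.exists(cooc)) {
    ct <- utils::read.delim(cooc, stringsAsFactors = FALSE)
    lines <- c(lines, "co-occurrence (%):",
               sprintf("  %-5s %-8s %6.1f", ct$type, ct$label, ct$percent))
  }
  pv <- file.path(outDir, "phylo_verify.tsv")
  if (file.exists(pv)) {
    v <- utils::read.delim(pv, stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("phylogeny conflicts: %d", sum(v$conflict)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
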