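# Synthetic-data generator: sequences, genomes, corpora and labelled trees
# with the statistical structure the downstream analysis assumes.

SUB_RATE_TM <- 0.15    # per-residue substitution rate from the scaffold, TM
SUB_RATE_LOOP <- 0.30  # ... and loops/tails
MAX_REDRAWS <- 50L

drawLoopLength <- function(mean, sd, min) {
  for (i in seq_len(MAX_REDRAWS)) {
    L <- as.integer(round(stats::rnorm(1, mean, sd)))
    if (L >= min) return(L)
  }
  stop("degenerate loop-length profile: mean ", mean, ", sd ", sd,
       ", min ", min)
}

mutateRegion <- function(base, rate, pool) {
  hit <- stats::runif(length(base)) < rate
  if (any(hit)) base[hit] <- sampleFrom(pool, sum(hit))
  base
}

resizeLoop <- function(base, targetLen, pool) {
  n <- length(base)
  if (targetLen <= n) return(base[seq_len(targetLen)])
  c(base, sampleFrom(pool, targetLen - n))
}

sampleResidue <- function(freq) {
  sample(names(freq), 1L, prob = freq)
}

#' Generate one protein record from a type profile
#'
#' Builds a membrane protein realizing the profile's architecture: `nTM`
#' strongly hydrophobic helices separated by polar loops whose lengths are
#' drawn from the profile's per-side distributions (redrawn when below the
#' minimum, bounded retries), a cytoplasmic N-terminus with lysine-enriched
#' cytoplasmic loops (positive-inside rule), cysteine pairs planted in the
#' designated periplasmic loops at an intra-pair spacing of 4-8 interleaving
#' residues, and motif residues sampled from the profile's frequency tables
#' at the anchored helix-II (and, for 8-TM types, helix-VI) positions.
#' Outside the planted pairs, cysteine can appear only as a motif-background
#' draw inside a helix, never in a loop. The same profile and seed always
#' yield the identical record.
#'
#' @param profile A [TypeProfile-class].
#' @param seed Integer seed for this record's RNG stream.
#' @param id Optional record identifier.
#' @return List with elements `id`, `sequence` (string), `type`,
#'   `topology` (truth [Topology-class]), `motif` (named planted residues
#'   with protein-coordinate positions), `cysPairs` (data.frame `ecl`, `i`,
#'   `j`, `spacing`), `loops` (truth loop table).
#' @export
genSequence <- function(profile, seed, id = NULL) {
  sc <- profile@scaffold
  withSeed(seed, {
    nTM <- profile@nTM
    plan <- sc$plan
    cysEcl <- sort(match(profile@cysLoops, c("ECL1", "ECL2", "ECL3", "ECL4")))
    # loop lengths for this record
    loopLens <- integer(nTM - 1L)
    for (k in seq_len(nTM - 1L)) {
      row <- match(plan$side[k], profile@loopLengths$side)
      minLen <- profile@loopLengths$min[row]
      if (!is.na(plan$ecl_index[k]) && plan$ecl_index[k] %in% cysEcl)
        minLen <- max(minLen, 12L)
      loopLens[k] <- drawLoopLength(profile@loopLengths$mean[row],
                                    profile@loopLengths$sd[row], minLen)
    }
    # regions: mutate scaffold, resize loops
    tms <- lapply(seq_len(nTM), function(k)
      mutateRegion(sc$tmSeqs[[k]], SUB_RATE_TM, TM_POOL))
    loops <- lapply(seq_len(nTM - 1L), function(k) {
      pool <- if (plan$side[k] == "out") LOOP_POOL_PERI else LOOP_POOL_CYTO
      resizeLoop(mutateRegion(sc$loopBase[[k]], SUB_RATE_LOOP, pool),
                 loopLens[k], pool)
    })
    tailN <- mutateRegion(sc$tails$N, SUB_RATE_LOOP, LOOP_POOL_CYTO)
    tailC <- mutateRegion(sc$tails$C, SUB_RATE_LOOP, LOOP_POOL_CYTO)

    # plant cysteine pairs in the designated periplasmic loops
    cysPairs <- data.frame(ecl = integer(), iLoop = integer(),
                           jLoop = integer())
    for (ecl in cysEcl) {
      k <- which(plan$ecl_index == ecl)
      spacing <- sample(4:8, 1L)
      i <- 3L
      j <- i + spacing + 1L
      stopifnot(j <= length(loops[[k]]))
      loops[[k]][c(i, j)] <- "C"
      cysPairs <- rbind(cysPairs,
                        data.frame(ecl = ecl, iLoop = i, jLoop = j))
    }

    # plant motif residues
    freqs <- profile@motifFreqs
    blockSlots <- c("E57", "X1", "X2", "H1", "R")
    mirrorSlots <- c("mX1", "mX2", "mX3", "H3", "mX4")
    motifRes <- character(0)
    if (length(freqs)) {
      drawn <- vapply(blockSlots, function(s) sampleResidue(freqs[[s]]),
                      character(1))
      tms[[sc$motifHelix]][MOTIF_BLOCK_OFFSET + 0:4] <- drawn
      motifRes <- drawn
      if (!is.na(sc$mirrorHelix) && all(mirrorSlots %in% names(freqs))) {
        mdrawn <- vapply(mirrorSlots, function(s) sampleResidue(freqs[[s]]),
                         character(1))
        tms[[sc$mirrorHelix]][MOTIF_BLOCK_OFFSET + 0:4] <- mdrawn
        motifRes <- c(motifRes, mdrawn)
      }
      if (!is.na(sc$h2Helix)) tms[[sc$h2Helix]][ANCHOR_OFFSET] <- "H"
      if (!is.na(sc$h4Helix)) tms[[sc$h4Helix]][ANCHOR_OFFSET] <- "H"
    }

    # assemble, tracking TM coordinates
    pieces <- list(tailN)
    tmStart <- integer(nTM)
    pos <- length(tailN)
    for (k in seq_len(nTM)) {
      tmStart[k] <- pos + 1L
      pieces <- c(pieces, list(tms[[k]]))
      pos <- pos + length(tms[[k]])
      if (k < nTM) {
        pieces <- c(pieces, list(loops[[k]]))
        pos <- pos + length(loops[[k]])
      }
    }
    pieces <- c(pieces, list(tailC))
    res <- unlist(pieces, use.names = FALSE)
    tmEnd <- tmStart + sc$tmLengths - 1L
    topo <- Topology(cbind(tmStart, tmEnd), "in", length(res))

    # truth bookkeeping in protein coordinates
    motif <- NULL
    if (length(motifRes)) {
      bpos <- tmStart[sc$motifHelix] + MOTIF_BLOCK_OFFSET - 1L + 0:4
      positions <- stats::setNames(bpos, blockSlots)
      if (length(motifRes) > 5L) {
        mpos <- tmStart[sc$mirrorHelix] + MOTIF_BLOCK_OFFSET - 1L + 0:4
        positions <- c(positions, stats::setNames(mpos, mirrorSlots))
      }
      motif <- list(residues = motifRes, positions = positions)
    }
    cp <- NULL
    if (nrow(cysPairs)) {
      k <- vapply(cysPairs$ecl, function(e) which(plan$ecl_index == e),
                  integer(1))
      loopStart <- tmEnd[k] + 1L
      cp <- data.frame(ecl = cysPairs$ecl,
                       i = loopStart + cysPairs$iLoop - 1L,
                       j = loopStart + cysPairs$jLoop - 1L)
      cp$spacing <- cp$j - cp$i - 1L
    }
    list(id = id, sequence = paste(res, collapse = ""),
         type = profile@typeLabel, topology = topo, motif = motif,
         cysPairs = cp, loops = extractLoops(topo))
  })
}

#' Generate a HAS-HOS fusion record
#'
#' Concatenates a HAS record (N-terminal domain) and an HOS record
#' (C-terminal domain) with a short polar linker, as seen in the type-1A
#' fusions. The truth topology covers only the HAS moiety.
#'
#' @param hasProfile,hosProf [TypeProfile-class] objects for the two moieties.
#' @param seed Integer seed.
#' @param id Optional identifier.
#' @return As [genSequence()], plus `fusion = TRUE` and `hasLength`.
#' @export
genFusionSequence <- function(hasProfile, hosProf = hosProfile(), seed,
                              id = NULL) {
  has <- genSequence(hasProfile, seed, id = id)
  hos <- genSequence(hosProf, seed + 1L)
  linker <- withSeed(seed + 2L,
                     paste(sampleFrom(LOOP_POOL_CYTO, 6L), collapse = ""))
  has$hasLength <- nchar(has$sequence)
  has$sequence <- paste0(has$sequence, linker, hos$sequence)
  has$fusion <- TRUE
  has
}

placeNeighbors <- function(freeOffsets, probs) {
  fams <- names(probs)[stats::runif(length(probs)) < probs]
  fams <- fams[seq_len(min(length(fams), length(freeOffsets)))]
  if (!length(fams)) return(NULL)
  off <- sample(freeOffsets, length(fams))
  stats::setNames(off, fams)
}

#' Generate a gene table (and protein FASTA) for one synthetic genome
#'
#' Lays out `nGenes` contiguous, non-overlapping genes on a single contig
#' and plants HAS genes of the requested types at the requested positions.
#' Neighbor families are placed inside the +/-5-gene window around each
#' planted gene according to the neighbor model's per-type probabilities;
#' the remaining genes carry filler annotations. Type-1A records become
#' HAS-HOS fusions with probability `model$fusionProb`, emitted as a single
#' gene annotated with both family labels.
#'
#' @param nGenes Number of genes (>= 1).
#' @param planted data.frame with columns `type`, `position` (1-based gene
#'   index; duplicated positions are an error).
#' @param model Neighbor model, see [defaultNeighborModel()].
#' @param seed Integer seed.
#' @param assembly Assembly identifier.
#' @param profiles Profiles list from [hasTypeProfiles()].
#' @param emitProteins When `TRUE`, generate protein sequences for the
#'   planted HAS genes (filler genes receive no sequence).
#' @return List with `genes` (data.frame: assembly, contig, gene_id, start,
#'   end, strand, annotation), `records` (list of planted-record outputs of
#'   [genSequence()] keyed by gene id) and `truth` (data.frame of planted
#'   types and fusion flags).
#' @export
genGenome <- function(nGenes, planted, model = defaultNeighborModel(),
                      seed, assembly = "asm1",
                      profiles = hasTypeProfiles(), emitProteins = TRUE) {
  stopifnot(nGenes >= 1)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    if (anyDuplicated(planted$position))
      stop("two planted genes at the same position")
    if (any(planted$position < 1 | planted$position > nGenes))
      stop("planted positions outside 1..nGenes")
  }
  withSeed(seed, {
    geneId <- sprintf("%s_g%04d", assembly, seq_len(nGenes))
    width <- 1000L
    genes <- data.frame(
      assembly = assembly, contig = paste0(assembly, "_c1"),
      gene_id = geneId,
      start = (seq_len(nGenes) - 1L) * (width + 200L) + 1L,
      end = (seq_len(nGenes) - 1L) * (width + 200L) + width,
      strand = sample(c("+", "-"), nGenes, replace = TRUE),
      annotation = sample(FILLER_VOCAB, nGenes, replace = TRUE),
      stringsAsFactors = FALSE)
    records <- list()
    truth <- data.frame(gene_id = character(), type = character(),
                        fusion = logical(), stringsAsFactors = FALSE)
    occupied <- planted$position
    for (r in seq_len(nrow(planted))) {
      type <- planted$type[r]
      posn <- planted$position[r]
      if (!type %in% names(profiles)) stop("no profile for type ", type)
      probs <- model$perType[[type]]
      if (is.null(probs)) probs <- numeric(0)
      fusion <- type == "1A" && stats::runif(1) < model$fusionProb
      recSeed <- sample.int(.Machine$integer.max %/% 2L, 1L)
      rec <- if (fusion && emitProteins) {
        genFusionSequence(profiles[[type]], seed = recSeed,
                          id = genes$gene_id[posn])
      } else if (emitProteins) {
        genSequence(profiles[[type]], recSeed, id = genes$gene_id[posn])
      } else NULL
      hasLabel <- paste0("HAS_", type)
      genes$annotation[posn] <- if (fusion) paste0(hasLabel, ";HOS")
                                else hasLabel
      # neighbor placement inside the +/-5 window; fused HOS satisfies the
      # HOS slot by itself
      win <- setdiff(max(1L, posn - 5L):min(nGenes, posn + 5L),
                     c(posn, occupied))
      if (fusion) probs <- probs[setdiff(names(probs), "HOS")]
      hit <- placeNeighbors(win, probs)
      if (!is.null(hit)) {
        genes$annotation[hit] <- names(hit)
        occupied <- c(occupied, unname(hit))
      }
      if (!is.null(rec)) records[[genes$gene_id[posn]]] <- rec
      truth <- rbind(truth, data.frame(gene_id = genes$gene_id[posn],
                                       type = type, fusion = fusion,
                                       stringsAsFactors = FALSE))
    }
    list(genes = genes, records = records, truth = truth)
  })
}

# small fixed taxonomy vocabulary mirroring the qualitative domain split:
# 4-TM and 1A*-like types archaeal, 1B/1C/1D/2 bacterial, type 0 in both
defaultTaxonomyFor <- function(type, i) {
  arch <- list(c("Archaea", "Thermoproteota", "Thermoprotei"),
               c("Archaea", "Euryarchaeota", "Halobacteria"),
               c("Archaea", "Ca_Marsarchaeota", "unclassified"))
  bact <- list(c("Bacteria", "Pseudomonadota", "Alphaproteobacteria"),
               c("Bacteria", "Bacillota", "Bacilli"),
               c("Bacteria", "Actinomycetota", "Actinomycetes"))
  pick <- switch(type,
    "1A" = , "1A*" = arch,
    "0" = c(arch[1], bact[3]),
    bact)
  unlist(pick[[(i - 1L) %% length(pick) + 1L]])
}

#' Generate a full synthetic corpus
#'
#' One genome per requested record (the HAS gene planted mid-contig),
#' written out as protein FASTA, gene table TSV, topology TSV, taxonomy TSV
#' and truth TSV when `outDir` is given. Per-type counts are exactly as
#' requested.
#'
#' @param counts Named integer vector of per-type record counts, e.g.
#'   `c("1A" = 10, "1B" = 10)`.
#' @param seed Integer seed.
#' @param outDir Optional output directory (created if needed).
#' @param model Neighbor model.
#' @param nGenes Genes per genome.
#' @param profiles Profiles list; requesting a type without a profile is an
#'   error.
#' @return List with `records`, `genes`, `topologies`, `taxonomy`, `truth`
#'   (and, with `outDir`, the written file paths in `files`).
#' @export
genCorpus <- function(counts, seed, outDir = NULL,
                      model = defaultNeighborModel(), nGenes = 11L,
                      profiles = hasTypeProfiles()) {
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) == 0) stop("zero total sequences")
  missing <- setdiff(names(counts), names(profiles))
  if (length(missing))
    stop("no profile for type(s): ", paste(missing, collapse = ", "))
  allGenes <- list(); records <- list(); topo <- list()
  taxonomy <- data.frame(); truth <- data.frame()
  idx <- 0L
  for (type in names(counts)) {
    for (i in seq_len(counts[[type]])) {
      idx <- idx + 1L
      asm <- sprintf("asm%05d", idx)
      g <- genGenome(nGenes, data.frame(type = type,
                                        position = (nGenes + 1L) %/% 2L),
                     model = model, seed = seed + idx, assembly = asm,
                     profiles = profiles)
      allGenes[[asm]] <- g$genes
      rec <- g$records[[1]]
      records[[rec$id]] <- rec
      topo[[rec$id]] <- rec$topology
      tax <- defaultTaxonomyFor(type, i)
      taxonomy <- rbind(taxonomy,
        data.frame(assembly = asm, domain = tax[1], phylum = tax[2],
                   class = tax[3], stringsAsFactors = FALSE))
      truth <- rbind(truth,
        data.frame(record_id = rec$id, assembly = asm, type = type,
                   fusion = isTRUE(rec$fusion),
                   n_tm = tmCount(rec$topology),
                   stringsAsFactors = FALSE))
    }
  }
  genes <- do.call(rbind, allGenes)
  rownames(genes) <- NULL
  out <- list(records = records, genes = genes, topologies = topo,
              taxonomy = taxonomy, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seqs <- Biostrings::AAStringSet(
      vapply(records, `[[`, character(1), "sequence"))
    names(seqs) <- names(records)
    files <- list(
      fasta = file.path(outDir, "proteins.faa"),
      genes = file.path(outDir, "genes.tsv"),
      topology = file.path(outDir, "topology.tsv"),
      taxonomy = file.path(outDir, "taxonomy.tsv"),
      truth = file.path(outDir, "truth.tsv"))
    Biostrings::writeXStringSet(seqs, files$fasta)
    utils::write.table(genes, files$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeTopologyTSV(topo, files$topology)
    utils::write.table(taxonomy, files$taxonomy, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- files
  }
  out
}

# random binary tree in Newick, leaf labels as given
randomCladeNewick <- function(labels) {
  bl <- function() sprintf("%.4f", stats::runif(1, 0.05, 1))
  build <- function(lab) {
    if (length(lab) == 1L) return(paste0(lab, ":", bl()))
    k <- sample(seq_len(length(lab) - 1L), 1L)
    paste0("(", build(lab[seq_len(k)]), ",",
           build(lab[-seq_len(k)]), "):", bl())
  }
  build(sample(labels))
}

caterpillarNewick <- function(tips) {
  bl <- function() sprintf("%.4f", stats::runif(1, 0.05, 1))
  out <- tips[[1]]
  for (t in tips[-1]) out <- paste0("(", out, ",", t, "):", bl())
  out
}

#' Generate a labelled phylogeny under a clean or intercalated scenario
#'
#' `"clean"` places each type's leaves in a single clade. `"intercalated"`
#' emulates repeated cysteine-pair loss: the type-1C leaves are split into
#' `k` separated subclades planted along a type-1B caterpillar backbone, so
#' the parsimony-minimum number of 1B-to-1C transitions equals `k`; other
#' types keep clean clades.
#'
#' @param assignments Named character vector, leaf label -> type.
#' @param scenario `"clean"` or `"intercalated"`.
#' @param k Number of independent 1C transitions (intercalated scenario).
#' @param seed Integer seed.
#' @return List with `tree` (an [ape::phylo]) and `truth` (scenario, k).
#' @export
genLabeledTree <- function(assignments, scenario = c("clean", "intercalated"),
                           k = 3L, seed = 1L) {
  if (length(assignments) < 2L) stop("need at least 2 leaves")
  scenario <- match.arg(scenario)
  withSeed(seed, {
    types <- split(names(assignments), assignments)
    bl <- function() sprintf("%.4f", stats::runif(1, 0.05, 1))
    if (scenario == "clean") {
      clades <- vapply(types, function(lab)
        if (length(lab) == 1L) paste0(lab, ":", bl())
        else paste0("(", randomCladeNewick(lab), "):", bl()),
        character(1))
      nwk <- if (length(clades) == 1L) {
        lab <- types[[1]]
        if (length(lab) == 1L) stop("need at least 2 leaves")
        paste0("(", randomCladeNewick(lab), ");")
      } else paste0("(", paste(clades, collapse = ","), ");")
    } else {
      b <- types[["1B"]]; cc <- types[["1C"]]
      if (is.null(b) || is.null(cc))
        stop("intercalated scenario needs 1B and 1C leaves")
      k <- min(k, length(cc), max(1L, length(b) - 1L))
      patches <- split(cc, rep(seq_len(k), length.out = length(cc)))
      spine <- lapply(b, identity)
      # interleave: one 1C patch after every other 1B spine tip
      tips <- list()
      pi <- 1L
      for (i in seq_along(spine)) {
        tips <- c(tips, spine[[i]])
        if (i %% 2L == 0L && pi <= k) {
          patch <- patches[[pi]]
          tips <- c(tips, if (length(patch) == 1L) patch
                    else paste0("(", randomCladeNewick(patch), "):", bl()))
          pi <- pi + 1L
        }
      }
      while (pi <= k) { # leftovers if the spine was short
        patch <- patches[[pi]]
        tips <- c(tips, if (length(patch) == 1L) patch
                  else paste0("(", randomCladeNewick(patch), "):", bl()))
        pi <- pi + 1L
      }
      core <- caterpillarNewick(tips)
      others <- types[setdiff(names(types), c("1B", "1C"))]
      clades <- vapply(others, function(lab)
        if (length(lab) == 1L) paste0(lab, ":", bl())
        else paste0("(", randomCladeNewick(lab), "):", bl()),
        character(1))
      nwk <- paste0("(", paste(c(core, clades), collapse = ","), ");")
    }
    tree <- ape::read.tree(text = nwk)
    list(tree = tree, truth = list(scenario = scenario,
                                   k = if (scenario == "intercalated") k
                                       else NA_integer_))
  })
}
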