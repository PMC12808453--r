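# Gene-neighborhood synteny: +/-5-gene window extraction, per-type
# co-occurrence statistics, taxonomic distribution matrices, and the
# sole-HAS fraction.

#' Read a gene table
#'
#' Native dialect: TSV with columns `assembly`, `contig`, `gene_id`,
#' `start`, `end`, `strand`, `annotation`. GFF3 files (via rtracklayer) are
#' also accepted; gene id is taken from the `ID` attribute and the
#' annotation from the `product` or `Name` attribute.
#'
#' @param path Path to a gene table (TSV or GFF3, by extension).
#' @return data.frame in the native column layout.
#' @export
readGeneTable <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    ann <- if ("product" %in% names(df)) df$product
           else if ("Name" %in% names(df)) df$Name
           else rep(NA_character_, nrow(df))
    data.frame(assembly = basename(path),
               contig = as.character(df$seqnames),
               gene_id = df$ID, start = df$start, end = df$end,
               strand = as.character(df$strand),
               annotation = ann, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(assembly = "character",
                                     contig = "character",
                                     gene_id = "character",
                                     strand = "character",
                                     annotation = "character"))
  }
}

#' Extract the +/-k gene window around a focal gene
#'
#' Neighbors are the up to `k` genes on each side of the focal gene in
#' positional order (by start coordinate) on the same contig, truncated at
#' contig ends. Offsets are negative upstream (left) and positive
#' downstream (right); the focal strand does not reorient the window.
#'
#' @param genes Gene table (see [readGeneTable()]).
#' @param focalId Gene id present in the table.
#' @param k Window half-width (default 5).
#' @return List: `focal` (one-row data.frame), `neighbors` (data.frame with
#'   `offset`, `gene_id`, `annotation`, `strand`).
#' @export
extractWindow <- function(genes, focalId, k = 5) {
  hit <- which(genes$gene_id == focalId)
  if (!length(hit)) stop("focal gene not in table: ", focalId)
  focal <- genes[hit[1], , drop = FALSE]
  same <- genes[genes$contig == focal$contig &
                  genes$assembly == focal$assembly, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  pos <- which(same$gene_id == focalId)
  sel <- setdiff(max(1L, pos - k):min(nrow(same), pos + k), pos)
  neighbors <- data.frame(offset = sel - pos,
                          gene_id = same$gene_id[sel],
                          annotation = same$annotation[sel],
                          strand = same$strand[sel],
                          stringsAsFactors = FALSE)
  list(focal = focal, neighbors = neighbors)
}

#' Per-type neighbor co-occurrence table
#'
#' For each HAS type and each target neighbor family, counts the records of
#' that type whose window contains at least one neighbor carrying the
#' label (presence semantics: one occurrence is as good as several).
#' Fusion records count as self-containing their fused partner label.
#' Percentages are `100 * n_with / n_total`, one decimal, half-up (the
#' printed precision of co-occurrence fractions). An unknown label yields
#' a zero row with a warning.
#'
#' @param contexts List of [extractWindow()] results.
#' @param types Character vector of focal HAS types, parallel to
#'   `contexts`.
#' @param targetLabels Character vector of neighbor family labels.
#' @return data.frame: `type`, `label`, `n_with`, `n_total`, `percent`.
#' @export
cooccurrenceTable <- function(contexts, types, targetLabels) {
  stopifnot(length(contexts) == length(types))
  seen <- unique(unlist(lapply(contexts, function(ctx)
    c(ctx$neighbors$annotation,
      strsplit(ctx$focal$annotation, ";", fixed = TRUE)[[1]]))))
  rows <- list()
  for (type in unique(types)) {
    sel <- contexts[types == type]
    for (lab in targetLabels) {
      if (!lab %in% seen)
        warning("label never observed: ", lab)
      with <- vapply(sel, function(ctx) {
        own <- strsplit(ctx$focal$annotation, ";", fixed = TRUE)[[1]]
        lab %in% ctx$neighbors$annotation || lab %in% own[-1]
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, label = lab, n_with = sum(with),
        n_total = length(sel),
        percent = percentHalfUp(sum(with), length(sel), digits = 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Taxonomic distribution matrix of HAS types
#'
#' Rows are lineages (phylum, or class for Euryarchaeota), columns HAS
#' types; each cell is the percentage of the lineage's assemblies that
#' contain at least one record of that type. Lineage sets named in
#' `collapseRules` that have no hits at all are collapsed into a single
#' row.
#'
#' @param assignments data.frame with columns `assembly`, `type`.
#' @param taxonomy data.frame with columns `assembly`, `domain`, `phylum`,
#'   `class`; every assembly in `assignments` must appear (missing ones
#'   are an error listing the ids).
#' @param collapseRules Optional named list: collapsed-row name ->
#'   character vector of lineages eligible for collapsing when hit-free.
#' @param classFor Phyla whose rows are split by class (default
#'   `"Euryarchaeota"`).
#' @return List: `matrix` (numeric, lineages x types), `nAssemblies`
#'   (named integer vector).
#' @export
distributionMatrix <- function(assignments, taxonomy, collapseRules = NULL,
                               classFor = "Euryarchaeota") {
  missing <- setdiff(unique(assignments$assembly), taxonomy$assembly)
  if (length(missing))
    stop("assemblies missing from taxonomy: ",
         paste(missing, collapse = ", "))
  lin <- ifelse(taxonomy$phylum %in% classFor,
                paste0(taxonomy$phylum, ":", taxonomy$class),
                taxonomy$phylum)
  names(lin) <- taxonomy$assembly
  types <- sort(unique(assignments$type))
  lineages <- sort(unique(lin))
  nAsm <- vapply(lineages, function(l)
    length(unique(taxonomy$assembly[lin[taxonomy$assembly] == l])),
    integer(1))
  mat <- matrix(0, nrow = length(lineages), ncol = length(types),
                dimnames = list(lineages, types))
  for (l in lineages) {
    asms <- unique(taxonomy$assembly[lin[taxonomy$assembly] == l])
    for (t in types) {
      with <- unique(assignments$assembly[assignments$type == t])
      mat[l, t] <- percentHalfUp(sum(asms %in% with), length(asms),
                                 digits = 1)
    }
  }
  if (!is.null(collapseRules)) {
    for (nm in names(collapseRules)) {
      cand <- intersect(collapseRules[[nm]], rownames(mat))
      zero <- cand[rowSums(mat[cand, , drop = FALSE]) == 0]
      if (length(zero) > 1) {
        keep <- setdiff(rownames(mat), zero)
        collapsed <- rbind(mat[keep, , drop = FALSE],
                           matrix(0, 1, ncol(mat),
                                  dimnames = list(nm, colnames(mat))))
        nAsm <- c(nAsm[keep], stats::setNames(sum(nAsm[zero]), nm))
        mat <- collapsed
      }
    }
  }
  list(matrix = mat, nAssemblies = nAsm)
}

#' Fraction of records that are the only HAS in their genome
#'
#' Of all records assigned to `type`, the fraction that are the sole
#' HAS-family record in their assembly, as an integer percent (half-up).
#'
#' @param assignments data.frame with columns `record_id`, `assembly`,
#'   `type`.
#' @param type Focal type label.
#' @return List: `n_sole`, `n_total`, `percent`.
#' @export
soleHasFraction <- function(assignments, type) {
  sel <- assignments[assignments$type == type, , drop = FALSE]
  perAsm <- table(assignments$assembly)
  sole <- perAsm[sel$assembly] == 1L
  list(n_sole = sum(sole), n_total = nrow(sel),
       percent = if (nrow(sel)) percentHalfUp(sum(sole), nrow(sel)) else 0)
}
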