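#' Read a rooted gene-family tree from a Newick file
#'
#' The leaf order of the returned [GeneTree-class] is the left-to-right order
#' in which the leaves are written in the Newick string (the order used for
#' legume-clade detection). Internal node labels (bootstrap support) are
#' preserved on the underlying `phylo` object.
#'
#' @param path path to a Newick file containing a single tree.
#' @param config optional [SpeciesConfig-class]; when supplied, every leaf
#'   label must resolve to a configured species.
#' @param superfamilyId identifier for the superfamily; defaults to the file
#'   name without extension.
#' @return a [GeneTree-class].
#' @export
readGeneTree <- function(path, config = NULL,
                         superfamilyId = sub("\\.[^.]*$", "", basename(path))) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("cannot parse Newick in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick in '", path, "'")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in '", path, "'")
    tr <- tr[[1L]]
  }
  geneTreeFromPhylo(tr, superfamilyId = superfamilyId, config = config)
}

#' Build a GeneTree from an ape phylo object
#'
#' @param tr a `phylo` object; tip numbering (and hence `tip.label` order) is
#'   assumed to follow the order of appearance in the source Newick, which is
#'   what [ape::read.tree()] produces.
#' @inheritParams readGeneTree
#' @return a [GeneTree-class].
#' @export
geneTreeFromPhylo <- function(tr, superfamilyId = "superfamily",
                              config = NULL) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (length(tr$tip.label) == 0L) stop("tree has no leaves")
  gt <- new("GeneTree", superfamilyId = superfamilyId, tree = tr,
            leafOrder = tr$tip.label)
  if (!is.null(config)) speciesOfGene(gt@leafOrder, config)  # totality check
  gt
}

.computeOrdinals <- function(tb) {
  # genome-wide rank by start within (species, chromosome);
  # ties broken by end then gene_id for determinism
  ord <- rep(NA_integer_, nrow(tb))
  for (key in split(seq_len(nrow(tb)), paste(tb$species, tb$chromosome))) {
    o <- order(tb$start[key], tb$end[key], tb$gene_id[key])
    ord[key[o]] <- seq_along(key)
  }
  ord
}

#' Construct GenePositions from a data.frame
#'
#' @param table data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, and optionally `strand`, `ordinal`, `species`. Coordinates are
#'   1-based inclusive. Missing ordinals are computed by sorting genes per
#'   chromosome by start (ties by end, then gene_id).
#' @param species species code applied to rows lacking a `species` column.
#' @return a [GenePositions-class].
#' @export
genePositions <- function(table, species = NA_character_) {
  tb <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(tb$species)) tb$species <- species
  if (is.null(tb$strand)) tb$strand <- "."
  tb$strand[is.na(tb$strand) | !tb$strand %in% c("+", "-", ".")] <- "."
  if (anyDuplicated(tb$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(tb$gene_id[duplicated(tb$gene_id)]), collapse = ", "))
  if (any(tb$end < tb$start))
    stop("end < start for gene(s): ",
         paste(tb$gene_id[tb$end < tb$start], collapse = ", "))
  if (is.null(tb$ordinal) || anyNA(tb$ordinal))
    tb$ordinal <- .computeOrdinals(tb)
  tb <- tb[, c("gene_id", "species", "chromosome", "start", "end",
               "strand", "ordinal")]
  tb$start <- as.numeric(tb$start); tb$end <- as.numeric(tb$end)
  tb$ordinal <- as.integer(tb$ordinal)
  rownames(tb) <- NULL
  new("GenePositions", table = tb)
}

#' Read gene coordinates
#'
#' Two dialects are supported. `"tsv6"` is a tab-separated table with header
#' `gene_id, chromosome, start, end, strand, ordinal` (1-based inclusive
#' coordinates; an empty/NA ordinal column is recomputed from starts).
#' `"gff3"` reads gene features (`type == "gene"`) through
#' [rtracklayer::import()], taking `gene_id` from the `ID` attribute and
#' computing ordinals per chromosome.
#'
#' @param path file path.
#' @param dialect `"tsv6"` or `"gff3"`.
#' @param species species code recorded for all genes in the file.
#' @return a [GenePositions-class].
#' @export
readPositions <- function(path, dialect = c("tsv6", "gff3"),
                          species = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv6") {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start", "end", "strand")
    if (!all(need %in% names(tb)))
      stop("tsv6 file must have columns: ", paste(need, collapse = ", "))
    return(genePositions(tb, species = species))
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  tb <- data.frame(
    gene_id = as.character(gr$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  tb$strand[tb$strand == "*"] <- "."
  genePositions(tb, species = species)
}

#' Write a GenePositions object as a tsv6 table
#'
#' Writing then re-reading reproduces an identical gene record set.
#'
#' @param positions a [GenePositions-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePositions <- function(positions, path) {
  tb <- positions@table[, c("gene_id", "chromosome", "start", "end",
                            "strand", "ordinal")]
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positions table accessor
#'
#' @param positions a [GenePositions-class].
#' @return the underlying data.frame.
#' @export
positionsTable <- function(positions) positions@table

#' Convert GenePositions to a GRanges
#'
#' @param positions a [GenePositions-class].
#' @return a [GenomicRanges::GRanges] with `gene_id`, `species` and
#'   `ordinal` metadata columns.
#' @export
positionsAsGRanges <- function(positions) {
  tb <- positions@table
  str <- tb$strand; str[str == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = tb$chromosome,
    ranges = IRanges::IRanges(start = tb$start, end = tb$end),
    strand = str,
    gene_id = tb$gene_id, species = tb$species, ordinal = tb$ordinal)
}

#' Construct a TissueExpression object
#'
#' @param values non-negative numeric matrix, genes x samples, with gene ids
#'   as rownames and sample names as colnames.
#' @param sampleTissue named character mapping each sample to one of
#'   `"nodule"`, `"root"`, `"shoot"`. Samples absent from the map are dropped
#'   with a warning.
#' @param species species code the matrix belongs to.
#' @return a [TissueExpression-class].
#' @export
tissueExpression <- function(values, sampleTissue,
                             species = NA_character_) {
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(values < 0)) stop("negative expression value(s)")
  keep <- colnames(values) %in% names(sampleTissue)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) missing from the tissue map: ",
            paste(colnames(values)[!keep], collapse = ", "))
    values <- values[, keep, drop = FALSE]
  }
  st <- sampleTissue[colnames(values)]
  new("TissueExpression", values = values, sampleTissue = st,
      species = species)
}

#' Read an expression matrix and its sample-to-tissue map
#'
#' The matrix file is tab-separated with the gene id in the first column and
#' one column per sample. The sample map is tab-separated with columns
#' `sample_id` and `tissue`.
#'
#' @param path expression matrix file.
#' @param sampleMap sample map file.
#' @param species species code for the matrix.
#' @return a [TissueExpression-class].
#' @export
readExpression <- function(path, sampleMap, species = NA_character_) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tb[[1L]])
  vals <- as.matrix(tb[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  sm <- utils::read.delim(sampleMap, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(sm)))
    stop("sample map must have columns sample_id and tissue")
  map <- stats::setNames(sm$tissue, sm$sample_id)
  tissueExpression(vals, map, species = species)
}

#' Write a TissueExpression matrix and sample map
#'
#' @param expr a [TissueExpression-class].
#' @param path expression matrix file to write.
#' @param sampleMap sample map file to write.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, sampleMap) {
  tb <- data.frame(gene_id = rownames(expr@values), expr@values,
                   check.names = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- data.frame(sample_id = names(expr@sampleTissue),
                   tissue = unname(expr@sampleTissue))
  utils::write.table(sm, sampleMap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expression values and tissue map accessors
#'
#' @param expr a [TissueExpression-class].
#' @return `exprValues()` the matrix; `sampleTissue()` the named tissue map.
#' @export
exprValues <- function(expr) expr@values

#' @rdname exprValues
#' @export
sampleTissue <- function(expr) expr@sampleTissue
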