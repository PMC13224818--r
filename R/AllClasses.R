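#' @import methods
NULL

VALID_GROUPS  <- c("PAP", "CAE", "DET", "CER", "ROS", "OUT")
LEGUME_GROUPS <- c("PAP", "CAE", "DET", "CER")
TISSUES       <- c("nodule", "root", "shoot")

#' SpeciesConfig: species codes, subfamily groups and flags
#'
#' Maps five-letter species codes (three genus + two species letters, e.g.
#' \code{"medtr"} for *Medicago truncatula*) to legume subfamily groups
#' (PAP, CAE, DET, CER) or outgroup groups (ROS, OUT), together with
#' legume and nodulation flags. Also records which codes are treated as the
#' Papilionoideae (PAP) set and which single code as the caesalpinioid (CAE)
#' reference for expression-conservation categorization.
#'
#' @slot species data.frame with columns \code{code}, \code{group},
#'   \code{is_legume}, \code{nodulating}.
#' @slot papSet character, codes used as the PAP set in categorization.
#' @slot caeCode character(1), the CAE reference code.
#' @seealso [legumeSpeciesConfig()], [readSpeciesConfig()]
#' @exportClass SpeciesConfig
setClass("SpeciesConfig",
  representation(species = "data.frame", papSet = "character",
                 caeCode = "character"))

setValidity("SpeciesConfig", function(object) {
  sp <- object@species
  need <- c("code", "group", "is_legume", "nodulating")
  if (!all(need %in% names(sp)))
    return(paste("species table must have columns:", paste(need, collapse = ", ")))
  if (any(nchar(sp$code) != 5L))
    return("species codes must be exactly 5 characters")
  if (anyDuplicated(sp$code)) return("duplicate species codes")
  if (!all(sp$group %in% VALID_GROUPS))
    return(paste("group must be one of", paste(VALID_GROUPS, collapse = "/")))
  if (!identical(as.logical(sp$is_legume), sp$group %in% LEGUME_GROUPS))
    return("is_legume must be TRUE exactly for groups PAP/CAE/DET/CER")
  if (!all(object@papSet %in% sp$code)) return("papSet not a subset of configured codes")
  if (length(object@caeCode) != 1L || !object@caeCode %in% sp$code)
    return("caeCode must be a single configured code")
  TRUE
})

#' GeneTree: a rooted, leaf-labelled gene-family tree
#'
#' Wraps an [ape::read.tree()] \code{phylo} object for one gene superfamily.
#' Leaf labels have the form \code{<code>.<gene_id>} where \code{code} is a
#' configured five-letter species code. \code{leafOrder} is the left-to-right
#' listing of leaves exactly as written in the source Newick; all clade
#' detection operates on this listing, never on branch lengths.
#'
#' @slot superfamilyId character(1).
#' @slot tree a \code{phylo} object (rooted).
#' @slot leafOrder character, permutation of the tip labels in written order.
#' @seealso [readGeneTree()], [detectLegumeClades()]
#' @exportClass GeneTree
setClass("GeneTree",
  representation(superfamilyId = "character", tree = "ANY",
                 leafOrder = "character"))

setValidity("GeneTree", function(object) {
  if (length(object@superfamilyId) != 1L) return("superfamilyId must be length 1")
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be a 'phylo' object")
  if (length(object@leafOrder) != length(tr$tip.label) ||
      !setequal(object@leafOrder, tr$tip.label) ||
      anyDuplicated(object@leafOrder))
    return("leafOrder must be a permutation of the tip labels")
  TRUE
})

#' GenePositions: genomic coordinates and ordinal ranks of genes
#'
#' One row per gene: 1-based inclusive coordinates (GFF3 convention) and the
#' gene's genome-wide ordinal rank on its chromosome (rank among all annotated
#' genes sorted by start). Ordinals drive the "immediately adjacent" test for
#' tandem duplicates; strand is stored but ignored by all proximity logic.
#'
#' @slot table data.frame with columns \code{gene_id}, \code{species},
#'   \code{chromosome}, \code{start}, \code{end}, \code{strand},
#'   \code{ordinal}.
#' @seealso [readPositions()], [localParalogPairs()]
#' @exportClass GenePositions
setClass("GenePositions", representation(table = "data.frame"))

setValidity("GenePositions", function(object) {
  tb <- object@table
  need <- c("gene_id", "species", "chromosome", "start", "end", "strand", "ordinal")
  if (!all(need %in% names(tb)))
    return(paste("positions table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb) == 0L) return(TRUE)
  if (anyDuplicated(tb$gene_id)) return("duplicate gene_id")
  if (any(tb$start < 1L) || any(tb$end < tb$start))
    return("coordinates must satisfy 1 <= start <= end")
  if (any(tb$ordinal < 1L)) return("ordinals must be >= 1")
  if (!all(tb$strand %in% c("+", "-", ".")))
    return("strand must be one of '+', '-', '.'")
  key <- paste(tb$species, tb$chromosome, tb$ordinal)
  if (anyDuplicated(key)) return("ordinal must be unique per (species, chromosome)")
  TRUE
})

#' TissueExpression: a genes-by-samples expression matrix with a tissue map
#'
#' Non-negative expression values (FPKM or TMM-normalized units) for one
#' species, with every retained sample mapped to exactly one of the three
#' tissues nodule, root, shoot.
#'
#' @slot values numeric matrix, genes x samples, all values >= 0.
#' @slot sampleTissue named character: sample name -> tissue.
#' @slot species character(1), the species code the matrix belongs to.
#' @seealso [readExpression()], [tissueProfile()], [geneBias()]
#' @exportClass TissueExpression
setClass("TissueExpression",
  representation(values = "matrix", sampleTissue = "character",
                 species = "character"))

setValidity("TissueExpression", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (any(v < 0)) return("expression values must be non-negative")
  if (is.null(rownames(v))) return("values must have gene ids as rownames")
  if (anyDuplicated(rownames(v))) return("duplicate gene ids")
  st <- object@sampleTissue
  if (!setequal(colnames(v), names(st)) || length(st) != ncol(v))
    return("every sample (column) must be mapped to exactly one tissue")
  if (!all(st %in% TISSUES))
    return(paste("tissues must be among", paste(TISSUES, collapse = "/")))
  if (length(object@species) != 1L) return("species must be length 1")
  TRUE
})

setMethod("show", "SpeciesConfig", function(object) {
  sp <- object@species
  cat("SpeciesConfig with", nrow(sp), "species:",
      sum(sp$is_legume), "legume /", sum(!sp$is_legume), "non-legume\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(sp$group)),
                                  table(sp$group)), collapse = " "), "\n")
  cat("  PAP set:", paste(object@papSet, collapse = ", "),
      "| CAE:", object@caeCode, "\n")
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree", object@superfamilyId, "with",
      length(object@leafOrder), "leaves,",
      length(unique(leafSpecies(object))), "species\n")
})

setMethod("show", "GenePositions", function(object) {
  tb <- object@table
  cat("GenePositions with", nrow(tb), "genes across",
      length(unique(tb$species)), "species\n")
})

setMethod("show", "TissueExpression", function(object) {
  cat("TissueExpression [", object@species, "]: ",
      nrow(object@values), " genes x ", ncol(object@values), " samples (",
      paste(sprintf("%s=%d", TISSUES,
                    vapply(TISSUES, function(t)
                      sum(object@sampleTissue == t), 1L)), collapse = " "),
      ")\n", sep = "")
})
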