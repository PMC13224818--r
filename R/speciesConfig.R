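#' Construct a SpeciesConfig
#'
#' @param species data.frame with columns `code` (5-letter species code),
#'   `group` (one of PAP/CAE/DET/CER/ROS/OUT), `is_legume`, `nodulating`.
#' @param papSet codes treated as the Papilionoideae set for conservation
#'   categorization. Default: the three papilionoids with expression data.
#' @param caeCode the caesalpinioid reference code. Default `"chafa"`
#'   (*Chamaecrista fasciculata*), dropped to the first configured CAE code
#'   if absent.
#' @return a [SpeciesConfig-class] object.
#' @export
SpeciesConfig <- function(species,
                          papSet = intersect(c("medtr", "glyma", "phavu"),
                                             species$code),
                          caeCode = "chafa") {
  species$code <- as.character(species$code)
  species$group <- as.character(species$group)
  species$is_legume <- as.logical(species$is_legume)
  species$nodulating <- as.logical(species$nodulating)
  if (!caeCode %in% species$code) {
    cae <- species$code[species$group == "CAE"]
    if (length(cae)) caeCode <- cae[[1L]]
  }
  new("SpeciesConfig", species = species, papSet = papSet, caeCode = caeCode)
}

#' The default 18-species configuration
#'
#' Twelve legumes spanning four subfamilies (Papilionoideae, Caesalpinioideae,
#' Detarioideae, Cercidoideae) plus six non-legume outgroups at increasing
#' distance (Quillaja, the two Cannabaceae, Prunus, Arabidopsis, Vitis).
#' Codes are three genus + two species letters, e.g. `"lotja"` for
#' *Lotus japonicus*.
#'
#' @return a [SpeciesConfig-class] object.
#' @export
legumeSpeciesConfig <- function() {
  sp <- data.frame(
    code = c("glyma", "medtr", "phavu", "lotja", "aesev",
             "chafa", "sento", "acacr",
             "singl",
             "cerca", "bauva", "phach",
             "quisa", "treor", "paran",
             "arath", "prupe", "vitvi"),
    group = c(rep("PAP", 5), rep("CAE", 3), "DET", rep("CER", 3),
              rep("ROS", 3), rep("OUT", 3)),
    nodulating = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, FALSE, TRUE,
                   FALSE,
                   FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE,
                   FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  sp$is_legume <- sp$group %in% LEGUME_GROUPS
  SpeciesConfig(sp)
}

#' Read a species configuration table
#'
#' Tab-separated file with header `code, group, is_legume, nodulating`.
#'
#' @param path file path.
#' @param papSet,caeCode see [SpeciesConfig()].
#' @return a [SpeciesConfig-class] object.
#' @export
readSpeciesConfig <- function(path,
                              papSet = NULL, caeCode = "chafa") {
  sp <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(papSet)) papSet <- intersect(c("medtr", "glyma", "phavu"), sp$code)
  SpeciesConfig(sp, papSet = papSet, caeCode = caeCode)
}

#' Accessors for SpeciesConfig
#'
#' `speciesCodes()` returns all configured codes, `papSet()` the PAP set,
#' `caeCode()` the CAE reference, `isLegume()` the legume flag for given
#' codes, and `speciesGroup()` the subfamily group.
#'
#' @param config a [SpeciesConfig-class].
#' @param codes character vector of species codes.
#' @return character or logical vectors as described.
#' @export
speciesCodes <- function(config) config@species$code

#' @rdname speciesCodes
#' @export
papSet <- function(config) config@papSet

#' @rdname speciesCodes
#' @export
caeCode <- function(config) config@caeCode

#' @rdname speciesCodes
#' @export
isLegume <- function(config, codes) {
  i <- match(codes, config@species$code)
  if (anyNA(i)) stop("unknown species code(s): ",
                     paste(unique(codes[is.na(i)]), collapse = ", "))
  config@species$is_legume[i]
}

#' @rdname speciesCodes
#' @export
speciesGroup <- function(config, codes) {
  i <- match(codes, config@species$code)
  if (anyNA(i)) stop("unknown species code(s): ",
                     paste(unique(codes[is.na(i)]), collapse = ", "))
  config@species$group[i]
}

#' Resolve the species of a gene-tree leaf label
#'
#' Leaf labels have the form `<code>.<gene_id>`; the species code is the part
#' before the first `"."`, falling back to the first five characters when no
#' separator is present.
#'
#' @param label leaf label(s), e.g. `"medtr.Medtr5g099060"`.
#' @param config a [SpeciesConfig-class].
#' @return one row of the species table per label (data.frame with columns
#'   `code`, `group`, `is_legume`, `nodulating`).
#' @export
speciesOfGene <- function(label, config) {
  if (length(label) == 0L || any(!nzchar(label)))
    stop("empty leaf label")
  code <- sub("\\..*$", "", label)
  nosep <- !grepl(".", label, fixed = TRUE)
  code[nosep] <- substr(label[nosep], 1L, 5L)
  i <- match(code, config@species$code)
  if (anyNA(i))
    stop("leaf label(s) with unknown species code: ",
         paste(unique(label[is.na(i)]), collapse = ", "))
  config@species[i, , drop = FALSE]
}

#' Species code of each leaf of a gene tree
#'
#' @param tree a [GeneTree-class].
#' @param config optional [SpeciesConfig-class]; when given, codes are
#'   validated against it.
#' @return character vector of species codes in leaf order.
#' @export
leafSpecies <- function(tree, config = NULL) {
  lab <- tree@leafOrder
  if (!is.null(config)) return(speciesOfGene(lab, config)$code)
  code <- sub("\\..*$", "", lab)
  nosep <- !grepl(".", lab, fixed = TRUE)
  code[nosep] <- substr(lab[nosep], 1L, 5L)
  code
}

#' Leaf labels in written (left-to-right) order
#'
#' @param tree a [GeneTree-class].
#' @return character vector of leaf labels.
#' @export
leafOrder <- function(tree) tree@leafOrder

#' Superfamily identifier of a gene tree
#'
#' @param tree a [GeneTree-class].
#' @return character(1).
#' @export
superfamilyId <- function(tree) tree@superfamilyId
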