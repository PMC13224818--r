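#' Run the full superfamily analysis pipeline
#'
#' Orchestrates clade detection, duplication classification, ancient-local
#' detection, and tissue-bias labelling with conservation categorization over
#' a collection of superfamilies, producing one `FamilySummary` row per
#' superfamily plus global roll-ups. Families that fail to process are
#' skipped and listed in the `errors` element; the run continues. The result
#' is deterministic given inputs and parameters and equals the join of the
#' individually run module outputs.
#'
#' @param trees list of [GeneTree-class] objects.
#' @param positions a single [GenePositions-class] covering all genes, or a
#'   list parallel to `trees`.
#' @param expression named list of [TissueExpression-class] objects, one per
#'   species code with expression data (may be empty: families without
#'   expression data get NA biases and conservation category 5).
#' @param config a [SpeciesConfig-class].
#' @param window bp window for locality; default 1 Mb.
#' @param fold tissue-bias fold threshold; default 2.
#' @param minSpecies ancient-local species threshold; default 6.
#' @param mode clade mode used for the reported permissive count (both modes
#'   are always computed).
#' @return list with elements
#'   `summary` (data.frame: `superfamily_id`, `n_species`, `n_genes`,
#'   `clade_count_permissive`, `clade_count_strict`, `has_local`,
#'   `n_genes_with_local_paralog`, `is_ancient_local`, one `bias_<code>`
#'   column per expression species, `category`),
#'   `rollups` (named list: `n_families`, `n_multi`, `n_six_plus`,
#'   `n_families_with_local`, `total_genes_with_local_paralog`, `n_ancient`,
#'   `bias_census`), and `errors` (data.frame of skipped families).
#' @export
runAll <- function(trees, positions, expression = list(), config,
                   window = 1e6, fold = 2, minSpecies = 6L,
                   mode = "permissive") {
  single <- methods::is(positions, "GenePositions")
  exprSpecies <- names(expression)
  rows <- list(); errors <- list()
  for (k in seq_along(trees)) {
    res <- tryCatch({
      tr <- trees[[k]]
      pos <- if (single) positions else positions[[k]]
      genes <- .leafGeneId(tr@leafOrder)
      sp <- leafSpecies(tr, config)
      nPerm <- length(detectLegumeClades(tr, config, mode = "permissive"))
      nStrict <- length(detectLegumeClades(tr, config, mode = "strict"))
      have <- genes %in% pos@table$gene_id
      pairs <- if (any(have))
        localParalogPairs(pos, window = window, genes = genes[have])
        else data.frame(relation = character(), gene_a = character(),
                        gene_b = character())
      withLocal <- genesWithLocalParalog(pairs)
      anc <- detectAncientLocal(tr, pos, config, window = window,
                                minSpecies = minSpecies)
      biases <- vapply(exprSpecies, function(code) {
        members <- genes[sp == code]
        if (!length(members)) return(NA_character_)
        familyBias(expression[[code]], members, fold = fold)
      }, character(1))
      cat5 <- suppressWarnings(
        if (length(exprSpecies))
          assignCategory(stats::setNames(biases, exprSpecies), config)
        else 5L)
      row <- data.frame(superfamily_id = tr@superfamilyId,
                        n_species = length(unique(sp)),
                        n_genes = length(genes),
                        clade_count_permissive = nPerm,
                        clade_count_strict = nStrict,
                        has_local = length(withLocal) > 0L,
                        n_genes_with_local_paralog = length(withLocal),
                        is_ancient_local = anc$isAncient,
                        stringsAsFactors = FALSE)
      for (code in exprSpecies) row[[paste0("bias_", code)]] <- biases[[code]]
      row$category <- cat5
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        index = k, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else NULL
  census <- if (!is.null(summary) && length(exprSpecies)) {
    biasCensus(summary[, paste0("bias_", exprSpecies), drop = FALSE])
  } else NULL
  if (!is.null(census)) rownames(census) <- exprSpecies
  rollups <- list(
    n_families = if (is.null(summary)) 0L else nrow(summary),
    n_multi = if (is.null(summary)) 0L
              else sum(summary$clade_count_permissive >= 2L),
    n_six_plus = if (is.null(summary)) 0L
                 else sum(summary$clade_count_permissive >= 6L),
    n_families_with_local = if (is.null(summary)) 0L
                            else sum(summary$has_local),
    total_genes_with_local_paralog =
      if (is.null(summary)) 0L else sum(summary$n_genes_with_local_paralog),
    n_ancient = if (is.null(summary)) 0L else sum(summary$is_ancient_local),
    bias_census = census)
  list(summary = summary,
       rollups = rollups,
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame(index = integer(), message = character()))
}
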