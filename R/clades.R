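#' Enumerate legume gene clades from a tree's leaf listing
#'
#' A legume gene clade is a maximal run of legume-species leaves in the
#' left-to-right leaf listing of a rooted gene tree. In `"strict"` mode a
#' clade is exactly such a run, terminated by any non-legume leaf. In
#' `"permissive"` mode a single non-legume leaf whose immediate neighbours in
#' the listing are both legume leaves does not terminate the run; it is
#' absorbed and recorded as an intruder. Two or more consecutive non-legume
#' leaves always terminate a run, and a non-legume leaf at either end of the
#' listing is never absorbable (it lacks a legume flank on one side). By
#' default a clade may absorb any number of such isolated, individually
#' flanked singletons; `maxIntruders` imposes the stricter
#' one-intruder-per-clade reading (when the cap would be exceeded the
#' offending singleton terminates the clade instead).
#'
#' No re-rooting or ladderization is performed: the listing is taken exactly
#' as written in the source Newick.
#'
#' @param tree a [GeneTree-class].
#' @param config a [SpeciesConfig-class] used to resolve leaf species.
#' @param mode `"permissive"` (default) or `"strict"`.
#' @param maxIntruders maximum number of absorbed intruders per clade in
#'   permissive mode (default `Inf`).
#' @return a list of clades in leaf order. Each clade is a list with elements
#'   `index` (1-based), `members` (ordered legume leaf labels), `intruders`
#'   (absorbed non-legume leaf labels) and `speciesPresent` (species codes of
#'   the members).
#' @examples
#' cfg <- legumeSpeciesConfig()
#' tr <- ape::read.tree(text = "((medtr.a,(vitvi.x,glyma.b)),prupe.y);")
#' gt <- geneTreeFromPhylo(tr, "example")
#' length(detectLegumeClades(gt, cfg, mode = "permissive"))  # 1
#' length(detectLegumeClades(gt, cfg, mode = "strict"))      # 2
#' @export
detectLegumeClades <- function(tree, config,
                               mode = c("permissive", "strict"),
                               maxIntruders = Inf) {
  mode <- match.arg(mode)
  leaves <- tree@leafOrder
  if (length(leaves) == 0L) stop("tree has no leaves")
  legume <- isLegume(config, leafSpecies(tree, config))
  runsToClades(leaves, legume, mode = mode, maxIntruders = maxIntruders)
}

#' Run-enumeration over a binary legume/non-legume leaf sequence
#'
#' The scanning core of [detectLegumeClades()], exposed so that clade logic
#' can be exercised directly on a labelled binary sequence.
#'
#' @param leaves character vector of leaf labels.
#' @param legume logical vector, `TRUE` where the leaf is a legume sequence.
#' @inheritParams detectLegumeClades
#' @return see [detectLegumeClades()].
#' @export
runsToClades <- function(leaves, legume, mode = c("permissive", "strict"),
                         maxIntruders = Inf) {
  mode <- match.arg(mode)
  stopifnot(length(leaves) == length(legume))
  n <- length(leaves)
  clades <- list()
  cur_members <- character(); cur_intruders <- character()
  flush <- function() {
    if (length(cur_members)) {
      clades[[length(clades) + 1L]] <<- list(
        index = length(clades) + 1L,
        members = cur_members,
        intruders = cur_intruders,
        speciesPresent = unique(sub("\\..*$", "", cur_members)))
    }
    cur_members <<- character(); cur_intruders <<- character()
  }
  for (i in seq_len(n)) {
    if (legume[i]) {
      cur_members <- c(cur_members, leaves[i])
    } else {
      absorbable <- mode == "permissive" &&
        i > 1L && i < n && legume[i - 1L] && legume[i + 1L] &&
        length(cur_intruders) < maxIntruders
      if (absorbable) {
        cur_intruders <- c(cur_intruders, leaves[i])
      } else {
        flush()
      }
    }
  }
  flush()
  clades
}

#' Count legume gene clades across a collection of trees
#'
#' @param trees a list of [GeneTree-class] objects.
#' @param config a [SpeciesConfig-class].
#' @param mode clade mode, see [detectLegumeClades()].
#' @param maxIntruders see [detectLegumeClades()].
#' @return a data.frame with one row per superfamily (`superfamily_id`,
#'   `clade_count`), carrying the derived summaries `n_multi` (superfamilies
#'   with >= 2 clades) and `n_six_plus` (>= 6 clades) as attributes
#'   `"n_multi"` and `"n_six_plus"`.
#' @export
cladeCountTable <- function(trees, config,
                            mode = c("permissive", "strict"),
                            maxIntruders = Inf) {
  mode <- match.arg(mode)
  ids <- vapply(trees, superfamilyId, character(1))
  counts <- vapply(trees, function(tr)
    length(detectLegumeClades(tr, config, mode = mode,
                              maxIntruders = maxIntruders)), integer(1))
  out <- data.frame(superfamily_id = ids, clade_count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "n_multi") <- sum(counts >= 2L)
  attr(out, "n_six_plus") <- sum(counts >= 6L)
  out
}
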