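#' Classify same-species paralog pairs by genomic proximity
#'
#' Evaluates every unordered same-species gene pair of one superfamily.
#' Local duplicates are pairs within `window` base pairs on the same
#' chromosome (distance anchored at `|start_a - start_b|`); they are
#' subdivided into tandem duplicates (immediately adjacent: genome-wide
#' ordinal difference exactly 1) and proximal duplicates (non-adjacent but
#' within the window). All remaining pairs -- different chromosomes, or beyond
#' the window (even when ordinally adjacent) -- are distal.
#'
#' @param positions a [GenePositions-class] holding the superfamily's genes
#'   (ordinals are genome-wide ranks, not within-superfamily ranks).
#' @param window window size in base pairs; default 1 Mb.
#' @param adjacency `"genome"` (default) uses the ordinals stored in
#'   `positions` (ranks among all annotated genes); `"within-family"`
#'   recomputes ordinals among the superfamily's genes only before applying
#'   the adjacency test.
#' @param genes optional character vector restricting the analysis to a
#'   subset of gene ids. Ids without coordinates are dropped with a warning.
#' @return data.frame with columns `gene_a`, `gene_b`, `species`,
#'   `chromosome` (NA for cross-chromosome pairs), `distance` (bp; NA for
#'   cross-chromosome pairs) and `relation` (tandem/proximal/distal).
#' @export
localParalogPairs <- function(positions, window = 1e6,
                              adjacency = c("genome", "within-family"),
                              genes = NULL) {
  adjacency <- match.arg(adjacency)
  tb <- positions@table
  if (!is.null(genes)) {
    missing <- setdiff(genes, tb$gene_id)
    if (length(missing))
      warning("excluding ", length(missing),
              " gene(s) without coordinates: ",
              paste(utils::head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ...")
    tb <- tb[tb$gene_id %in% genes, , drop = FALSE]
  }
  if (adjacency == "within-family") tb$ordinal <- .computeOrdinals(tb)
  out <- list()
  for (sp in split(tb, tb$species)) {
    n <- nrow(sp)
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    a <- idx[1L, ]; b <- idx[2L, ]
    same_chr <- sp$chromosome[a] == sp$chromosome[b]
    dist <- ifelse(same_chr, abs(sp$start[a] - sp$start[b]), NA_real_)
    adj <- same_chr & abs(sp$ordinal[a] - sp$ordinal[b]) == 1L
    relation <- ifelse(same_chr & !is.na(dist) & dist <= window,
                       ifelse(adj, "tandem", "proximal"), "distal")
    out[[length(out) + 1L]] <- data.frame(
      gene_a = sp$gene_id[a], gene_b = sp$gene_id[b],
      species = sp$species[a],
      chromosome = ifelse(same_chr, sp$chromosome[a], NA_character_),
      distance = dist, relation = relation, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      species = character(), chromosome = character(),
                      distance = numeric(), relation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes having at least one local (tandem or proximal) paralog
#'
#' @param pairs output of [localParalogPairs()].
#' @return character vector of gene ids appearing in >= 1 pair with relation
#'   tandem or proximal (both members of each local pair are included).
#' @export
genesWithLocalParalog <- function(pairs) {
  loc <- pairs[pairs$relation %in% c("tandem", "proximal"), , drop = FALSE]
  sort(unique(c(loc$gene_a, loc$gene_b)))
}

.leafGeneId <- function(labels) sub("^[^.]*\\.", "", labels)

#' Classify a pair of legume clades as segmental or local in origin
#'
#' For each species present in both clades, tests whether any cross-clade
#' pair (one member in each clade, same species) lies within `window` base
#' pairs on the same chromosome. Clade pairs with positional support in at
#' least `minLocalSpecies` species are called `"local"` (descended from a
#' tandem/proximal duplication); otherwise `"segmental"` (consistent with a
#' WGD-derived duplication, whose copies land on different chromosomes or far
#' apart).
#'
#' @param cladeA,cladeB clades as returned by [detectLegumeClades()], or
#'   plain character vectors of leaf labels / gene ids.
#' @param positions a [GenePositions-class]; clade member labels are matched
#'   by stripping the `<code>.` prefix, falling back to the full label.
#' @param window bp window; default 1 Mb.
#' @param minLocalSpecies minimum number of supporting species for a local
#'   call; default 1 (per-pair typing).
#' @return list with `call` ("segmental"/"local", or NA when the clades share
#'   no species), `sharedSpecies` and `localSupportSpecies`.
#' @export
classifyCladePair <- function(cladeA, cladeB, positions, window = 1e6,
                              minLocalSpecies = 1L) {
  memA <- if (is.list(cladeA)) cladeA$members else cladeA
  memB <- if (is.list(cladeB)) cladeB$members else cladeB
  stopifnot(length(memA) > 0L, length(memB) > 0L)
  tb <- positions@table
  lookup <- function(labels) {
    ids <- .leafGeneId(labels)
    i <- match(ids, tb$gene_id)
    miss <- is.na(i)
    i[miss] <- match(labels[miss], tb$gene_id)
    tb[i[!is.na(i)], , drop = FALSE]
  }
  ta <- lookup(memA); tb2 <- lookup(memB)
  shared <- intersect(ta$species, tb2$species)
  if (!length(shared)) {
    warning("clades share no species; call undefined")
    return(list(call = NA_character_, sharedSpecies = character(),
                localSupportSpecies = character()))
  }
  support <- character()
  for (s in shared) {
    ga <- ta[ta$species == s, , drop = FALSE]
    gb <- tb2[tb2$species == s, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(ga))) {
      same <- gb$chromosome == ga$chromosome[i]
      if (any(same & abs(gb$start - ga$start[i]) <= window, na.rm = TRUE)) {
        hit <- TRUE; break
      }
    }
    if (hit) support <- c(support, s)
  }
  list(call = if (length(support) >= minLocalSpecies) "local" else "segmental",
       sharedSpecies = shared, localSupportSpecies = support)
}

#' Detect ancient retained local duplications in a superfamily
#'
#' An ancient local duplication -- one predating legume diversification -- is
#' called when at least `minSpecies` species have paralogous copies located
#' within `window` bp of one another on the same chromosome, with the two
#' copies falling in *different* strict legume clades (clades containing only
#' legume sequences and bounded by non-legume sequences).
#'
#' @param tree a [GeneTree-class].
#' @param positions a [GenePositions-class] for the superfamily's genes.
#' @param config a [SpeciesConfig-class].
#' @param window bp window; default 1 Mb.
#' @param minSpecies minimum number of supporting species; default 6.
#' @param legumeOnlySupport when `TRUE`, only legume species count as
#'   support. Strict clades contain only legume sequences, so this is a
#'   no-op safeguard; it matters only if non-legume labelled genes are
#'   present in the coordinate table under a legume clade member id.
#' @return list with `superfamilyId`, `isAncient`, `supportingSpecies` and
#'   `cladePairs` (data.frame of supporting clade index pairs per species).
#' @export
detectAncientLocal <- function(tree, positions, config, window = 1e6,
                               minSpecies = 6L, legumeOnlySupport = FALSE) {
  clades <- detectLegumeClades(tree, config, mode = "strict")
  empty <- list(superfamilyId = tree@superfamilyId, isAncient = FALSE,
                supportingSpecies = character(),
                cladePairs = data.frame(species = character(),
                                        clade_a = integer(),
                                        clade_b = integer()))
  if (length(clades) < 2L) return(empty)
  tb <- positions@table
  members <- unlist(lapply(clades, `[[`, "members"), use.names = FALSE)
  cladeOf <- rep(vapply(clades, `[[`, integer(1), "index"),
                 vapply(clades, function(cl) length(cl$members), integer(1)))
  ids <- .leafGeneId(members)
  i <- match(ids, tb$gene_id)
  miss <- is.na(i)
  i[miss] <- match(members[miss], tb$gene_id)
  keep <- !is.na(i)
  dat <- tb[i[keep], , drop = FALSE]
  dat$clade <- cladeOf[keep]
  if (legumeOnlySupport)
    dat <- dat[isLegume(config, dat$species), , drop = FALSE]
  support <- character(); pr <- list()
  for (sp in split(dat, dat$species)) {
    n <- nrow(sp)
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    a <- idx[1L, ]; b <- idx[2L, ]
    ok <- sp$clade[a] != sp$clade[b] &
      sp$chromosome[a] == sp$chromosome[b] &
      abs(sp$start[a] - sp$start[b]) <= window
    if (any(ok)) {
      support <- c(support, sp$species[1L])
      pr[[length(pr) + 1L]] <- data.frame(
        species = sp$species[1L],
        clade_a = pmin(sp$clade[a[ok]], sp$clade[b[ok]]),
        clade_b = pmax(sp$clade[a[ok]], sp$clade[b[ok]]),
        stringsAsFactors = FALSE)
    }
  }
  list(superfamilyId = tree@superfamilyId,
       isAncient = length(support) >= minSpecies,
       supportingSpecies = sort(support),
       cladePairs = if (length(pr)) unique(do.call(rbind, pr))
                    else empty$cladePairs)
}

#' Per-superfamily duplication summary
#'
#' @param trees list of [GeneTree-class] objects.
#' @param positionsList a single [GenePositions-class] covering all genes, or
#'   a list of them parallel to `trees`.
#' @param config a [SpeciesConfig-class].
#' @param window bp window; default 1 Mb.
#' @param minSpecies ancient-local species threshold; default 6.
#' @param adjacency see [localParalogPairs()].
#' @return data.frame with one row per superfamily (`superfamily_id`,
#'   `n_genes`, `n_local_pairs`, `has_local`, `n_genes_with_local_paralog`,
#'   `is_ancient`) carrying the global roll-ups `n_families_with_local`,
#'   `total_genes_with_local_paralog` and `n_ancient` as attributes.
#' @export
familyDupSummary <- function(trees, positionsList, config, window = 1e6,
                             minSpecies = 6L,
                             adjacency = c("genome", "within-family")) {
  adjacency <- match.arg(adjacency)
  single <- methods::is(positionsList, "GenePositions")
  rows <- lapply(seq_along(trees), function(k) {
    tr <- trees[[k]]
    pos <- if (single) positionsList else positionsList[[k]]
    genes <- .leafGeneId(tr@leafOrder)
    have <- genes %in% pos@table$gene_id
    if (!any(have)) {
      warning("superfamily ", tr@superfamilyId,
              ": no genes with coordinates")
      return(data.frame(superfamily_id = tr@superfamilyId,
                        n_genes = length(genes), n_local_pairs = 0L,
                        has_local = FALSE, n_genes_with_local_paralog = 0L,
                        is_ancient = FALSE, stringsAsFactors = FALSE))
    }
    pairs <- localParalogPairs(pos, window = window, adjacency = adjacency,
                               genes = genes[have])
    withLocal <- genesWithLocalParalog(pairs)
    anc <- detectAncientLocal(tr, pos, config, window = window,
                              minSpecies = minSpecies)
    data.frame(superfamily_id = tr@superfamilyId,
               n_genes = length(genes),
               n_local_pairs = sum(pairs$relation %in% c("tandem", "proximal")),
               has_local = length(withLocal) > 0L,
               n_genes_with_local_paralog = length(withLocal),
               is_ancient = anc$isAncient, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_families_with_local") <- sum(out$has_local)
  attr(out, "total_genes_with_local_paralog") <-
    sum(out$n_genes_with_local_paralog)
  attr(out, "n_ancient") <- sum(out$is_ancient)
  out
}
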