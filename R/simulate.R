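#' Simulation configuration for gene-family evolution
#'
#' Defines the study conditions under which synthetic gene families evolve on
#' the fixed 18-species tree (see [legumeSpeciesConfig()]): whole-genome
#' duplication (WGD) events at named internal nodes with per-lineage
#' retention probabilities, tandem and proximal duplication rates per gene
#' per branch, per-copy loss probability per branch, and the chromosome /
#' gene-spacing model used to realize coordinates.
#'
#' Placement guarantees, chosen so the 1 Mb locality rule is exercised on
#' both sides of the boundary: genes descended from local duplications stay
#' in one genomic cluster whose realized span is capped below 1 Mb (tandem
#' copies adjacent, proximal copies with 2-6 intervening background genes),
#' while distinct clusters on the same chromosome are separated by more than
#' 1.2 Mb and WGD copies land on a different chromosome.
#'
#' Nodes eligible for WGD and local-duplication placement include the
#' pre-legume nodes `"eudicots"`, `"rosids"`, `"fabids"`, `"fabales"` (events
#' there predate the legume/non-legume split and are therefore detectable as
#' ancient), the subfamily nodes `"papilionoideae"` and `"caesalpinioideae"`,
#' and any species code (lineage-specific events, e.g. `"glyma"`).
#'
#' @param seed integer; fixes all randomness (per-family substreams are
#'   derived from it, so families are independently reproducible).
#' @param nChrom chromosomes per species.
#' @param tandemRate,proximalRate expected tandem / proximal duplications per
#'   gene per branch.
#' @param lossRate per-copy loss probability per branch.
#' @param wgdEvents list of `list(node =, retention =)` entries; at the named
#'   species-tree node every gene lineage is duplicated onto a different
#'   chromosome with the given retention probability.
#' @param pAncientLocal probability that a family carries a planted tandem
#'   duplication at the root (predating all speciations).
#' @param ancientRetention per-legume-species probability that the planted
#'   root duplicate is retained to the present.
#' @param spacing range (bp) of distances between adjacent gene starts.
#' @param interClusterGap range (bp) separating gene clusters on a
#'   chromosome (kept > 1 Mb).
#' @param clusterSpanCap maximum realized span (bp) of one cluster.
#' @param geneLength annotated gene length (bp).
#' @param maxGenes runaway guard: error if a family exceeds this many gene
#'   lineages.
#' @return a list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1L, nChrom = 8L,
                      tandemRate = 0.04, proximalRate = 0.02,
                      lossRate = 0,
                      wgdEvents = list(
                        list(node = "fabids", retention = 0.4),
                        list(node = "papilionoideae", retention = 0.6),
                        list(node = "caesalpinioideae", retention = 0.4),
                        list(node = "glyma", retention = 0.8)),
                      pAncientLocal = 0.3, ancientRetention = 0.7,
                      spacing = c(2e4, 2e5),
                      interClusterGap = c(1.3e6, 2.5e6),
                      clusterSpanCap = 9.5e5,
                      geneLength = 1e3, maxGenes = 1e5) {
  stopifnot(tandemRate >= 0, tandemRate <= 1, proximalRate >= 0,
            proximalRate <= 1, lossRate >= 0, lossRate <= 1,
            pAncientLocal >= 0, pAncientLocal <= 1,
            ancientRetention >= 0, ancientRetention <= 1)
  cfg <- list(seed = as.integer(seed), nChrom = as.integer(nChrom),
              tandemRate = tandemRate, proximalRate = proximalRate,
              lossRate = lossRate, wgdEvents = wgdEvents,
              pAncientLocal = pAncientLocal,
              ancientRetention = ancientRetention,
              spacing = spacing, interClusterGap = interClusterGap,
              clusterSpanCap = clusterSpanCap, geneLength = geneLength,
              maxGenes = maxGenes)
  class(cfg) <- "simConfig"
  cfg
}

# Fixed 18-taxon species tree (topology only; matches legumeSpeciesConfig)
.speciesTreeSpec <- function() {
  leaf <- function(code) list(name = code, leaf = TRUE)
  n <- function(name, ...) list(name = name, leaf = FALSE,
                                children = list(...))
  n("eudicots",
    n("rosids",
      n("fabids",
        n("fabales",
          n("legumes",
            n("dpanc",
              n("pcanc",
                n("papilionoideae",
                  n("nplc",
                    n("phaseoloids", leaf("glyma"), leaf("phavu")),
                    n("hologalegina", leaf("lotja"), leaf("medtr"))),
                  leaf("aesev")),
                n("caesalpinioideae",
                  leaf("acacr"),
                  n("cassieae", leaf("sento"), leaf("chafa")))),
              leaf("singl")),
            n("cercidoideae",
              leaf("cerca"),
              n("bauhinieae", leaf("bauva"), leaf("phach")))),
          leaf("quisa")),
        n("rosales",
          n("cannabaceae", leaf("treor"), leaf("paran")),
          leaf("prupe"))),
      leaf("arath")),
    leaf("vitvi"))
}

# species-tree nodes whose descendants include both legumes and >= 1
# non-legume: a local duplication at (or above) these nodes ends up spanning
# different strict legume clades, i.e. is detectably ancient
.ancientNodes <- c("eudicots", "rosids", "fabids", "fabales")

#' Simulate one gene family with a known event history
#'
#' Evolves a family down the fixed 18-species tree under the given
#' [simConfig()]: WGD copies land on a different chromosome, tandem copies at
#' the adjacent ordinal position, proximal copies within the same cluster
#' with intervening genes, and losses delete copies. The emitted gene tree
#' reflects the true duplication/speciation history (leaf order is the tree's
#' planar order); coordinates and genome-wide ordinals are consistent with
#' the placements.
#'
#' @param config a [simConfig()].
#' @param familyIndex 1-based family index; combined with `config$seed` to
#'   derive an independent, reproducible random substream per family.
#' @return list with elements
#'   \describe{
#'     \item{tree}{a [GeneTree-class]; leaves `<code>.<gene_id>`.}
#'     \item{positions}{a [GenePositions-class] for all surviving genes with
#'       genome-wide ordinals.}
#'     \item{events}{data.frame event log (`event`, `node`, `parent`,
#'       `child`, `role`, `label`) from which the final gene set can be
#'       reconstructed.}
#'     \item{truth}{ground truth: `pairs` (expected tandem/proximal pairs per
#'       species; all other same-species pairs are distal), `wgd` (per
#'       retained WGD duplication, the two descendant leaf sets), `ancient`
#'       (planted flag, structurally supporting species, i.e. legume species
#'       holding a within-cluster pair whose duplication predates the
#'       legume/non-legume split).}
#'   }
#' @export
simulateFamily <- function(config = simConfig(), familyIndex = 1L) {
  set.seed((abs(config$seed) %% 9973L) * 104729L + familyIndex * 7919L)
  famId <- sprintf("fam%03d", familyIndex)
  env <- new.env(parent = emptyenv())
  env$nextGid <- 0L; env$nextCid <- 0L
  env$log <- list(); env$records <- list(); env$truthPairs <- list()
  chroms <- paste0("chr", seq_len(config$nChrom))
  spTab <- legumeSpeciesConfig()@species
  legumeCodes <- spTab$code[spTab$is_legume]

  newGid <- function() {
    env$nextGid <- env$nextGid + 1L
    if (env$nextGid > config$maxGenes)
      stop("runaway simulation: more than ", config$maxGenes,
           " gene lineages")
    sprintf("g%05d", env$nextGid)
  }
  logRow <- function(event, node, parent, child, role = NA_character_,
                     label = NA_character_) {
    env$log[[length(env$log) + 1L]] <-
      list(event = event, node = node, parent = parent, child = child,
           role = role, label = label)
  }
  newCluster <- function(chrom, members, gaps = integer()) {
    env$nextCid <- env$nextCid + 1L
    list(id = env$nextCid, chrom = chrom, members = members, gaps = gaps)
  }
  findCluster <- function(genome, gid) {
    for (ci in seq_along(genome$clusters))
      if (gid %in% genome$clusters[[ci]]$members) return(ci)
    stop("internal: gene ", gid, " not in any cluster")
  }
  renameGene <- function(genome, old, new) {
    ci <- findCluster(genome, old)
    m <- genome$clusters[[ci]]$members
    m[m == old] <- new
    genome$clusters[[ci]]$members <- m
    genome$genes[[new]] <- genome$genes[[old]]
    genome$genes[[old]] <- NULL
    genome
  }
  removeGene <- function(genome, gid) {
    ci <- findCluster(genome, gid)
    cl <- genome$clusters[[ci]]
    i <- match(gid, cl$members)
    if (length(cl$members) == 1L) {
      genome$clusters[[ci]] <- NULL
    } else {
      g <- cl$gaps
      if (i == 1L) g <- g[-1L]
      else if (i == length(cl$members)) g <- g[-(i - 1L)]
      else { g[i - 1L] <- g[i - 1L] + g[i]; g <- g[-i] }
      cl$members <- cl$members[-i]
      cl$gaps <- g
      genome$clusters[[ci]] <- cl
    }
    genome$genes[[gid]] <- NULL
    genome
  }
  tandemInsert <- function(genome, parent, child) {
    ci <- findCluster(genome, parent)
    cl <- genome$clusters[[ci]]
    i <- match(parent, cl$members)
    cl$members <- append(cl$members, child, after = i)
    cl$gaps <- append(cl$gaps, 0L, after = i - 1L)
    genome$clusters[[ci]] <- cl
    genome
  }
  proximalInsert <- function(genome, parent, child) {
    ci <- findCluster(genome, parent)
    cl <- genome$clusters[[ci]]
    cl$members <- c(cl$members, child)
    cl$gaps <- c(cl$gaps, sample(2:6, 1L))
    genome$clusters[[ci]] <- cl
    genome
  }
  wgdInsert <- function(genome, parent, child) {
    ci <- findCluster(genome, parent)
    other <- setdiff(chroms, genome$clusters[[ci]]$chrom)
    genome$clusters[[length(genome$clusters) + 1L]] <-
      newCluster(sample(other, 1L), child)
    genome
  }
  duplicate <- function(genome, gid, type, node, insert) {
    cont <- newGid(); copy <- newGid()
    logRow(type, node, gid, cont, role = "cont")
    logRow(type, node, gid, copy, role = "copy")
    genome <- renameGene(genome, gid, cont)
    genome <- insert(genome, cont, copy)
    genome$genes[[copy]] <- genome$genes[[cont]]
    list(genome = genome, cont = cont, copy = copy)
  }

  applyWgd <- function(genome, nodeName) {
    for (ev in config$wgdEvents) {
      if (ev$node != nodeName) next
      for (gid in sort(names(genome$genes))) {
        if (stats::runif(1) < ev$retention)
          genome <- duplicate(genome, gid, "dup_wgd", nodeName,
                              wgdInsert)$genome
      }
    }
    genome
  }
  branchEvents <- function(genome, nodeName) {
    for (gid in sort(names(genome$genes))) {
      if (stats::runif(1) < config$lossRate) {
        logRow("loss", nodeName, gid, NA_character_)
        genome <- removeGene(genome, gid)
        next
      }
      cur <- gid
      if (stats::runif(1) < config$tandemRate) {
        r <- duplicate(genome, cur, "dup_tandem", nodeName, tandemInsert)
        genome <- r$genome; cur <- r$cont
      }
      if (stats::runif(1) < config$proximalRate) {
        r <- duplicate(genome, cur, "dup_proximal", nodeName, proximalInsert)
        genome <- r$genome; cur <- r$cont
      }
    }
    genome
  }
  speciate <- function(genome, childName, role) {
    g2 <- list(genes = list(), clusters = genome$clusters)
    for (gid in sort(names(genome$genes))) {
      ng <- newGid()
      logRow("speciation", childName, gid, ng, role = role)
      for (ci in seq_along(g2$clusters)) {
        m <- g2$clusters[[ci]]$members
        if (gid %in% m) {
          m[m == gid] <- ng
          g2$clusters[[ci]]$members <- m
          break
        }
      }
      g2$genes[[ng]] <- genome$genes[[gid]]
    }
    g2
  }

  realizeTip <- function(code, genome) {
    geneId <- function(gid) paste0(famId, "_", gid)
    # deterministic cluster order per chromosome (by creation id)
    byChrom <- split(seq_along(genome$clusters),
                     vapply(genome$clusters, `[[`, character(1), "chrom"))
    for (chrom in sort(names(byChrom))) {
      cis <- byChrom[[chrom]]
      cis <- cis[order(vapply(genome$clusters[cis], `[[`, numeric(1), "id"))]
      pos <- 0; ordinal <- 0L
      for (ci in cis) {
        cl <- genome$clusters[[ci]]
        nbg <- sample(10:15, 1L)
        gapBp <- stats::runif(1, config$interClusterGap[1L],
                              config$interClusterGap[2L])
        pos <- pos + gapBp
        ordinal <- ordinal + nbg  # background genes inside the gap
        m <- length(cl$members)
        # realized intra-cluster steps: one distance per background slot
        # and per family gene beyond the first; capped cluster span
        steps <- if (m > 1L) sum(cl$gaps) + (m - 1L) else 0L
        d <- if (steps > 0L)
          stats::runif(steps, config$spacing[1L], config$spacing[2L])
          else numeric()
        if (steps > 0L && sum(d) > config$clusterSpanCap)
          d <- d * (config$clusterSpanCap / sum(d))
        k <- 0L
        slots <- integer(m)
        for (j in seq_len(m)) {
          if (j > 1L) {
            nsteps <- cl$gaps[j - 1L] + 1L
            pos <- pos + sum(d[(k + 1L):(k + nsteps)])
            ordinal <- ordinal + cl$gaps[j - 1L]
            k <- k + nsteps
          }
          ordinal <- ordinal + 1L
          slots[j] <- if (j == 1L) 0L else slots[j - 1L] + cl$gaps[j - 1L] + 1L
          env$records[[length(env$records) + 1L]] <- data.frame(
            gene_id = geneId(cl$members[j]), species = code,
            chromosome = chrom, start = round(pos),
            end = round(pos) + config$geneLength,
            strand = sample(c("+", "-"), 1L), ordinal = ordinal,
            stringsAsFactors = FALSE)
        }
        if (m > 1L) {
          idx <- utils::combn(m, 2L)
          env$truthPairs[[length(env$truthPairs) + 1L]] <- data.frame(
            gene_a = geneId(cl$members[idx[1L, ]]),
            gene_b = geneId(cl$members[idx[2L, ]]),
            species = code,
            relation = ifelse(abs(slots[idx[2L, ]] - slots[idx[1L, ]]) == 1L,
                              "tandem", "proximal"),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (gid in sort(names(genome$genes)))
      logRow("tip", code, gid, NA_character_,
             label = paste0(code, ".", geneId(gid)))
  }

  evolve <- function(node, genome) {
    genome <- applyWgd(genome, node$name)
    if (isTRUE(node$leaf)) {
      legume <- node$name %in% legumeCodes
      ancients <- names(genome$genes)[
        vapply(genome$genes, function(g) isTRUE(g$ancient), logical(1))]
      if (length(ancients) && legume &&
          stats::runif(1) > config$ancientRetention) {
        for (gid in ancients) {
          logRow("loss", node$name, gid, NA_character_)
          genome <- removeGene(genome, gid)
        }
      }
      realizeTip(node$name, genome)
      return(invisible(NULL))
    }
    childGenomes <- list()
    for (i in seq_along(node$children))
      childGenomes[[i]] <- speciate(genome, node$children[[i]]$name,
                                    role = if (i == 1L) "left" else "right")
    for (i in seq_along(node$children)) {
      cg <- branchEvents(childGenomes[[i]], node$children[[i]]$name)
      evolve(node$children[[i]], cg)
    }
    invisible(NULL)
  }

  # root genome: one gene, optionally with a planted root-level tandem copy
  g1 <- newGid()
  genome <- list(genes = stats::setNames(list(list(ancient = FALSE)), g1),
                 clusters = list(newCluster(sample(chroms, 1L), g1)))
  plantedAncient <- stats::runif(1) < config$pAncientLocal
  if (plantedAncient) {
    r <- duplicate(genome, g1, "dup_tandem", "eudicots", tandemInsert)
    genome <- r$genome
    genome$genes[[r$copy]]$ancient <- TRUE
  }
  evolve(.speciesTreeSpec(), genome)

  log <- do.call(rbind, lapply(env$log, as.data.frame))
  rownames(log) <- NULL
  tree <- .geneTreeFromLog(log, famId)
  records <- do.call(rbind, env$records)
  positions <- genePositions(records)
  pairs <- if (length(env$truthPairs)) {
    p <- do.call(rbind, env$truthPairs); rownames(p) <- NULL; p
  } else data.frame(gene_a = character(), gene_b = character(),
                    species = character(), relation = character(),
                    stringsAsFactors = FALSE)
  truth <- list(
    pairs = pairs,
    wgd = .wgdTruth(log),
    ancient = list(planted = plantedAncient,
                   supportingSpecies = .ancientSupport(log, pairs, famId)))
  list(tree = tree, positions = positions, events = log, truth = truth)
}

# reconstruct the gene tree (Newick, planar order = event order) from the log
.geneTreeFromLog <- function(log, famId) {
  kids <- split(seq_len(nrow(log)), log$parent)
  build <- function(gid) {
    rows <- kids[[gid]]
    if (is.null(rows)) return(NULL)  # should not happen: every gid has a fate
    ev <- log$event[rows[1L]]
    if (ev == "tip") return(log$label[rows[1L]])
    if (ev == "loss") return(NULL)
    l <- build(log$child[rows[1L]])
    r <- build(log$child[rows[2L]])
    if (is.null(l)) return(r)
    if (is.null(r)) return(l)
    paste0("(", l, ",", r, ")")
  }
  # root gid is the one never created as a child
  rootGid <- setdiff(log$parent, log$child)[1L]
  s <- build(rootGid)
  if (is.null(s)) stop("family went extinct: no surviving genes")
  if (!grepl("(", s, fixed = TRUE)) s <- paste0("(", s, ")")
  tr <- ape::read.tree(text = paste0(s, ";"))
  geneTreeFromPhylo(tr, superfamilyId = famId)
}

# leaf sets descending from each retained WGD duplication
.wgdTruth <- function(log) {
  kids <- split(seq_len(nrow(log)), log$parent)
  tipsUnder <- function(gid) {
    rows <- kids[[gid]]
    if (is.null(rows)) return(character())
    ev <- log$event[rows[1L]]
    if (ev == "tip") return(log$label[rows[1L]])
    if (ev == "loss") return(character())
    c(tipsUnder(log$child[rows[1L]]), tipsUnder(log$child[rows[2L]]))
  }
  w <- which(log$event == "dup_wgd" & log$role == "cont")
  out <- list()
  for (i in w) {
    parent <- log$parent[i]
    rows <- kids[[parent]]
    a <- tipsUnder(log$child[rows[1L]])
    b <- tipsUnder(log$child[rows[2L]])
    if (!length(a) || !length(b)) next
    spA <- sub("\\..*$", "", a); spB <- sub("\\..*$", "", b)
    if (!length(intersect(spA, spB))) next
    out[[length(out) + 1L]] <- list(node = log$node[i], cladeA = a,
                                    cladeB = b)
  }
  out
}

# legume species holding a within-cluster pair whose duplication event
# predates the legume/non-legume split (node among .ancientNodes)
.ancientSupport <- function(log, pairs, famId) {
  if (!nrow(pairs)) return(character())
  cfg <- legumeSpeciesConfig()
  legumes <- cfg@species$code[cfg@species$is_legume]
  pairs <- pairs[pairs$species %in% legumes, , drop = FALSE]
  if (!nrow(pairs)) return(character())
  parentOf <- stats::setNames(log$parent, log$child)
  eventOf <- stats::setNames(log$event, log$child)
  nodeOf <- stats::setNames(log$node, log$child)
  chain <- function(gid) {
    out <- gid
    while (gid %in% names(parentOf)) {
      gid <- parentOf[[gid]]
      out <- c(out, gid)
    }
    out
  }
  stripFam <- function(ids) sub(paste0("^", famId, "_"), "", ids)
  support <- character()
  for (i in seq_len(nrow(pairs))) {
    a <- stripFam(pairs$gene_a[i]); b <- stripFam(pairs$gene_b[i])
    # gids at tips carry no species prefix in the log
    ca <- chain(a); cb <- chain(b)
    anc <- ca[ca %in% cb][1L]
    if (is.na(anc)) next
    childOnA <- ca[match(anc, ca) - 1L]
    if (eventOf[[childOnA]] %in% c("dup_tandem", "dup_proximal") &&
        nodeOf[[childOnA]] %in% .ancientNodes)
      support <- c(support, pairs$species[i])
  }
  sort(unique(support))
}

#' Simulate a batch of gene families
#'
#' @param n number of families.
#' @param config a [simConfig()]; family `k` uses an independent random
#'   substream derived from `config$seed` and `k`.
#' @return list of [simulateFamily()] results.
#' @export
simulateFamilies <- function(n, config = simConfig()) {
  lapply(seq_len(n), function(k) simulateFamily(config, familyIndex = k))
}
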