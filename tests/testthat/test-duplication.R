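test_that("paralog pairs are classified tandem/proximal/distal by the 1 Mb rule", {
  # adjacent ordinals, within window -> tandem
  p <- localParalogPairs(posTable(c(1e5, 6e5), c(10L, 11L)))
  expect_equal(p$relation, "tandem")
  expect_equal(p$distance, 5e5)

  # within window, non-adjacent -> proximal
  p <- localParalogPairs(posTable(c(1e5, 9e5), c(10L, 14L)))
  expect_equal(p$relation, "proximal")

  # different chromosomes -> distal, distance undefined
  p <- localParalogPairs(posTable(c(1e5, 2e5), c(1L, 1L),
                                  chrom = c("chr1", "chr2")))
  expect_equal(p$relation, "distal")
  expect_true(is.na(p$distance))

  # adjacent ordinals but beyond 1 Mb -> distal (tandem requires the window)
  p <- localParalogPairs(posTable(c(1e5, 1.5e6), c(10L, 11L)))
  expect_equal(p$relation, "distal")

  # different species are never paired
  two <- genePositions(data.frame(
    gene_id = c("a", "b"), species = c("medtr", "glyma"),
    chromosome = "chr1", start = c(1e5, 2e5), end = c(1e5, 2e5) + 100,
    strand = "+", ordinal = c(1L, 2L)))
  expect_equal(nrow(localParalogPairs(two)), 0L)
})

test_that("relation partitions all same-species pairs", {
  set.seed(7)
  pos <- posTable(sort(sample(1:5e6, 12)), 1:12,
                  chrom = sample(c("chr1", "chr2"), 12, replace = TRUE))
  pos@table$ordinal <- nodufam:::.computeOrdinals(pos@table)
  p <- localParalogPairs(pos)
  expect_equal(nrow(p), choose(12, 2))
  expect_true(all(p$relation %in% c("tandem", "proximal", "distal")))
  # tandem pairs are always within the window
  expect_true(all(p$distance[p$relation == "tandem"] <= 1e6))
})

test_that("within-family adjacency is an explicit variant", {
  # two family genes separated by background genes: genome-wide ordinals
  # differ by 3 -> proximal; within-family ordinals are adjacent -> tandem
  pos <- posTable(c(1e5, 4e5), c(10L, 13L))
  expect_equal(localParalogPairs(pos)$relation, "proximal")
  expect_equal(localParalogPairs(pos, adjacency = "within-family")$relation,
               "tandem")
})

test_that("genes with a local paralog include both members of each pair", {
  pairs <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
                      relation = c("tandem", "distal"))
  expect_setequal(genesWithLocalParalog(pairs), c("g1", "g2"))
  expect_length(genesWithLocalParalog(pairs[0, ]), 0L)
})

test_that("clade pairs are typed segmental or local from positional support", {
  # one gene per clade per species, different chromosomes -> segmental
  pos <- genePositions(data.frame(
    gene_id = c("a1", "a2", "b1", "b2"),
    species = c("medtr", "glyma", "medtr", "glyma"),
    chromosome = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1e5, 1e5, 1e5, 1e5), end = 1e5 + 100, strand = "+",
    ordinal = c(1L, 1L, 1L, 1L)))
  cc <- classifyCladePair(c("medtr.a1", "glyma.a2"),
                          c("medtr.b1", "glyma.b2"), pos)
  expect_equal(cc$call, "segmental")
  expect_setequal(cc$sharedSpecies, c("medtr", "glyma"))
  expect_length(cc$localSupportSpecies, 0L)

  # a single within-window cross-clade pair -> local at minLocalSpecies = 1
  pos2 <- genePositions(data.frame(
    gene_id = c("a1", "b1"), species = "medtr", chromosome = "chr1",
    start = c(1e5, 2e5), end = c(1e5, 2e5) + 100, strand = "+",
    ordinal = c(1L, 2L)))
  cc2 <- classifyCladePair("medtr.a1", "medtr.b1", pos2)
  expect_equal(cc2$call, "local")
  expect_equal(cc2$localSupportSpecies, "medtr")

  # no shared species -> undefined call with warning
  expect_warning(
    cc3 <- classifyCladePair("medtr.a1", "glyma.b2", pos),
    "no species")
  expect_true(is.na(cc3$call))
})

test_that("ancient local detection uses strict clades and a species threshold", {
  fam <- simulateFamily(
    simConfig(seed = 9L, tandemRate = 0, proximalRate = 0,
              pAncientLocal = 1, ancientRetention = 1, wgdEvents = list()), 1L)
  a <- detectAncientLocal(fam$tree, fam$positions, CFG)
  expect_true(a$isAncient)
  expect_length(a$supportingSpecies, 12L)  # all legume species retained
  expect_true(all(a$cladePairs$clade_a != a$cladePairs$clade_b))

  # monotone in the threshold: raising it can only turn the call off
  a13 <- detectAncientLocal(fam$tree, fam$positions, CFG, minSpecies = 13L)
  expect_false(a13$isAncient)

  # fewer than 2 strict clades: no call possible
  single <- treeFromPattern(c("L", "L"))
  a0 <- detectAncientLocal(single, fam$positions, CFG)
  expect_false(a0$isAncient)
})

test_that("family-level duplication summaries roll up", {
  mk <- function(id, starts, ords) {
    ids <- paste0(id, "_g", seq_along(starts))
    labs <- paste0("medtr.", ids)
    s <- labs[length(labs)]
    for (i in rev(seq_len(length(labs) - 1L))) s <- paste0("(", labs[i], ",", s, ")")
    tree <- geneTreeFromPhylo(ape::read.tree(text = paste0(s, ";")),
                              superfamilyId = id)
    list(tree = tree, pos = posTable(starts, ords, ids = ids))
  }
  f1 <- mk("f1", c(1e5, 2e5, 5e5), c(1L, 2L, 4L))   # tandem + 2 proximal
  f2 <- mk("f2", c(1e5, 5e6), c(1L, 40L))            # distal only
  f3 <- mk("f3", c(1e5, 3e5), c(1L, 3L))             # 1 proximal
  summ <- familyDupSummary(list(f1$tree, f2$tree, f3$tree),
                           list(f1$pos, f2$pos, f3$pos), CFG)
  expect_equal(summ$n_local_pairs, c(3L, 0L, 1L))
  expect_equal(summ$has_local, c(TRUE, FALSE, TRUE))
  expect_equal(attr(summ, "n_families_with_local"), 2L)
  expect_equal(attr(summ, "total_genes_with_local_paralog"), 3L + 0L + 2L)

  # genes without coordinates: has_local FALSE with a warning
  orphan <- treeFromPattern(c("L", "L"))
  expect_warning(
    s2 <- familyDupSummary(list(orphan), list(posTable(1e5, 1L, ids = "zz")),
                           CFG),
    "no genes with coordinates")
  expect_false(s2$has_local)
})
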