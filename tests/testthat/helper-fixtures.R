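# Shared fixtures: built in code at test time.

CFG <- legumeSpeciesConfig()

# Build a GeneTree from an explicit binary legume/non-legume leaf sequence,
# using a caterpillar topology so leaf order equals the given sequence.
# legume positions get medtr leaves, others vitvi.
treeFromPattern <- function(pattern) {
  stopifnot(all(pattern %in% c("L", "N")))
  labs <- ifelse(pattern == "L",
                 paste0("medtr.L", seq_along(pattern)),
                 paste0("vitvi.N", seq_along(pattern)))
  nwk <- if (length(labs) == 1L) paste0("(", labs, ");") else {
    s <- labs[length(labs)]
    for (i in rev(seq_len(length(labs) - 1L))) s <- paste0("(", labs[i], ",", s, ")")
    paste0(s, ";")
  }
  geneTreeFromPhylo(ape::read.tree(text = nwk), superfamilyId = "pattern")
}

# Independent oracle for clade enumeration: regular-expression matching on
# the L/N string (strict: maximal runs of L; permissive: L(NL|L)* so isolated
# flanked N's are absorbed).
oracleCladeCounts <- function(pattern) {
  s <- paste(pattern, collapse = "")
  count <- function(rx) {
    m <- gregexpr(rx, s)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  list(strict = count("L+"), permissive = count("L(NL|L)*"))
}

# One cached batch of simulated families under the default study conditions
# (seed 1, loss-free), shared by the synthetic-data and acceptance tests.
simBatch50 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateFamilies(50, simConfig(seed = 1L))
    cache
  }
})

# A small positions table built by hand (one species unless stated).
posTable <- function(starts, ordinals, chrom = "chr1", species = "medtr",
                     ids = paste0("g", seq_along(starts))) {
  genePositions(data.frame(
    gene_id = ids, species = species,
    chromosome = rep_len(chrom, length(starts)),
    start = starts, end = starts + 1000, strand = "+",
    ordinal = ordinals, stringsAsFactors = FALSE))
}
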