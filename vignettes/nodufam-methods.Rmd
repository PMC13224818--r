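---
title: "Methods: duplication and expression-bias analysis of nodulation gene superfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication and expression-bias analysis of nodulation gene superfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodufam)
```

## The problem

Root-nodule symbiosis (RNS) genes live in superfamilies whose copy numbers
were shaped by whole-genome duplications (WGDs) and by local — tandem and
proximal — duplications. Given per-superfamily rooted gene trees over a panel
of legume and outgroup species, gene coordinates, and tissue-level expression
matrices, `nodufam` answers four questions per superfamily: how many legume
gene clades does the tree contain; which paralog pairs are local and which
duplicated clades are segmental (WGD-derived) versus local in origin; does
the family carry an *ancient* retained local duplication predating legume
diversification; and how are two-fold tissue-expression biases distributed
and conserved across species.

The package deliberately works from the *leaf listing* of a rooted tree
rather than from tree reconciliation: clades are runs in the written leaf
order, and duplication typing combines run structure with genomic proximity.
This mirrors how practitioners annotate large superfamily trees by eye and
keeps every call auditable.

## Data model

Five-letter species codes (three genus + two species letters) prefix every
leaf label as `<code>.<gene_id>`; `legumeSpeciesConfig()` ships the default
18-species panel spanning four legume subfamilies (PAP, CAE, DET, CER) and
six non-legume outgroups (ROS, OUT). Coordinates are 1-based inclusive (GFF3
convention), read either from GFF3 gene features or a six-column TSV. The
*ordinal* of a gene is its genome-wide rank among all annotated genes on its
chromosome sorted by start; when absent it is computed from starts with ties
broken by end then gene id, a deterministic choice. Strand is stored but
never consulted: locality is about distance and ordinal adjacency, not
orientation.

## Clade enumeration

Scanning the leaf listing left to right over the binary legume/non-legume
sequence, strict mode emits maximal runs of legume leaves. Permissive mode
additionally absorbs a non-legume leaf whose immediate neighbours are both
legume leaves; two or more consecutive non-legume leaves always terminate a
run, and a non-legume leaf at either end of the listing is never absorbable
(it lacks a flank on one side — the flanking requirement read literally).
Because an absorbed intruder can only merge strict runs, the permissive
count never exceeds the strict count.

Two genuinely open readings are both supported. The absorption rule could
cap intruders at one per clade or treat each isolated, flanked singleton
independently; the default is per-occurrence (unlimited, each individually
flanked), with `maxIntruders = 1` giving the per-clade reading. And no
re-rooting or ladderization is ever applied — the listing is taken exactly
as written, so that results are reproducible from the distributed tree files
alone.

```{r clades}
cfg <- legumeSpeciesConfig()
tr <- geneTreeFromPhylo(ape::read.tree(
  text = "((medtr.a,(vitvi.x,(glyma.b,(prupe.y,(vitvi.z,chafa.c))))));"),
  "demo")
length(detectLegumeClades(tr, cfg, mode = "permissive"))
length(detectLegumeClades(tr, cfg, mode = "strict"))
```

## Duplication typing

Every unordered same-species pair of a superfamily is classified with a
window of exactly 10^6 bp: *tandem* if on one chromosome, within the window,
and ordinally adjacent genome-wide; *proximal* if within the window but not
adjacent; *distal* otherwise. Three boundary decisions matter and are fixed
as follows. Distance is anchored at the difference of starts (not the
inter-gene gap and not midpoints): at megabase scale the choice is
immaterial, and starts are insensitive to annotation differences in gene
length. Adjacency is genome-wide — "immediately adjacent" means no
intervening annotated gene of any family — with `adjacency = "within-family"`
exposing the alternative where only the superfamily's own genes are ranked.
An ordinally adjacent pair farther than 1 Mb apart is distal, since tandem
is by definition a subdivision of the local (within-window) class.

Clade pairs are typed by positional support: for every species present in
both clades, any cross-clade same-chromosome pair within the window counts
as local support; one supporting species suffices for a *local* call (the
per-pair default), otherwise the pair is *segmental*. The ancient-local rule
uses its own threshold: a superfamily is flagged when at least six species
(any configured species with qualifying coordinates; in practice only legume
species can sit in strict clades) have within-window pairs spanning
different strict legume clades. Strict clades are used here because the
bounding by non-legume sequences is what certifies that the duplication
predates the legume/non-legume split. The threshold is monotone: raising
`minSpecies` can only switch the flag off.

## Expression bias and conservation categories

Per gene, tissue means over replicates are converted to relative expression
(each tissue's mean over the gene's total; NA when the total is zero). The
bias label is the top tissue when its mean is at least two-fold — inclusive,
≥ 2 — that of *each* other tissue, else neutral. The rule is scale-invariant,
so FPKM- and TMM-normalized inputs are treated identically and means versus
relative values give the same answer. The gene-level rule applies the same
fold margin as the superfamily rule (an `rule = "argmax"` variant preserves
plain highest-expression labelling); the superfamily label averages member
gene tissue means unweighted before applying the margin, so large recent
expansions are not double-counted by expression magnitude but are by copy
number — a deliberate, documented coarseness.

Conservation categories compare the PAP label multiset *P* (default
`medtr`, `glyma`, `phavu`) with the CAE label *c* (`chafa`): category 5 when
*c* is NA, any PAP label is NA, or everything is neutral; category 1/2 when
PAP labels are unanimous and non-neutral (1 if *c* matches, else 2);
otherwise 3 when *c* is non-neutral and matches at least one PAP label, else
4. Edge cases the category list leaves open — a unanimous *neutral* PAP
consensus with a biased CAE, NA handling — are resolved by the order of
these checks, and the mapping is total: every combination in the 5^4 label
space lands in exactly one category (this exhaustiveness is tested).

PCA summaries use one row per superfamily and 12 features (4 species × 3
tissues of superfamily-level relative expression), complete-case rows,
centered and unit-scaled columns, with constant columns dropped; variance
fractions come from the singular values. The feature construction is a
package choice — the superfamily level keeps rows comparable across species
with different copy numbers.

## Family-size statistics

Kruskal–Wallis (mid-ranks, standard tie correction, chi-squared reference
with k−1 degrees of freedom) via `stats::kruskal.test`; pairwise two-sided
Wilcoxon rank-sum tests via `stats::wilcox.test` with Benjamini–Hochberg
adjustment over all k(k−1)/2 p-values. The effect size uses the conventional
rank-based definition ε² = H(n+1)/(n²−1). Tests default to uncapped counts:
the 50-gene cap exists for display (`heatmapMatrix`), and applying it before
testing is an explicit flag-level choice left to the caller.

```{r stats}
kw <- kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
c(H = kw$H, eps2 = epsilonSquared(kw$H, 6))
```

## The simulator: what it emulates, and what it does not

`simulateFamily()` evolves a family down a fixed 18-taxon species tree whose
topology and group structure match the analysis panel. Events are logged so
that every downstream call can be scored: WGD copies land on a different
chromosome; tandem copies insert at the adjacent ordinal position; proximal
copies join the parent's cluster with 2–6 intervening background genes;
losses delete copies. Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| tandem / proximal rate | 0.04 / 0.02 per gene per branch | a few local events per mid-sized family, matching the prevalence of local duplicates in RNS superfamilies |
| loss rate | 0 | the loss-free regime is the recovery baseline; losses (e.g. 0.2) are a monitored regime |
| WGD nodes | fabids 0.4, papilionoideae 0.6, caesalpinioideae 0.4, glyma 0.8 | one pre-legume event (detectable as two permissive clades) plus the subfamily- and *Glycine*-level polyploidies of the panel |
| planted root tandem | probability 0.3, per-legume-species retention 0.7 | yields families on both sides of the six-species ancient-local threshold |
| gene spacing | U[20, 200] kb | tandem placements always fall within 1 Mb |
| cluster span cap / inter-cluster gap | < 0.95 Mb / > 1.3 Mb | the 1 Mb rule is exercised on both sides of the boundary by construction |

Branch lengths are event counts, not time; no component of the pipeline
reads them. The generator does *not* emulate: sequence evolution (trees are
emitted directly, so tree-inference error is out of scope), unequal
chromosome sizes or realistic gene density, correlated expression among
paralogs, dosage effects after WGD, or incomplete lineage sorting. Passing
recovery tests therefore demonstrates the correctness of the rules on data
satisfying their assumptions — not robustness to tree-estimation error or to
annotation noise in real genomes, where the flags (`adjacency`,
`maxIntruders`, `rule`) exist precisely to explore rule sensitivity.

Expression simulation plants a label and fold per gene: each replicate is
`base × fold^[tissue = label] × exp(N(0, σ))` with base log-uniform in
[1, 100]. Neutral genes have fold 1. Recovery of planted labels is monotone
non-increasing in σ and non-decreasing in fold.

## Numerical and testing choices

Relative expression sums to 1 within 1e-12 for genes with positive totals;
ties at the top tissue fall to neutral under any fold > 1 (the inclusive ≥
comparison only matters against *other* tissues). Wilcoxon exactness
follows `stats::wilcox.test` defaults (exact below 50 observations without
ties). The simulator derives one random substream per family index from the
global seed, so families are independently reproducible and byte-identical
across runs.

The test suite works at deliberately modest problem sizes — 200 random leaf
listings against a regular-expression clade oracle, 50 loss-free families
for duplication recovery, 1,000 genes for bias recovery, a 10,000 × 12
matrix for PCA isotropy — sizes at which Monte-Carlo error is negligible for
the asserted margins while the whole suite stays fast.

## Known limitations

Leaf-listing clades depend on the rooting and writing order of the input
Newick; trees rooted differently will enumerate different runs, which is
inherent to the listing-based operationalization rather than a defect.
Superfamily-level bias averaging can mask subfunctionalization among recent
duplicates — gene-level labels are emitted alongside for that reason. The
ancient-local rule counts species, not independent retention events, so a
single widely retained duplication and several convergent ones are not
distinguished. And the statistics module treats superfamilies as independent
observations, as the underlying comparative design does.
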