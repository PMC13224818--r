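#' Per-tissue expression profile of a gene
#'
#' Mean expression per tissue over that tissue's replicates, the standard
#' error of each mean, and the relative expression (each tissue's mean
#' divided by the gene's total expression across all tissues). Relative
#' values are NA for genes whose total expression is zero.
#'
#' @param expr a [TissueExpression-class].
#' @param gene gene id present in the matrix.
#' @return list with `gene`, `mean` (named by tissue), `se` and `rel`.
#' @export
tissueProfile <- function(expr, gene) {
  v <- expr@values
  if (!gene %in% rownames(v)) stop("gene '", gene, "' absent from matrix")
  x <- v[gene, ]
  tis <- expr@sampleTissue[names(x)]
  m <- vapply(TISSUES, function(t) mean(x[tis == t]), numeric(1))
  se <- vapply(TISSUES, function(t) {
    xs <- x[tis == t]
    if (length(xs) > 1L) stats::sd(xs) / sqrt(length(xs)) else NA_real_
  }, numeric(1))
  tot <- sum(m)
  rel <- if (is.na(tot) || tot <= 0) stats::setNames(rep(NA_real_, 3L), TISSUES)
         else m / tot
  list(gene = gene, mean = m, se = se, rel = rel)
}

.biasFromMeans <- function(m, fold = 2, rule = c("fold", "argmax")) {
  rule <- match.arg(rule)
  if (all(is.na(m)) || sum(m, na.rm = TRUE) <= 0) return(NA_character_)
  top <- which.max(m)
  others <- m[-top]
  if (rule == "argmax") return(names(m)[top])
  if (all(m[top] >= fold * others)) names(m)[top] else "neutral"
}

#' Two-fold tissue-bias label for a gene
#'
#' A gene is biased toward the tissue with its highest mean expression when
#' that mean is at least `fold` (default two-fold, inclusive) times the mean
#' of each other tissue; otherwise it is neutral. Genes without data (total
#' expression zero) are NA. The rule is scale-invariant, so means and
#' relative expression values give the same label. `rule = "argmax"`
#' preserves the plain highest-expression labelling without the fold margin.
#'
#' @param profile a profile from [tissueProfile()], or a named numeric vector
#'   of per-tissue means.
#' @param fold fold threshold (>= is inclusive); default 2.
#' @param rule `"fold"` (default) or `"argmax"`.
#' @return one of `"nodule"`, `"root"`, `"shoot"`, `"neutral"`, or NA.
#' @export
geneBias <- function(profile, fold = 2, rule = c("fold", "argmax")) {
  m <- if (is.list(profile)) profile$mean else profile
  .biasFromMeans(m, fold = fold, rule = rule)
}

#' Tissue-bias labels for every gene in a matrix
#'
#' @param expr a [TissueExpression-class].
#' @param fold,rule see [geneBias()].
#' @return named character vector of labels, one per gene.
#' @export
geneBiasTable <- function(expr, fold = 2, rule = c("fold", "argmax")) {
  rule <- match.arg(rule)
  v <- expr@values
  tis <- expr@sampleTissue[colnames(v)]
  means <- sapply(TISSUES, function(t)
    rowMeans(v[, tis == t, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(v), TISSUES))
  out <- apply(means, 1L, .biasFromMeans, fold = fold, rule = rule)
  stats::setNames(as.character(out), rownames(v))
}

#' Superfamily-level tissue-bias label
#'
#' Averages the per-tissue gene means over all member genes present in the
#' matrix (unweighted across genes), then applies the same inclusive
#' `fold`-threshold rule as [geneBias()]. NA when no member has data.
#'
#' @param expr a [TissueExpression-class].
#' @param members gene ids of the superfamily's members in this species.
#' @param fold fold threshold; default 2.
#' @return one of `"nodule"`, `"root"`, `"shoot"`, `"neutral"`, or NA.
#' @export
familyBias <- function(expr, members, fold = 2) {
  stopifnot(length(members) > 0L)
  v <- expr@values
  members <- intersect(members, rownames(v))
  if (!length(members)) return(NA_character_)
  tis <- expr@sampleTissue[colnames(v)]
  gm <- sapply(TISSUES, function(t)
    rowMeans(v[members, tis == t, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(members, TISSUES))
  fam <- colMeans(gm)
  .biasFromMeans(fam, fold = fold)
}

#' Per-tissue relative expression of a superfamily in one species
#'
#' Member-gene tissue means are averaged (unweighted) and converted to
#' proportions; used to build the cross-species feature matrix for
#' [pcaVariance()].
#'
#' @inheritParams familyBias
#' @return named numeric of length 3 (proportions summing to 1), or NAs.
#' @export
familyRelExpression <- function(expr, members) {
  v <- expr@values
  members <- intersect(members, rownames(v))
  if (!length(members)) return(stats::setNames(rep(NA_real_, 3L), TISSUES))
  tis <- expr@sampleTissue[colnames(v)]
  gm <- sapply(TISSUES, function(t)
    rowMeans(v[members, tis == t, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(members, TISSUES))
  fam <- colMeans(gm)
  tot <- sum(fam)
  if (is.na(tot) || tot <= 0) return(stats::setNames(rep(NA_real_, 3L), TISSUES))
  fam / tot
}

#' Cross-species conservation category of a superfamily's bias labels
#'
#' Superfamilies are placed in one of five categories from the bias labels of
#' the configured PAP species and the CAE reference species:
#' \enumerate{
#'   \item conserved across all species (all PAP labels equal, non-neutral,
#'     and equal to the CAE label);
#'   \item conserved within PAP but distinct from CAE;
#'   \item mixed within PAP, partially overlapping CAE (CAE non-neutral and
#'     matching at least one PAP label);
#'   \item mixed within PAP and distinct from CAE;
#'   \item insufficient or missing data, or all-neutral patterns.
#' }
#' Category 5 applies when the CAE label is NA, any PAP label is NA, or all
#' labels are neutral. Every label combination maps to exactly one category.
#'
#' @param labels named character vector of bias labels (values among
#'   nodule/root/shoot/neutral/NA), named by species code; must cover the
#'   configured PAP set and CAE code. Missing names are treated as NA with a
#'   warning.
#' @param config a [SpeciesConfig-class].
#' @return integer in 1..5.
#' @export
assignCategory <- function(labels, config) {
  need <- c(config@papSet, config@caeCode)
  missing <- setdiff(need, names(labels))
  if (length(missing)) {
    warning("missing bias label(s) for: ", paste(missing, collapse = ", "),
            "; treated as NA")
    labels[missing] <- NA_character_
  }
  P <- unname(labels[config@papSet])
  cae <- unname(labels[config@caeCode])
  if (is.na(cae) || anyNA(P)) return(5L)
  if (all(c(P, cae) == "neutral")) return(5L)
  if (length(unique(P)) == 1L && P[1L] != "neutral") {
    if (cae == P[1L]) return(1L) else return(2L)
  }
  if (cae != "neutral" && cae %in% P) return(3L)
  4L
}

#' Census of bias labels per species across superfamilies
#'
#' @param labels a data.frame or matrix of bias labels, superfamilies in rows
#'   and species in columns (NA allowed).
#' @return data.frame with one row per species and one column per label
#'   (nodule, root, shoot, neutral, NA); rows sum to the number of
#'   superfamilies.
#' @export
biasCensus <- function(labels) {
  labels <- as.matrix(labels)
  lev <- c(TISSUES, "neutral")
  out <- t(apply(labels, 2L, function(col) {
    c(table(factor(col, levels = lev)), "NA" = sum(is.na(col)))
  }))
  as.data.frame(out)
}

#' Variance fractions of a PCA on centered, scaled features
#'
#' Columns are centered to mean zero and scaled to unit variance; constant
#' columns (scale undefined) are dropped with a warning. Variance fractions
#' are computed from the singular values, in descending order.
#'
#' @param x numeric matrix or data.frame, observations x features (e.g.
#'   superfamilies x species-tissue relative-expression features). Rows with
#'   missing values are dropped (complete-case analysis).
#' @return numeric vector of variance fractions (non-negative, weakly
#'   decreasing, summing to <= 1, = 1 over full rank).
#' @export
pcaVariance <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant column(s)")
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  v <- p$sdev^2
  v / sum(v)
}

#' Cap a superfamily-by-species count matrix for display
#'
#' @param counts non-negative integer matrix (superfamilies x species).
#' @param cap upper limit; default 50.
#' @return the matrix with entries `min(count, cap)`, order preserved.
#' @export
heatmapMatrix <- function(counts, cap = 50L) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("negative count(s)")
  pmin(counts, cap)
}
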