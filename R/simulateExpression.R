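#' Planted expression truth for a set of genes
#'
#' Assigns each gene a planted tissue label and fold. Neutral genes have
#' fold 1 (no tissue is elevated); biased genes have the planted fold in
#' their labelled tissue.
#'
#' @param genes character vector of gene ids.
#' @param labels optional character vector of planted labels (among nodule /
#'   root / shoot / neutral); when NULL, labels are drawn uniformly over the
#'   three tissues with probability `1 - neutralFraction`, and neutral
#'   otherwise.
#' @param fold planted fold (>= 1) for biased genes.
#' @param sigma multiplicative log-normal noise (standard deviation on the
#'   natural-log scale), >= 0.
#' @param replicates replicates per tissue.
#' @param neutralFraction fraction of neutral genes when `labels` is NULL.
#' @return data.frame with columns `gene`, `label`, `fold`, `sigma`,
#'   `replicates`.
#' @export
expressionTruth <- function(genes, labels = NULL, fold = 4, sigma = 0.25,
                            replicates = 3L, neutralFraction = 0.25) {
  stopifnot(fold >= 1, sigma >= 0, replicates >= 1L)
  if (is.null(labels)) {
    labels <- ifelse(stats::runif(length(genes)) < neutralFraction,
                     "neutral", sample(TISSUES, length(genes),
                                       replace = TRUE))
  }
  stopifnot(length(labels) == length(genes),
            all(labels %in% c(TISSUES, "neutral")))
  data.frame(gene = genes, label = labels,
             fold = ifelse(labels == "neutral", 1, fold),
             sigma = sigma, replicates = as.integer(replicates),
             stringsAsFactors = FALSE)
}

#' Simulate an expression matrix with planted tissue biases
#'
#' Per replicate, the value for gene *g* in tissue *t* is
#' `base_g * fold_g^[t == label_g] * exp(N(0, sigma_g))`, with `base_g` drawn
#' log-uniformly in \\[1, 100\\]. The matrix is non-negative by construction.
#'
#' @param truth an [expressionTruth()] table.
#' @param seed integer seed fixing all randomness.
#' @param species species code recorded on the result.
#' @return a [TissueExpression-class] with `replicates` samples per tissue.
#' @export
simulateExpression <- function(truth, seed = 1L, species = NA_character_) {
  if (any(truth$sigma < 0)) stop("sigma must be >= 0")
  set.seed(seed)
  reps <- unique(truth$replicates)
  stopifnot(length(reps) == 1L)
  samples <- paste(rep(TISSUES, each = reps), seq_len(reps), sep = "_")
  tissueOf <- rep(TISSUES, each = reps)
  base <- 10^stats::runif(nrow(truth), 0, 2)
  vals <- matrix(0, nrow = nrow(truth), ncol = length(samples),
                 dimnames = list(truth$gene, samples))
  for (j in seq_along(samples)) {
    planted <- ifelse(truth$label == tissueOf[j], truth$fold, 1)
    vals[, j] <- base * planted *
      exp(stats::rnorm(nrow(truth), 0, truth$sigma))
  }
  tissueExpression(vals, stats::setNames(tissueOf, samples),
                   species = species)
}

#' Recovery metrics of pipeline calls against simulator truth
#'
#' Pair-level precision and recall of tandem and proximal calls against the
#' expected-pair table of [simulateFamily()] truth; an aggregate `local` row
#' pools both relations.
#'
#' @param truthPairs truth pair table (`gene_a`, `gene_b`, `relation`).
#' @param calledPairs output of [localParalogPairs()].
#' @return data.frame with columns `relation`, `n_truth`, `n_called`,
#'   `precision`, `recall` (NA when a denominator is empty).
#' @export
truthReport <- function(truthPairs, calledPairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  metrics <- function(truthKeys, calledKeys) {
    tp <- length(intersect(truthKeys, calledKeys))
    data.frame(
      n_truth = length(truthKeys), n_called = length(calledKeys),
      precision = if (length(calledKeys)) tp / length(calledKeys)
                  else NA_real_,
      recall = if (length(truthKeys)) tp / length(truthKeys) else NA_real_)
  }
  rows <- lapply(c("tandem", "proximal"), function(rel) {
    cbind(relation = rel, metrics(
      key(truthPairs$gene_a[truthPairs$relation == rel],
          truthPairs$gene_b[truthPairs$relation == rel]),
      key(calledPairs$gene_a[calledPairs$relation == rel],
          calledPairs$gene_b[calledPairs$relation == rel])))
  })
  locT <- truthPairs[truthPairs$relation %in% c("tandem", "proximal"), ]
  locC <- calledPairs[calledPairs$relation %in% c("tandem", "proximal"), ]
  rows[[3L]] <- cbind(relation = "local",
                      metrics(key(locT$gene_a, locT$gene_b),
                              key(locC$gene_a, locC$gene_b)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
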