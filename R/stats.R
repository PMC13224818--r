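#' Kruskal-Wallis test over per-species family-size distributions
#'
#' Thin wrapper over [stats::kruskal.test()] (mid-ranks with the standard tie
#' correction; p-value from the chi-squared distribution with k-1 degrees of
#' freedom), operating on a list of per-species count vectors.
#'
#' @param groups named list of numeric vectors (one per species,
#'   per-superfamily gene counts; zeros included), or a matrix/data.frame
#'   with one column per species.
#' @return list with `H` (statistic, chi-squared scale), `df` and `p`.
#' @export
kruskalWallis <- function(groups) {
  groups <- .asGroupList(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(!lengths(groups))) stop("empty group(s)")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

.asGroupList <- function(groups) {
  if (is.matrix(groups) || is.data.frame(groups)) {
    groups <- as.data.frame(groups)
    groups <- lapply(groups, as.numeric)
  }
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Rank-based epsilon-squared effect size for the Kruskal-Wallis test
#'
#' The conventional effect size reported alongside the Kruskal-Wallis
#' statistic: \eqn{\epsilon^2 = H (n + 1) / (n^2 - 1)} with `n` the total
#' number of observations.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n total number of observations (>= 2).
#' @return epsilon-squared in [0, 1].
#' @export
epsilonSquared <- function(H, n) {
  if (n < 2L) stop("n must be >= 2")
  H * (n + 1) / (n^2 - 1)
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided rank-sum tests (with tie handling as in
#' [stats::wilcox.test()]) for every unordered pair of species, with BH
#' adjustment applied over all k(k-1)/2 p-values.
#'
#' @inheritParams kruskalWallis
#' @return symmetric species-by-species matrix of BH-adjusted q-values with
#'   NA on the diagonal; the raw p-value matrix is attached as attribute
#'   `"p"`.
#' @export
pairwiseWilcoxonBH <- function(groups) {
  groups <- .asGroupList(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(!lengths(groups))) stop("empty group(s)")
  k <- length(groups)
  nm <- names(groups)
  idx <- utils::combn(k, 2L)
  p <- apply(idx, 2L, function(ab) {
    suppressWarnings(stats::wilcox.test(groups[[ab[1L]]], groups[[ab[2L]]],
                                        exact = NULL)$p.value)
  })
  q <- stats::p.adjust(p, method = "BH")
  qm <- pm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (j in seq_len(ncol(idx))) {
    a <- idx[1L, j]; b <- idx[2L, j]
    qm[a, b] <- qm[b, a] <- q[j]
    pm[a, b] <- pm[b, a] <- p[j]
  }
  attr(qm, "p") <- pm
  qm
}
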