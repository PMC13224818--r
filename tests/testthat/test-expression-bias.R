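mkExpr <- function(means, reps = 1L, species = "medtr") {
  # means: named list gene -> c(nodule, root, shoot)
  samples <- paste(rep(TISSUES <- c("nodule", "root", "shoot"), each = reps),
                   seq_len(reps), sep = "_")
  vals <- t(vapply(means, function(m) rep(m, each = reps),
                   numeric(3L * reps)))
  colnames(vals) <- samples
  tissueExpression(vals, stats::setNames(rep(TISSUES, each = reps), samples),
                   species = species)
}

test_that("tissue profiles give means, SEs and relative expression", {
  e <- mkExpr(list(g1 = c(10, 10, 10), g2 = c(6, 3, 1), g3 = c(0, 0, 0)))
  expect_equal(unname(tissueProfile(e, "g1")$rel), rep(1 / 3, 3))
  expect_equal(unname(tissueProfile(e, "g2")$rel), c(0.6, 0.3, 0.1))
  expect_true(all(is.na(tissueProfile(e, "g3")$rel)))
  expect_error(tissueProfile(e, "nope"), "absent")

  # rel sums to 1 whenever total is positive
  set.seed(1)
  e2 <- mkExpr(list(a = runif(3, 1, 9), b = runif(3, 1, 9)), reps = 3L)
  for (g in c("a", "b"))
    expect_equal(sum(tissueProfile(e2, g)$rel), 1, tolerance = 1e-12)
})

test_that("the two-fold rule labels genes, inclusively and scale-invariantly", {
  lab <- function(m) geneBias(stats::setNames(m, c("nodule", "root", "shoot")))
  expect_equal(lab(c(0.6, 0.3, 0.1)), "nodule")
  expect_equal(lab(c(0.5, 0.3, 0.2)), "neutral")
  expect_equal(lab(c(1, 1, 1) / 3), "neutral")
  expect_equal(lab(c(2, 1, 1)), "nodule")       # >= is inclusive
  expect_true(is.na(lab(c(0, 0, 0))))
  # invariant to uniform rescaling
  set.seed(2)
  for (i in 1:20) {
    m <- stats::setNames(runif(3, 0, 10), c("nodule", "root", "shoot"))
    expect_equal(geneBias(m), geneBias(m * runif(1, 0.01, 100)))
  }
  # fold = 1 returns the argmax except on exact ties
  expect_equal(geneBias(stats::setNames(c(3, 2, 1),
                                        c("nodule", "root", "shoot")),
                        fold = 1), "nodule")
  expect_equal(geneBias(stats::setNames(c(1, 2, 3),
                                        c("nodule", "root", "shoot")),
                        rule = "argmax"), "shoot")
})

test_that("superfamily bias averages gene means before the fold rule", {
  e <- mkExpr(list(g1 = c(8, 1, 1), g2 = c(0, 1, 1),
                   g3 = c(4, 1, 1), g4 = c(1, 4, 1)))
  expect_equal(familyBias(e, c("g1", "g2")), "nodule")   # means (4,1,1)
  expect_equal(familyBias(e, c("g3", "g4")), "neutral")  # means (2.5,2.5,1)
  expect_true(is.na(familyBias(e, "absent_gene")))
  rel <- familyRelExpression(e, c("g1", "g2"))
  expect_equal(unname(rel), c(4, 1, 1) / 6)
})

test_that("conservation categories follow the five-way definition", {
  lab <- function(pap, cae)
    assignCategory(stats::setNames(c(pap, cae),
                                   c("medtr", "glyma", "phavu", "chafa")),
                   CFG)
  expect_equal(lab(c("nodule", "nodule", "nodule"), "nodule"), 1L)
  expect_equal(lab(c("shoot", "shoot", "shoot"), "nodule"), 2L)
  expect_equal(lab(c("nodule", "shoot", "neutral"), "shoot"), 3L)
  expect_equal(lab(c("nodule", "shoot", "neutral"), "root"), 4L)
  expect_equal(lab(c("nodule", "nodule", "nodule"), NA), 5L)
  expect_equal(lab(c(NA, "nodule", "nodule"), "nodule"), 5L)
  expect_equal(lab(rep("neutral", 3), "neutral"), 5L)
  expect_warning(
    expect_equal(assignCategory(c(medtr = "nodule"), CFG), 5L),
    "missing bias label")
})

test_that("bias census counts labels per species", {
  labs <- data.frame(medtr = c("nodule", "neutral", NA),
                     chafa = c("shoot", "shoot", "root"))
  cen <- biasCensus(labs)
  expect_equal(cen["medtr", "nodule"], 1)
  expect_equal(cen["medtr", "NA"], 1)
  expect_equal(cen["chafa", "shoot"], 2)
  expect_equal(unname(rowSums(cen)), c(3, 3))
})

test_that("PCA variance fractions behave on degenerate and noisy input", {
  # rank-1 matrix: PC1 carries everything
  x <- outer(1:20, c(1, 2, 3, 4))
  v <- pcaVariance(x)
  expect_equal(v[1L], 1, tolerance = 1e-12)
  expect_true(all(diff(v) <= 1e-12))
  expect_lte(sum(v), 1 + 1e-12)
  expect_true(all(v >= -1e-12))
  # constant columns are dropped with a warning
  expect_warning(pcaVariance(cbind(x, 5)), "constant column")
})

test_that("count matrices are capped for display", {
  m <- matrix(c(878L, 12L, 0L, 50L), 2)
  expect_equal(as.vector(heatmapMatrix(m)), c(50L, 12L, 0L, 50L))
  expect_error(heatmapMatrix(matrix(-1L)), "negative")
})

test_that("noise-free planted biases are recovered exactly", {
  set.seed(10)
  truth <- expressionTruth(paste0("g", 1:200), fold = 4, sigma = 0,
                           replicates = 3L)
  expr <- simulateExpression(truth, seed = 99L)
  labels <- geneBiasTable(expr)
  expect_equal(unname(labels[truth$gene]), truth$label)
})
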