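# Differential expression: log2 guard, moderated/plain t, BH behavior,
# the fold-change/adjusted-p screen, intersection and merge.

makeDs <- function(values, group) {
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  expressionDataset(values, group)
}

test_that("log2 guard takes the right branch and rejects negatives", {
  m <- matrix(c(15.2, 3.1, 8.8, 10.0), 2, 2)
  expect_identical(attr(normalizeLog2(m), "log2_branch"), "passthrough")
  expect_equal(normalizeLog2(m)[1, 1], 15.2)
  lin <- matrix(c(1023, 0, 511, 3), 2, 2)
  out <- normalizeLog2(lin)
  expect_identical(attr(out, "log2_branch"), "transformed")
  expect_equal(out[1, 1], 10.0)
  lin[2, 1] <- -1
  expect_error(normalizeLog2(lin), "negative")
})

test_that("duplicate gene IDs collapse to the highest-mean probe", {
  m <- rbind(a = c(1, 1), b = c(5, 5), a2 = c(9, 9))
  rownames(m) <- c("gA", "gB", "gA")
  out <- collapseDuplicateGenes(m)
  expect_equal(sort(rownames(out)), c("gA", "gB"))
  expect_equal(unname(out["gA", 1]), 9)
})

test_that("log2fc is the exact difference of group means", {
  m <- rbind(c(10, 10, 10, 8, 8, 8),
             c(5, 6, 7, 5, 6, 7))
  ds <- makeDs(m, rep(c("case", "control"), each = 3))
  de <- differentialExpression(ds, varMethod = "none")
  expect_equal(de$log2fc[1], 2.0)
  expect_identical(de$regulation[1], "Up")
  expect_equal(de$log2fc[2], 0.0)
})

test_that("swapping group labels negates log2fc and keeps p", {
  sim <- genExpression(synthConfig(nGenes = 60L, nDE = 6L, seed = 11L))
  ds <- sim$dataset
  swapped <- expressionDataset(
    exprValues(ds),
    ifelse(sampleGroups(ds) == "case", "control", "case"))
  a <- differentialExpression(ds)
  b <- differentialExpression(swapped)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p, a$p)
})

test_that("a group with fewer than 2 samples is refused by name", {
  m <- matrix(rnorm(12), 3, 4)
  ds <- makeDs(m, c("case", "case", "case", "control"))
  expect_error(differentialExpression(ds), "control")
})

test_that("zero-variance genes are handled without NaN", {
  m <- rbind(c(5, 5, 5, 5, 5, 5),       # flat, lfc = 0
             c(9, 9, 9, 4, 4, 4),       # flat, lfc != 0
             matrix(rnorm(5 * 6), 5, 6))
  ds <- makeDs(m, rep(c("case", "control"), each = 3))
  for (vm in c("eb", "floor", "none")) {
    de <- differentialExpression(ds, varMethod = vm)
    expect_false(any(is.nan(de$p)), info = vm)
    expect_equal(de$p[1], 1)
    expect_lt(de$p[2], 0.05)
  }
})

test_that("moderated t agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sim <- genExpression(synthConfig(nGenes = 300L, nDE = 20L, seed = 5L))
  m <- exprValues(sim$dataset); grp <- sampleGroups(sim$dataset)
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, grp == "case")))
  mine <- differentialExpression(sim$dataset, varMethod = "eb")
  expect_equal(mine$t_stat, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
  expect_equal(attr(mine, "df_prior"), fit$df.prior, tolerance = 1e-6)
})

test_that("plain t matches per-gene t.test as an oracle", {
  sim <- genExpression(synthConfig(nGenes = 25L, nDE = 3L, seed = 9L))
  m <- exprValues(sim$dataset); grp <- sampleGroups(sim$dataset)
  de <- differentialExpression(sim$dataset, varMethod = "none")
  ps <- apply(m, 1, function(x)
    t.test(x[grp == "case"], x[grp == "control"],
           var.equal = TRUE)$p.value)
  expect_equal(de$p, unname(ps), tolerance = 1e-12)
})

test_that("BH adjustment satisfies its defining invariants", {
  sim <- genExpression(synthConfig(nGenes = 200L, nDE = 10L, seed = 13L))
  de <- differentialExpression(sim$dataset)
  expect_true(all(de$p_adj >= de$p - 1e-15))
  expect_true(all(de$p_adj <= 1))
  ord <- order(de$p)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
  one <- de[1, ]
  expect_equal(p.adjust(one$p, "BH"), one$p)
})

test_that("the DEG screen enforces the quoted boundary semantics", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 2.0, -1.6, -1.6),
                    t_stat = 0, p = 0.01,
                    p_adj = c(0.01, 0.05, 0.2, 0.05),
                    regulation = c("Up", "Up", "Down", "Down"))
  out <- applyDegFilter(rec)
  expect_false("a" %in% out$genes)   # log2fc exactly 1.5: strict >
  expect_true("b" %in% out$genes)    # p_adj exactly 0.05: inclusive
  expect_false("c" %in% out$genes)   # p_adj 0.2
  expect_true("d" %in% out$genes)
  expect_equal(out$nUp, 1L)
  expect_equal(out$nDown, 1L)
  again <- applyDegFilter(out$table)
  expect_setequal(again$genes, out$genes)        # idempotent
  perm <- applyDegFilter(rec[sample(nrow(rec)), ])
  expect_setequal(perm$genes, out$genes)         # order-independent
})

test_that("intersection and merge follow set semantics with provenance", {
  m1 <- matrix(rnorm(5 * 4), 5, 4,
               dimnames = list(c("A", "B", "C", "D", "E"), paste0("x", 1:4)))
  m2 <- matrix(rnorm(5 * 4), 5, 4,
               dimnames = list(c("A", "B", "C", "D", "E"), paste0("y", 1:4)))
  d1 <- expressionDataset(m1, c("case", "case", "control", "control"))
  d2 <- expressionDataset(m2, c("case", "case", "control", "control"))
  out <- intersectAndMerge(list(c("A", "B", "C"), c("B", "C", "D")),
                           list(d1, d2))
  expect_identical(out$intersection, c("B", "C"))
  expect_setequal(out$union, c("A", "B", "C", "D"))
  expect_equal(ncol(exprValues(out$merged)), 8)
  expect_setequal(rownames(exprValues(out$merged)), out$union)
  prov <- SummarizedExperiment::colData(out$merged)$dataset
  expect_identical(as.integer(table(prov)[c("ds1", "ds2")]),
                   c(4L, 4L))
  ident <- intersectAndMerge(list(c("A", "B"), c("A", "B")), list(d1, d2))
  expect_identical(ident$intersection, ident$union)
  disj <- intersectAndMerge(list("A", "B"), list(d1, d2))
  expect_length(disj$intersection, 0)
  expect_setequal(disj$union, c("A", "B"))
})
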