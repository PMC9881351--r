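# ROC/AUC and Kaplan-Meier + log-rank.

trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

test_that("AUC handles separation, ties, and mixed ordering", {
  expect_equal(rocAuc(c(3, 4, 1, 2),
                      c("case", "case", "control", "control"))$auc, 1.0)
  expect_equal(rocAuc(rep(5, 6),
                      rep(c("case", "control"), 3))$auc, 0.5)
  # cases {2,3} vs controls {1,4}: wins (2,1) and (3,1), losses (2,4) and
  # (3,4) -> 2 of 4 pairs
  expect_equal(rocAuc(c(2, 3, 1, 4),
                      c("case", "case", "control", "control"))$auc, 0.5)
  expect_equal(bruteAuc(c(2, 3, 1, 4),
                        c("case", "case", "control", "control")), 0.5)
  expect_error(rocAuc(1:4, rep("case", 4)), "both classes")
})

test_that("AUC equals all-pairs counting on random data", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE)   # force ties
    labels <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAuc(scores, labels)$auc, bruteAuc(scores, labels))
  }
})

test_that("the trapezoidal area of the curve equals the rank AUC", {
  set.seed(11)
  scores <- c(rnorm(15, 1), rnorm(15))
  labels <- rep(c("case", "control"), each = 15)
  r <- rocAuc(scores, labels)
  expect_equal(trapezoid(r$curve), r$auc, tolerance = 1e-12)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("label swap and monotone transforms behave as invariants", {
  set.seed(3)
  scores <- rnorm(30)
  labels <- rep(c("case", "control"), 15)
  a <- rocAuc(scores, labels)$auc
  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(rocAuc(scores, swapped)$auc, 1 - a)
  expect_equal(rocAuc(exp(scores), labels)$auc, a)
  expect_equal(rocAuc(scores, labels, direction = "low")$auc, 1 - a)
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(40)
  labels <- rep(c("case", "control"), 20)
  mine <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("KM with no censoring equals the empirical survival function", {
  time <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- kmEstimate(time, rep(1L, 8))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(time > km$time[i]))
})

test_that("KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 60
  time <- round(rexp(n, 0.05), 2) + 0.01
  event <- rbinom(n, 1, 0.8)
  expr <- setNames(rnorm(n), paste0("s", 1:n))
  surv <- data.frame(sample = names(expr), time = time, event = event)
  mine <- kmLogrank(expr, surv)
  grp <- factor(mine$groups[surv$sample])
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(mine$chi2, ref$chisq, tolerance = 1e-9)
  expect_equal(mine$p, 1 - pchisq(ref$chisq, 1), tolerance = 1e-9)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = surv[grp == "high", ])
  km <- mine$curves$high
  ref_s <- summary(fit, times = km$time)$surv
  expect_equal(km$survival, ref_s, tolerance = 1e-9)
})

test_that("identical survival in both groups gives chi2 0 and p 1", {
  expr <- setNames(1:8, paste0("s", 1:8))       # split: 5-8 high
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = c(1, 2, 3, 4, 1, 2, 3, 4),
                     event = 1L)
  r <- kmLogrank(expr, surv)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
})

test_that("uniformly earlier events put the high curve below the low one", {
  expr <- setNames(c(1, 2, 3, 4, 10, 11, 12, 13), paste0("s", 1:8))
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = c(20, 21, 22, 23, 1, 2, 3, 4),
                     event = 1L)
  r <- kmLogrank(expr, surv)
  hi <- r$curves$high; lo <- r$curves$low
  for (t in hi$time) {
    sHi <- min(hi$survival[hi$time <= t])
    sLo <- c(1, lo$survival)[sum(lo$time <= t) + 1]
    expect_lte(sHi, sLo)
  }
})

test_that("samples exactly at the median fall in the low group", {
  expr <- setNames(c(1, 2, 2, 3, 4), paste0("s", 1:5))  # median 2
  surv <- data.frame(sample = paste0("s", 1:5),
                     time = 1:5, event = 1L)
  r <- kmLogrank(expr, surv)
  expect_identical(unname(r$groups[c("s2", "s3")]), c("low", "low"))
  expect_equal(r$nLow, 3)
  expect_error(kmLogrank(setNames(rep(1, 5), paste0("s", 1:5)), surv),
               "degenerate")
})

test_that("log-rank p is symmetric under group relabeling", {
  set.seed(12)
  expr <- setNames(rnorm(30), paste0("s", 1:30))
  surv <- data.frame(sample = paste0("s", 1:30),
                     time = rexp(30, 0.1) + 0.01,
                     event = rbinom(30, 1, 0.7))
  a <- kmLogrank(expr, surv)
  b <- kmLogrank(-expr, surv)     # flips high/low membership (no ties)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("an expression-linked hazard is detected in most simulations", {
  rejections <- vapply(1:12, function(s) {
    cfg <- synthConfig(nGenes = 5L, nDE = 0L, nSpecific = 0L,
                       nCase = 200L, nControl = 2L, hazardBeta = 1.5,
                       censorRate = 0.2, seed = s)
    sim <- genExpression(cfg)
    surv <- genSurvival(cfg, sim$dataset, "gene_0001")
    expr <- exprValues(sim$dataset)["gene_0001", surv$sample]
    kmLogrank(expr, surv)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
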