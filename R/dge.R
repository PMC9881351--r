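# Differential expression: log2 guard, per-gene pooled-variance t-test with
# Benjamini-Hochberg adjustment, the fold-change/adjusted-p screen, and
# cross-dataset intersection + merge.

#' Guard a matrix onto the log2 scale
#'
#' Heuristic shared by microarray pipelines: a matrix whose maximum exceeds
#' 50 is taken to be linear-scale and transformed with `log2(x + 1)`;
#' anything else passes through untouched.  The branch taken is recorded in
#' the `"log2_branch"` attribute (`"transformed"` or `"passthrough"`).
#'
#' @param values numeric matrix.
#' @return the (possibly transformed) matrix with attribute `log2_branch`.
#' @examples
#' attr(normalizeLog2(matrix(1023, 1, 1)), "log2_branch")
#' @export
normalizeLog2 <- function(values) {
  values <- as.matrix(values)
  if (max(values) > 50) {
    if (any(values < 0))
      stop("negative values in a linear-scale matrix; cannot log2-transform")
    out <- log2(values + 1)
    attr(out, "log2_branch") <- "transformed"
  } else {
    out <- values
    attr(out, "log2_branch") <- "passthrough"
  }
  out
}

#' Collapse duplicate gene IDs to the highest-mean probe
#'
#' @param values matrix with (possibly duplicated) gene rownames.
#' @return matrix with unique rownames; for each duplicated ID the row with
#'   the highest mean expression is kept.
#' @export
collapseDuplicateGenes <- function(values) {
  values <- as.matrix(values)
  if (!anyDuplicated(rownames(values))) return(values)
  means <- rowMeans(values)
  ord <- order(rownames(values), -means)
  values <- values[ord, , drop = FALSE]
  values[!duplicated(rownames(values)), , drop = FALSE]
}

# invert the trigamma function by Newton iteration (for the moment fit of
# the variance prior); trigamma is convex decreasing so this converges fast
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# empirical-Bayes moderation of per-gene variances: fit a scaled inverse
# chi-square prior (d0, s0^2) to the observed log-variances by the method
# of moments and return the posterior variances and the prior df
.moderateVariances <- function(sp2, df) {
  if (length(sp2) < 2) return(list(post = sp2, dfPrior = 0))
  med <- median(sp2)
  if (med == 0) return(list(post = sp2, dfPrior = 0))
  x <- pmax(sp2, 1e-5 * med)     # offset exact zeros away from log(0)
  e <- log(x) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond chi-square sampling noise: variances are
    # exchangeable, the prior is degenerate at the common mean
    return(list(post = rep(mean(x), length(sp2)), dfPrior = Inf))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(post = (d0 * s02 + df * x) / (d0 + df), dfPrior = d0)
}

#' Per-gene two-sample differential expression
#'
#' A per-gene linear-model t-test with pooled variance.  By default the
#' per-gene variances are moderated empirical-Bayes style: a scaled
#' inverse chi-square prior is fitted to all pooled variances by the
#' method of moments (trigamma inversion of the log-variance spread) and
#' each gene's variance is shrunk toward the prior, with the t-test run on
#' `d0 + d` degrees of freedom.  This borrows strength across genes at the
#' tiny sample sizes the screen is designed for and removes zero-variance
#' pathologies.  Alternatives: `"floor"` (ordinary t with the 5th-percentile
#' pooled-variance floor) and `"none"` (exact ordinary t).  Adjusted
#' p-values are Benjamini-Hochberg over all genes.  `log2fc` is
#' mean(case) - mean(control) on the log2 scale; regulation is `Up` iff
#' `log2fc > 0`.
#'
#' @param ds an [ExpressionDataset-class] with >= 2 samples per group.
#' @param varMethod `"eb"` (default, moderated t), `"floor"` or `"none"`.
#' @return data.frame(gene, log2fc, t_stat, p, p_adj, regulation), one row
#'   per gene in input order; prior df in attribute `"df_prior"` for
#'   `"eb"`.
#' @examples
#' sim <- genExpression(synthConfig(nGenes = 50, nDE = 5, seed = 1))
#' head(differentialExpression(sim$dataset))
#' @export
differentialExpression <- function(ds, varMethod = c("eb", "floor", "none")) {
  stopifnot(is(ds, "ExpressionDataset"))
  varMethod <- match.arg(varMethod)
  m <- exprValues(ds)
  grp <- sampleGroups(ds)
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2L) stop("group 'case' has fewer than 2 samples")
  if (n2 < 2L) stop("group 'control' has fewer than 2 samples")
  mc <- m[, grp == "case", drop = FALSE]
  mk <- m[, grp == "control", drop = FALSE]
  mean1 <- rowMeans(mc); mean2 <- rowMeans(mk)
  v1 <- apply(mc, 1, var); v2 <- apply(mk, 1, var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  dfPrior <- 0
  if (varMethod == "eb") {
    mod <- .moderateVariances(sp2, df)
    sp2 <- mod$post
    dfPrior <- mod$dfPrior
  } else if (varMethod == "floor") {
    sp2 <- pmax(sp2, quantile(sp2, 0.05, names = FALSE))
  }
  # total df for the moderated t, capped at the summed residual df so an
  # infinite prior cannot claim more information than the data hold
  dfTotal <- min(df + dfPrior, nrow(m) * df)
  lfc <- mean1 - mean2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * pt(-abs(tt), df = dfTotal)
  p[se == 0 & lfc == 0] <- 1
  res <- data.frame(gene = rownames(m), log2fc = lfc, t_stat = tt, p = p,
                    p_adj = p.adjust(p, "BH"),
                    regulation = ifelse(lfc > 0, "Up", "Down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "df_prior") <- dfPrior
  res
}

#' @importFrom stats var
NULL

#' Screen differential-expression records
#'
#' A gene is kept iff `log2fc > lfcThreshold` or `log2fc < -lfcThreshold`
#' (strict) and `p_adj <= alpha` (inclusive) — the conventional
#' fold-change/adjusted-p screen with its quoted boundary semantics.
#'
#' @param records data.frame from [differentialExpression()].
#' @param lfcThreshold positive log2 fold-change threshold (default 1.5).
#' @param alpha adjusted-p ceiling (default 0.05).
#' @return list with `genes` (kept gene IDs), `table` (kept records),
#'   `nUp`, `nDown`.
#' @export
applyDegFilter <- function(records, lfcThreshold = 1.5, alpha = 0.05) {
  stopifnot(nrow(records) > 0, lfcThreshold > 0, alpha > 0, alpha < 1)
  keep <- (records$log2fc > lfcThreshold | records$log2fc < -lfcThreshold) &
    records$p_adj <= alpha
  kept <- records[keep, , drop = FALSE]
  list(genes = kept$gene, table = kept,
       nUp = sum(kept$regulation == "Up"),
       nDown = sum(kept$regulation == "Down"))
}

#' Intersect DEG sets and merge datasets over the DEG union
#'
#' @param degSets list (length >= 2) of character vectors of DEG IDs.
#' @param datasets list of [ExpressionDataset-class] objects, parallel to
#'   `degSets`.
#' @return list with `intersection` (genes DE in every set), `union`, and
#'   `merged` (an `ExpressionDataset` over the union genes present in all
#'   datasets, samples concatenated with dataset provenance in colData).
#' @export
intersectAndMerge <- function(degSets, datasets) {
  stopifnot(length(degSets) >= 2L, length(degSets) == length(datasets))
  inter <- sort(Reduce(intersect, degSets))
  uni <- sort(Reduce(union, degSets))
  if (!length(uni)) stop("union of DEG sets is empty; nothing to merge")
  common <- Reduce(intersect, lapply(datasets, function(d)
    rownames(exprValues(d))))
  genes <- intersect(uni, common)
  mats <- list(); groups <- character(); prov <- character()
  for (i in seq_along(datasets)) {
    m <- exprValues(datasets[[i]])[genes, , drop = FALSE]
    colnames(m) <- paste0("ds", i, ".", colnames(m))
    mats[[i]] <- m
    groups <- c(groups, unname(sampleGroups(datasets[[i]])))
    prov <- c(prov, rep(paste0("ds", i), ncol(m)))
  }
  merged <- expressionDataset(do.call(cbind, mats), groups, dataset = prov)
  list(intersection = inter, union = uni, merged = merged)
}
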