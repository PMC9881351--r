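# Case-control SNP association from genotype counts: allele tables with
# formatted frequencies, the minor-allele frequency ratio with a Katz
# log-scale CI (the statistic printed as "OR" in the source design, with the
# classical odds ratio reported alongside), the Pearson allele chi-square,
# and dominant-model (carrier) tests.

.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Allele counts and frequencies from a genotype table
#'
#' Minor-allele count = 2*mm + Mm, major = 2*MM + Mm per group; frequencies
#' are counts over 2n, formatted as percentages to one decimal place
#' (round half up).
#'
#' @param table a [GenotypeTable-class].
#' @return list with `counts` (2x2 matrix, rows case/control, cols
#'   minor/major), `frequencies` (proportions), `percent` (formatted),
#'   and `degenerate` (`TRUE` when either group has zero minor alleles).
#' @examples
#' tab <- genotypeTable("rs463946", c("G", "C"), c(2, 11, 17), c(1, 3, 26))
#' alleleCounts(tab)$percent
#' @export
alleleCounts <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  cts <- table@counts
  minor <- 2 * cts[, "mm"] + cts[, "Mm"]
  major <- 2 * cts[, "MM"] + cts[, "Mm"]
  m <- cbind(minor = minor, major = major)
  tot <- rowSums(m)
  freq <- m / tot
  list(counts = m, frequencies = freq,
       percent = .roundHalfUp(100 * freq, 1),
       degenerate = any(minor == 0))
}

#' Allele-frequency ratio with Katz confidence interval
#'
#' The ratio of minor-allele frequencies, cases over controls, with the
#' log-scale (Katz) CI
#' `exp(log r +/- z * sqrt(1/a - 1/n1 + 1/c - 1/n2))` over allele totals.
#' The complementary major-allele ratio is reported the same way, and the
#' classical cross-product odds ratio with a Woolf CI is included,
#' labelled, for comparison.  Zero minor alleles in either group flag the
#' result degenerate; no continuity correction is applied silently.
#'
#' @param table a [GenotypeTable-class], or a 2x2 allele count matrix as
#'   returned in `alleleCounts(...)$counts`.
#' @param level confidence level (default 0.95).
#' @return data.frame with rows `minor` and `major`: ratio, ci_low,
#'   ci_high, plus attributes `oddsRatio` (list estimate/ci) and
#'   `degenerate`.
#' @examples
#' tab <- genotypeTable("rs463946", c("G", "C"), c(2, 11, 17), c(1, 3, 26))
#' alleleRatioCi(tab)     # 3.000 (1.164-7.732); major 0.818 (0.694-0.965)
#' @export
alleleRatioCi <- function(table, level = 0.95) {
  m <- if (is(table, "GenotypeTable")) alleleCounts(table)$counts
       else as.matrix(table)
  z <- qnorm(1 - (1 - level) / 2)
  n1 <- sum(m["case", ]); n2 <- sum(m["control", ])
  one <- function(a, c) {
    if (a == 0 || c == 0)
      return(c(ratio = if (c == 0) Inf else 0, ci_low = NA, ci_high = NA))
    r <- (a / n1) / (c / n2)
    se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n2)
    c(ratio = r, ci_low = exp(log(r) - z * se),
      ci_high = exp(log(r) + z * se))
  }
  res <- rbind(minor = one(m["case", "minor"], m["control", "minor"]),
               major = one(m["case", "major"], m["control", "major"]))
  out <- as.data.frame(res)
  degenerate <- m["case", "minor"] == 0 || m["control", "minor"] == 0
  # classical cross-product OR with Woolf CI, for transparency
  a <- m["case", "minor"]; b <- m["case", "major"]
  c_ <- m["control", "minor"]; d <- m["control", "major"]
  or <- if (min(a, b, c_, d) > 0) {
    est <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    list(estimate = est, ci = exp(log(est) + c(-1, 1) * z * se))
  } else list(estimate = NA_real_, ci = c(NA_real_, NA_real_))
  attr(out, "oddsRatio") <- or
  attr(out, "degenerate") <- degenerate
  out
}

#' Pearson chi-square on the 2x2 allele table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param table a [GenotypeTable-class] or 2x2 allele count matrix.
#' @return list with `chi2` and `p`.
#' @export
alleleChi2 <- function(table) {
  m <- if (is(table, "GenotypeTable")) alleleCounts(table)$counts
       else as.matrix(table)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  if (any(c(a + b, c_ + d, a + c_, b + d) == 0))
    stop("zero margin in the allele table")
  N <- a + b + c_ + d
  chi2 <- N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Dominant-model (minor-allele carrier) tests
#'
#' Carriers (mm + Mm) versus non-carriers (MM) in a 2x2 against group.
#' The headline p is the two-sided Fisher exact test (sum of hypergeometric
#' masses no larger than the observed table's); Pearson chi-square with and
#' without Yates continuity correction are reported alongside, since
#' genotype-level p-values in the literature rarely state their test.
#'
#' @param table a [GenotypeTable-class].
#' @return list with `p` (Fisher), `chi2P`, `chi2YatesP`, `model`
#'   description and the 2x2 `carriers` table.
#' @export
dominantTest <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  cts <- table@counts
  m <- cbind(carrier = cts[, "mm"] + cts[, "Mm"], noncarrier = cts[, "MM"])
  fisher <- fisher.test(m)$p.value
  chi2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  yates <- suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
  list(p = fisher, chi2P = chi2, chi2YatesP = yates,
       model = "dominant: minor-allele carriers (mm + Mm) vs MM",
       carriers = m)
}

#' Full association summary for one SNP
#'
#' Bundles genotype counts, the dominant-model tests, the 2x3 genotype
#' chi-square, allele counts with formatted frequencies, the allele
#' chi-square, and both allele-frequency ratios with Katz CIs (plus the
#' classical odds ratio) into one record shaped like a per-SNP results
#' table row.
#'
#' @param table a [GenotypeTable-class].
#' @return named list of the components above.
#' @export
snpAssociation <- function(table) {
  ac <- alleleCounts(table)
  ratios <- alleleRatioCi(table)
  geno2x3 <- suppressWarnings(stats::chisq.test(table@counts,
                                                correct = FALSE)$p.value)
  list(snp = table@snp, alleles = table@alleles,
       genotypes = table@counts,
       genotype2x3P = geno2x3,
       dominant = dominantTest(table),
       alleleCounts = ac$counts, allelePercent = ac$percent,
       allele = alleleChi2(table),
       ratios = ratios,
       oddsRatio = attr(ratios, "oddsRatio"),
       degenerate = ac$degenerate)
}

#' Aggregate per-subject genotype calls into a [GenotypeTable-class]
#'
#' @param subjects data.frame(subject, group, snp, genotype) with genotype
#'   strings like `"CG"`; group in case/control.
#' @param snp SNP to aggregate (default: the single SNP present).
#' @param minorAllele optional override; by default the allele with the
#'   lower pooled frequency is minor.
#' @return a `GenotypeTable`.
#' @export
aggregateGenotypes <- function(subjects, snp = NULL, minorAllele = NULL) {
  if (is.null(snp)) {
    snp <- unique(subjects$snp)
    stopifnot(length(snp) == 1L)
  }
  sub <- subjects[subjects$snp == snp, , drop = FALSE]
  alleles <- sort(unique(unlist(strsplit(sub$genotype, ""))))
  if (length(alleles) > 2L)
    stop("more than two allele symbols for ", snp, ": ",
         paste(alleles, collapse = ", "))
  if (length(alleles) == 1L) alleles <- c(alleles, alleles)
  pooled <- table(factor(unlist(strsplit(sub$genotype, "")),
                         levels = alleles))
  minor <- if (!is.null(minorAllele)) minorAllele
           else names(pooled)[which.min(pooled)]
  major <- setdiff(alleles, minor)
  if (!length(major)) major <- minor
  countGeno <- function(g) {
    nm <- vapply(strsplit(g, ""), function(x) sum(x == minor), integer(1))
    c(mm = sum(nm == 2), Mm = sum(nm == 1), MM = sum(nm == 0))
  }
  genotypeTable(snp, c(minor, major),
                countGeno(sub$genotype[sub$group == "case"]),
                countGeno(sub$genotype[sub$group == "control"]))
}
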