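# Gene-set enrichment: hypergeometric over-representation and a pre-ranked
# weighted running-sum statistic with a gene-permutation null.  Collections
# are interchange via GMT; sets are intersected with the analysis universe
# and size-filtered before testing.

#' Read a GMT gene-set file
#'
#' @param path tab-separated GMT file: set name, description, then member
#'   genes.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1)), path)
}

#' Hypergeometric over-representation analysis
#'
#' Each set is intersected with the universe and kept when its size lies in
#' `[minSize, maxSize]`; the one-sided upper-tail hypergeometric p-value of
#' the query/set overlap is computed per set and Benjamini-Hochberg adjusted
#' across tested sets.
#'
#' @param genes query gene set (must be contained in `universe`).
#' @param universe background gene identifiers.
#' @param collection named list of gene sets (e.g. from [readGmt()]).
#' @param minSize,maxSize set-size bounds after universe intersection
#'   (defaults 5 and 5000).
#' @return data.frame(set_name, set_size, overlap, p, q) for tested sets,
#'   sorted by p; skipped sets are recorded in the `"skipped"` attribute.
#' @examples
#' u <- paste0("g", 1:10)
#' ora(u[1:5], u, list(S = u[1:5]), minSize = 1)   # p = 1/choose(10, 5)
#' @export
ora <- function(genes, universe, collection, minSize = 5, maxSize = 5000) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("query genes must be a subset of the universe")
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  keep <- sizes >= minSize & sizes <= maxSize
  skipped <- names(collection)[!keep]
  sets <- sets[keep]
  N <- length(universe); nq <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    ov <- length(intersect(genes, sets[[nm]]))
    p <- phyper(ov - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_name = character(), set_size = integer(),
               overlap = integer(), p = numeric())
  res$q <- p.adjust(res$p, "BH")
  res <- res[order(res$p, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

.runningSumES <- function(isHit, weights, weight) {
  nh <- sum(isHit)
  n <- length(isHit)
  if (nh == 0 || nh == n)
    stop("gene set must hit a strict, non-empty subset of the ranked list")
  wAbs <- abs(weights)^weight
  hitW <- ifelse(isHit, wAbs, 0)
  denom <- sum(hitW)
  if (denom == 0) {               # all-zero hit scores at weight > 0
    hitW <- as.numeric(isHit)
    denom <- nh
  }
  steps <- hitW / denom - (!isHit) / (n - nh)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene-set enrichment with a gene-permutation null
#'
#' The weighted Kolmogorov-Smirnov running sum: walking the ranked list,
#' hits increment by |score|^weight (normalized to total 1), misses
#' decrement by 1/(N - Nh); ES is the most extreme deviation.  The null is
#' built by permuting which positions are hits (`nPerm` draws); NES divides
#' ES by the mean |null ES| of matching sign and the permutation p uses
#' same-sign nulls, with the +1 correction.
#'
#' @param ranked named numeric vector of per-gene scores, sorted or not
#'   (sorted internally, decreasing); names are unique gene IDs.
#' @param set character gene set; must intersect the ranked list strictly.
#' @param weight exponent on |score| for hit increments (default 1; 0 gives
#'   the classical unweighted statistic).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return list with `es`, `nes`, `p`, `fdr` (equal to `p` for a single
#'   set), `leadingEdge` (genes at or before the ES extremum) and `nPerm`.
#' @export
gseaPreranked <- function(ranked, set, weight = 1, nPerm = 1000, seed = 1) {
  if (anyDuplicated(names(ranked))) stop("ranked list has duplicate genes")
  ranked <- sort(ranked, decreasing = TRUE)
  genes <- names(ranked)
  isHit <- genes %in% set
  if (!any(isHit)) stop("gene set does not intersect the ranked list")
  es <- .runningSumES(isHit, ranked, weight)
  # leading edge: hits at or before the running-sum extremum
  nh <- sum(isHit); n <- length(isHit)
  wAbs <- abs(ranked)^weight
  hitW <- ifelse(isHit, wAbs, 0)
  denom <- if (sum(hitW) > 0) sum(hitW) else nh
  steps <- (if (sum(hitW) > 0) hitW / denom else as.numeric(isHit) / nh) -
    (!isHit) / (n - nh)
  rs <- cumsum(steps)
  peak <- which.max(abs(rs))
  leading <- if (es >= 0) genes[seq_len(peak)][isHit[seq_len(peak)]]
             else genes[peak:n][isHit[peak:n]]
  nullES <- withr::with_seed(seed, vapply(seq_len(nPerm), function(i) {
    perm <- logical(n)
    perm[sample.int(n, nh)] <- TRUE
    .runningSumES(perm, ranked, weight)
  }, numeric(1)))
  sameSign <- nullES[sign(nullES) == sign(es)]
  p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
  nes <- if (length(sameSign)) es / mean(abs(sameSign)) else NA_real_
  list(es = es, nes = nes, p = p, fdr = p, leadingEdge = leading,
       nPerm = nPerm)
}

#' Enrichment over a collection with the conventional significance gate
#'
#' Runs [gseaPreranked()] per set and flags sets significant when
#' `q < 0.05` and permutation `fdr < 0.25` (q = BH over permutation p).
#'
#' @inheritParams gseaPreranked
#' @param collection named list of gene sets.
#' @param minSize,maxSize set-size bounds after intersection with the
#'   ranked universe.
#' @return data.frame(set_name, es, nes, p, q, fdr, significant).
#' @export
gseaCollection <- function(ranked, collection, weight = 1, nPerm = 1000,
                           seed = 1, minSize = 5, maxSize = 5000) {
  universe <- names(ranked)
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) >= minSize & lengths(sets) <= maxSize &
                 lengths(sets) < length(universe)]
  rows <- lapply(names(sets), function(nm) {
    r <- gseaPreranked(ranked, sets[[nm]], weight, nPerm, seed)
    data.frame(set_name = nm, es = r$es, nes = r$nes, p = r$p, fdr = r$fdr,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_name = character(), es = numeric(), nes = numeric(),
               p = numeric(), fdr = numeric())
  res$q <- p.adjust(res$p, "BH")
  res$significant <- res$q < 0.05 & res$fdr < 0.25
  res[order(res$p, res$set_name), c("set_name", "es", "nes", "p", "q",
                                    "fdr", "significant")]
}
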