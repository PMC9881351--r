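# Consensus miRNA target selection across prediction sources and assembly
# of the tripartite mRNA-miRNA-lncRNA/circRNA (ceRNA) network.

# matching key: fully case-insensitive, so arm suffixes (-3p/-5p) stay
# significant but capitalization never splits an identifier
.mirKey <- function(x) tolower(x)

# canonical display form: conventional "miR-" stem capitalization, the
# rest of the identifier kept as written
.mirCanon <- function(x) sub("^[Mm][Ii][Rr]-", "miR-", x)

#' Consensus miRNA targets across prediction sources
#'
#' A (miRNA, gene) pair is kept when it appears in at least `minSupport`
#' distinct sources.  miRNA identifiers are matched case-insensitively on
#' the `miR-` stem, with arm suffixes (-3p/-5p) significant.
#'
#' @param predictionSets list of data.frames with columns `mirna`, `gene`
#'   (one per source), or a single data.frame with a `source` column.
#' @param gene target gene whose miRNAs are requested.
#' @param minSupport minimum number of distinct supporting sources
#'   (default 4).
#' @return sorted character vector of consensus miRNAs for `gene`.
#' @export
mirnaConsensus <- function(predictionSets, gene, minSupport = 4L) {
  if (is.data.frame(predictionSets))
    predictionSets <- split(predictionSets, predictionSets$source)
  if (length(predictionSets) < minSupport)
    stop("only ", length(predictionSets), " sources supplied but ",
         minSupport, " are required for consensus")
  hits <- lapply(predictionSets, function(df) {
    df <- df[df$gene == gene, , drop = FALSE]
    ids <- .mirCanon(df$mirna)
    keys <- .mirKey(df$mirna)
    data.frame(key = keys, id = ids,
               stringsAsFactors = FALSE)[!duplicated(keys), , drop = FALSE]
  })
  all <- do.call(rbind, hits)
  if (is.null(all) || !nrow(all)) return(character())
  support <- table(all$key)
  canon <- all$id[!duplicated(all$key)]        # first spelling per key wins
  names(canon) <- all$key[!duplicated(all$key)]
  sort(unname(canon[names(support)[support >= minSupport]]))
}

#' Filter ncRNA-miRNA interactions by CLIP support
#'
#' @param interactions data.frame(ncrna, kind, mirna, clip_support,
#'   samples, score); `kind` in lncRNA/circRNA.
#' @param minClip inclusive CLIP-experiment support threshold (default 5).
#' @return the rows with `clip_support >= minClip`; per-kind kept counts in
#'   attribute `"kept_by_kind"`.
#' @export
filterNcrna <- function(interactions, minClip = 5L) {
  out <- interactions[interactions$clip_support >= minClip, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept_by_kind") <- table(out$kind)
  out
}

#' Pick one circRNA isoform per parent transcript
#'
#' Among candidate shear-site isoforms of one transcript, the isoform with
#' the largest sample count wins; ties break by higher score, then by
#' lexicographically smaller identifier.
#'
#' @param candidates data.frame rows sharing a parent transcript, with
#'   columns `ncrna`, `samples`, `score`.
#' @return the single winning row.
#' @export
pickCircIsoform <- function(candidates) {
  if (!nrow(candidates)) stop("no candidate isoforms supplied")
  ord <- order(-candidates$samples, -candidates$score, candidates$ncrna)
  out <- candidates[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite ceRNA network
#'
#' mRNA-miRNA edges connect each hub gene to its consensus miRNAs; an
#' ncRNA is attached (through miRNA-lncRNA / miRNA-circRNA edges) when it
#' interacts with a strict majority of some gene's consensus miRNAs.  The
#' tripartite constraint (no mRNA-ncRNA or within-layer edges) is asserted
#' on every build.
#'
#' @param hubGenes character vector of hub genes.
#' @param consensusMirnas named list: gene -> consensus miRNA vector.
#' @param ncrnaInteractions data.frame(ncrna, kind, mirna, ...) already
#'   CLIP-filtered, or `NULL` for the bipartite mRNA-miRNA network.
#' @return list with `edges` (data.frame a, b, edge_type), `graph`
#'   (igraph with vertex attribute `layer`), `nNodes`, `nEdges` and
#'   per-layer node counts.
#' @export
assembleCerna <- function(hubGenes, consensusMirnas,
                          ncrnaInteractions = NULL) {
  edges <- list()
  mirnasInNet <- character()
  for (g in hubGenes) {
    mis <- consensusMirnas[[g]]
    if (!length(mis)) next
    edges[[length(edges) + 1L]] <- data.frame(
      a = g, b = mis, edge_type = "mRNA-miRNA", stringsAsFactors = FALSE)
    mirnasInNet <- union(mirnasInNet, mis)
  }
  ncrnasKept <- character()
  if (!is.null(ncrnaInteractions) && nrow(ncrnaInteractions)) {
    for (nc in unique(ncrnaInteractions$ncrna)) {
      rows <- ncrnaInteractions[ncrnaInteractions$ncrna == nc, , drop = FALSE]
      hitKeys <- unique(.mirKey(rows$mirna))
      keep <- FALSE
      for (g in hubGenes) {
        mis <- consensusMirnas[[g]]
        if (length(mis) && sum(.mirKey(mis) %in% hitKeys) > length(mis) / 2) {
          keep <- TRUE
          break
        }
      }
      if (!keep) next
      attach <- mirnasInNet[.mirKey(mirnasInNet) %in% hitKeys]
      if (!length(attach)) next
      kind <- rows$kind[1]
      edges[[length(edges) + 1L]] <- data.frame(
        a = attach, b = nc, edge_type = paste0("miRNA-", kind),
        stringsAsFactors = FALSE)
      ncrnasKept <- union(ncrnasKept, nc)
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), edge_type = character())
  layer <- c(setNames(rep("mRNA", length(hubGenes)), hubGenes),
             setNames(rep("miRNA", length(mirnasInNet)), mirnasInNet),
             setNames(rep("ncRNA", length(ncrnasKept)), ncrnasKept))
  ok <- (layer[edf$a] == "mRNA" & layer[edf$b] == "miRNA") |
    (layer[edf$a] == "miRNA" & layer[edf$b] == "ncRNA")
  if (!all(ok)) stop("tripartite constraint violated")  # defensive
  g <- igraph::graph_from_data_frame(
    edf[, c("a", "b")],
    directed = FALSE,
    vertices = data.frame(name = names(layer), layer = unname(layer),
                          stringsAsFactors = FALSE))
  usedMirnas <- intersect(mirnasInNet, c(edf$a, edf$b))
  list(edges = edf, graph = g,
       nNodes = length(hubGenes[vapply(hubGenes, function(x)
         x %in% c(edf$a, edf$b), logical(1))]) +
         length(usedMirnas) + length(ncrnasKept),
       nEdges = nrow(edf),
       nGenes = sum(hubGenes %in% c(edf$a, edf$b)),
       nMirnas = length(usedMirnas), nNcrnas = length(ncrnasKept))
}
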