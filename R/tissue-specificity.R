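# Tissue/organ-system-specific expression calling: the two-rule atlas
# screen (top tissue > 10x the per-gene median; second tissue <= top/3,
# with the top tissue(s) confined to a single organ system) and the
# per-system census of the resulting calls.

#' Default tissue -> organ-system mapping
#'
#' Ships the organ systems conventionally used when tabulating
#' tissue-specific expression of disease gene lists: nervous,
#' haematologic/immune, digestive, respiratory, circulatory, placenta,
#' endocrine, genital and others.
#'
#' @return data.frame(tissue, system) read from the packaged mapping file.
#' @export
defaultSystemMap <- function() {
  read.csv(system.file("extdata", "organ_systems.csv", package = "DEGnet"),
           stringsAsFactors = FALSE)
}

#' Call tissue-specific expression for one gene
#'
#' A gene is specific iff, over its atlas profile, (1) the top tissue value
#' strictly exceeds 10 times the per-gene median, (2) the second-highest
#' value is at most one third of the top (inclusive), and (3) all tissues
#' tied at the top map to a single organ system.  With a zero median rule 1
#' reduces to `max > 0`; an all-zero profile is never specific.  Ties at the
#' top spanning several systems are called not specific and flagged.
#'
#' @param atlas a [TissueAtlas-class] with >= 3 tissues.
#' @param gene gene identifier present in the atlas.
#' @return one-row data.frame(gene, specific, system, top_tissue, top_value,
#'   second_value, median_value, flag).
#' @examples
#' m <- rbind(g1 = c(100, rep(1, 9)))
#' colnames(m) <- paste0("t", 1:10)
#' atl <- tissueAtlas(m, setNames(rep("Nervous", 10), colnames(m)))
#' callSpecificity(atl, "g1")
#' @export
callSpecificity <- function(atlas, gene) {
  stopifnot(is(atlas, "TissueAtlas"))
  if (!gene %in% rownames(atlas@values))
    stop("gene '", gene, "' not found in atlas")
  x <- atlas@values[gene, ]
  if (length(x) < 3L) stop("atlas must contain at least 3 tissues")
  med <- median(x)
  ord <- order(-x, names(x))
  top <- x[ord[1]]; second <- x[ord[2]]
  rule1 <- top > 10 * med
  rule2 <- second <= top / 3
  tiedTop <- names(x)[x == top]
  systems <- unique(unname(atlas@systemOf[tiedTop]))
  oneSystem <- length(systems) == 1L
  specific <- rule1 && rule2 && oneSystem && top > 0
  flag <- if (!oneSystem && rule1) "top_tie_across_systems" else ""
  data.frame(gene = gene, specific = specific,
             system = if (specific) systems[1] else NA_character_,
             top_tissue = names(x)[ord[1]], top_value = unname(top),
             second_value = unname(second), median_value = unname(med),
             flag = flag, stringsAsFactors = FALSE)
}

#' Call specificity for many genes
#'
#' @param atlas a [TissueAtlas-class].
#' @param genes gene identifiers (default: every gene in the atlas).
#' @return data.frame, one row per gene, as in [callSpecificity()].
#' @export
callSpecificityAll <- function(atlas, genes = rownames(atlas@values)) {
  do.call(rbind, lapply(genes, function(g) callSpecificity(atlas, g)))
}

#' Per-organ-system census of specificity calls
#'
#' @param calls data.frame from [callSpecificityAll()].
#' @return data.frame(system, count, fraction) over specific genes, sorted
#'   by count descending; fractions sum to 1 (empty when nothing is
#'   specific).
#' @export
systemCensus <- function(calls) {
  spec <- calls[calls$specific, , drop = FALSE]
  if (!nrow(spec))
    return(data.frame(system = character(), count = integer(),
                      fraction = numeric()))
  tab <- sort(table(spec$system), decreasing = TRUE)
  data.frame(system = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(spec),
             stringsAsFactors = FALSE, row.names = NULL)
}
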