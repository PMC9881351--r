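# Plain-text interchange: expression/atlas TSV, edge-list TSV, prediction
# and interaction TSV, survival and genotype CSV, SIF/GraphML exports.

#' Read / write a gene x sample expression TSV
#'
#' Format: header row of sample IDs, first column gene IDs.  The reader
#' needs a parallel group assignment (either a `group` argument or sample
#' names prefixed `case_`/`ctrl_`).
#'
#' @param path file path.
#' @param group optional character vector of case/control labels.
#' @return `readExpressionTsv`: an [ExpressionDataset-class].
#' @export
readExpressionTsv <- function(path, group = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(group))
    group <- ifelse(grepl("^(case|sALS)", colnames(m)), "case", "control")
  expressionDataset(m, group)
}

#' @rdname readExpressionTsv
#' @param ds an [ExpressionDataset-class].
#' @export
writeExpressionTsv <- function(ds, path) {
  m <- exprValues(ds)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a scored edge-list TSV (node_a, node_b, combined_score)
#'
#' @param path file path.
#' @return data.frame ready for [buildGraph()]; the 0-1 vs 0-1000 score
#'   dialect is resolved there.
#' @export
readEdgeList <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a tissue atlas TSV plus a tissue -> organ-system mapping CSV
#'
#' @param atlasPath genes x tissues TSV (first column gene IDs).
#' @param mapPath CSV with columns tissue, system; defaults to the packaged
#'   mapping.
#' @return a [TissueAtlas-class].
#' @export
readAtlasTsv <- function(atlasPath, mapPath = NULL) {
  df <- read.delim(atlasPath, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  map <- if (is.null(mapPath)) defaultSystemMap()
         else read.csv(mapPath, stringsAsFactors = FALSE)
  tissueAtlas(m, setNames(map$system, map$tissue)[colnames(m)])
}

#' @rdname readAtlasTsv
#' @param atlas a [TissueAtlas-class]; `path` output TSV.
#' @param path file path.
#' @export
writeAtlasTsv <- function(atlas, path) {
  df <- data.frame(gene_id = rownames(atlas@values), atlas@values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write survival records CSV (sample, time, event)
#'
#' @param path file path.
#' @export
readSurvivalCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname readSurvivalCsv
#' @param records data.frame(sample, time, event).
#' @export
writeSurvivalCsv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
}

#' Read per-subject genotype calls CSV (subject, group, snp, genotype)
#'
#' @param path file path.
#' @export
readGenotypeCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Export a network in SIF format
#'
#' @param edges data.frame with the first two columns as endpoints; an
#'   `edge_type` column, when present, becomes the SIF relation.
#' @param path output path.
#' @export
writeSif <- function(edges, path) {
  rel <- if ("edge_type" %in% names(edges)) edges$edge_type else "pp"
  writeLines(paste(edges[[1]], rel, edges[[2]], sep = "\t"), path)
}

#' Export an igraph in GraphML format
#'
#' @param graph an igraph.
#' @param path output path.
#' @export
writeGraphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
}
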