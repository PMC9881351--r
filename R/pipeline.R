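# End-to-end orchestration: one configuration drives synthetic-input
# generation (or file loading), the expression -> specificity -> network ->
# enrichment -> ceRNA -> evaluation chain and the independent SNP arm, and
# a machine-readable report whose filter stages record before/after counts.

#' Write a complete synthetic input bundle
#'
#' One call produces every file the pipeline consumes — two expression
#' cohorts, the tissue atlas and system mapping, the scored edge list,
#' per-source prediction TSVs, ncRNA interaction TSV, survival CSV and
#' genotype CSV — plus a `ground_truth.json` sidecar of the planted truth.
#'
#' @param dir target directory (created if needed).
#' @param cfg a [SynthConfig-class]; its seed fixes the whole bundle.
#' @return invisibly, the list of written paths.
#' @export
makeFixture <- function(dir, cfg = synthConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  sim1 <- genExpression(cfg)
  cfg2 <- synthConfig(nGenes = cfg@nGenes, nCase = 3L, nControl = 3L,
                      nDE = cfg@nDE, deLog2fc = cfg@deLog2fc,
                      noiseSd = cfg@noiseSd, seed = cfg@seed + 101L)
  sim2 <- genExpression(cfg2)
  atlas <- genTissueAtlas(cfg)
  ppi <- genPPI(cfg)
  preds <- genPredictions(cfg, geneIds = sim1$truth)
  surv <- genSurvival(cfg, sim1$dataset, sim1$truth[1])
  geno <- genGenotypes(cfg)

  writeExpressionTsv(sim1$dataset, p("expression_cohort1.tsv"))
  writeExpressionTsv(sim2$dataset, p("expression_cohort2.tsv"))
  writeAtlasTsv(atlas$atlas, p("tissue_atlas.tsv"))
  write.csv(data.frame(tissue = colnames(atlas$atlas@values),
                       system = unname(atlas$atlas@systemOf[
                         colnames(atlas$atlas@values)])),
            p("organ_systems.csv"), row.names = FALSE, quote = FALSE)
  write.table(ppi$edges, p("ppi_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  predTab <- do.call(rbind, preds$sources)
  write.table(predTab, p("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mirnas <- preds$pairs$mirna
  interactions <- data.frame(
    ncrna = rep(c("lnc-SYN1", "circ-SYN1"), each = length(mirnas)),
    kind = rep(c("lncRNA", "circRNA"), each = length(mirnas)),
    mirna = rep(mirnas, 2),
    clip_support = rep(c(6L, 5L), each = length(mirnas)),
    samples = rep(c(10L, 8L), each = length(mirnas)),
    score = rep(c(0.9, 0.8), each = length(mirnas)))
  write.table(interactions, p("ncrna_interactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSurvivalCsv(surv, p("survival.csv"))
  write.csv(geno$subjects, p("genotypes.csv"), row.names = FALSE,
            quote = FALSE)
  truth <- list(planted_degs = sim1$truth, planted_degs_cohort2 = sim2$truth,
                planted_specific = atlas$truth,
                planted_modules = ppi$truth,
                consensus_mirnas = preds$truth,
                allele_ratio = geno$truth, seed = cfg@seed)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Run the full discovery pipeline on synthetic inputs
#'
#' Executes the stages in dependency order — differential expression per
#' cohort, the fold-change/adjusted-p screen, cross-cohort intersection and
#' merge, tissue-specificity calling, network construction with MCODE-style
#' modules and five-centrality hub consensus, optional enrichment, ceRNA
#' assembly, per-hub ROC and Kaplan-Meier evaluation — plus the independent
#' genotype-association arm.  Identical configuration reproduces the report
#' exactly.
#'
#' @param cfg a [SynthConfig-class] driving the synthetic inputs.
#' @param lfcThreshold,alpha DEG screen (defaults 1.5 and 0.05).
#' @param minScore edge combined-score filter, strict (default 0.4).
#' @param k top-k per centrality (default 14).
#' @param minSupport consensus source support (default 4).
#' @param minClip CLIP-support filter, inclusive (default 5).
#' @param collection optional named list of gene sets for enrichment.
#' @return a nested list report: per-stage parameters, before/after counts
#'   of every filter, hub sets, network sizes, per-gene AUC and log-rank p,
#'   association table and the seed.
#' @export
runPipeline <- function(cfg = synthConfig(), lfcThreshold = 1.5,
                        alpha = 0.05, minScore = 0.4, k = 14,
                        minSupport = 4L, minClip = 5L, collection = NULL) {
  report <- list(seed = cfg@seed,
                 params = list(lfcThreshold = lfcThreshold, alpha = alpha,
                               minScore = minScore, k = k,
                               minSupport = minSupport, minClip = minClip))

  # --- differential expression on two cohorts -------------------------
  sim1 <- genExpression(cfg)
  cfg2 <- synthConfig(nGenes = cfg@nGenes, nCase = 3L, nControl = 3L,
                      nDE = cfg@nDE, deLog2fc = cfg@deLog2fc,
                      noiseSd = cfg@noiseSd, seed = cfg@seed + 101L)
  sim2 <- genExpression(cfg2)
  de1 <- applyDegFilter(differentialExpression(sim1$dataset),
                        lfcThreshold, alpha)
  de2 <- applyDegFilter(differentialExpression(sim2$dataset),
                        lfcThreshold, alpha)
  merged <- intersectAndMerge(list(de1$genes, de2$genes),
                              list(sim1$dataset, sim2$dataset))
  report$dge <- list(
    cohort1 = list(tested = cfg@nGenes, kept = length(de1$genes),
                   up = de1$nUp, down = de1$nDown),
    cohort2 = list(tested = cfg2@nGenes, kept = length(de2$genes),
                   up = de2$nUp, down = de2$nDown),
    intersection = merged$intersection,
    unionSize = length(merged$union),
    planted = sim1$truth,
    sensitivity = if (length(sim1$truth))
      mean(sim1$truth %in% de1$genes) else NA_real_)

  # --- tissue specificity over the DEG union --------------------------
  atlas <- genTissueAtlas(cfg)
  degUnion <- intersect(merged$union, rownames(atlas$atlas@values))
  calls <- callSpecificityAll(atlas$atlas, degUnion)
  census <- systemCensus(calls)
  specific <- calls$gene[calls$specific]
  report$tissue <- list(tested = length(degUnion),
                        specific = length(specific), census = census)

  # --- interaction network, modules, hubs -----------------------------
  ppi <- genPPI(cfg)
  g <- buildGraph(ppi$edges, minScore = minScore)
  modules <- mcodeCluster(g)
  rankings <- lapply(.centralityMethods, function(m) centrality(g, m, k))
  hubs <- hubConsensus(rankings, tissueSpecific = atlas$truth)
  report$network <- list(
    nNodes = igraph::vcount(g), nEdges = igraph::ecount(g),
    modules = modules[, c("module", "n_nodes", "n_edges", "score")],
    topModuleMembers = if (nrow(modules)) modules$members[[1]] else
      character(),
    hubs = hubs$hubs, systemHubs = hubs$systemHubs)

  # --- enrichment (optional, needs a gene-set collection) -------------
  if (!is.null(collection)) {
    deTab <- differentialExpression(sim1$dataset)
    ranked <- setNames(deTab$t_stat, deTab$gene)
    report$enrichment <- list(
      ora = ora(de1$genes, rownames(exprValues(sim1$dataset)), collection),
      gsea = gseaCollection(ranked, collection, nPerm = 200,
                            seed = cfg@seed))
  }

  # --- ceRNA assembly --------------------------------------------------
  hubSet <- if (length(hubs$hubs)) hubs$hubs else sim1$truth[1:3]
  preds <- genPredictions(cfg, geneIds = hubSet)
  consensus <- lapply(setNames(hubSet, hubSet), function(gn)
    mirnaConsensus(preds$sources, gn, minSupport))
  cer <- assembleCerna(hubSet, consensus)
  report$cerna <- list(nNodes = cer$nNodes, nEdges = cer$nEdges,
                       nMirnas = cer$nMirnas,
                       consensusTruth = preds$truth)

  # --- biomarker evaluation -------------------------------------------
  evalGene <- sim1$truth[1]
  scores <- exprValues(sim1$dataset)[evalGene, ]
  roc <- rocAuc(scores, sampleGroups(sim1$dataset))
  survCfg <- synthConfig(nGenes = 10L, nCase = 100L, nControl = 2L,
                         nDE = 0L, nSpecific = 0L,
                         hazardBeta = cfg@hazardBeta,
                         censorRate = cfg@censorRate, seed = cfg@seed)
  survSim <- genExpression(survCfg)
  surv <- genSurvival(survCfg, survSim$dataset, "gene_0001")
  expr <- exprValues(survSim$dataset)["gene_0001", surv$sample]
  km <- kmLogrank(expr, surv)
  report$biomarker <- list(gene = evalGene, auc = roc$auc,
                           logrankChi2 = km$chi2, logrankP = km$p)

  # --- SNP association (independent arm) ------------------------------
  geno <- genGenotypes(cfg)
  assoc <- snpAssociation(geno$table)
  report$snp <- list(
    snp = assoc$snp,
    alleleRatio = assoc$ratios["minor", "ratio"],
    ci95 = c(assoc$ratios["minor", "ci_low"],
             assoc$ratios["minor", "ci_high"]),
    alleleP = assoc$allele$p, dominantP = assoc$dominant$p,
    plantedRatio = geno$truth)
  report
}

#' Serialize a pipeline report to JSON
#'
#' @param report list from [runPipeline()].
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
}
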