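# Planted-truth simulators for every pipeline input.  Each generator draws
# from its own substream derived from the single top-level seed, so the
# output of one generator is invariant to adding or re-running another.

.substream <- function(cfg, id) {
  # keep derived seeds well inside 32-bit integer range
  (cfg@seed %% 599479L) * 3581L + id
}

#' Simulate a case-control expression dataset with planted DEGs
#'
#' Values are drawn directly on the log2 scale: gene baselines ~ N(7, 1),
#' i.i.d. Gaussian noise with SD `noiseSd`, and the first `nDE` genes get
#' their case-group mean shifted by `deLog2fc`.
#'
#' @param cfg a [SynthConfig-class].
#' @return a list with `dataset` (an [ExpressionDataset-class]) and `truth`
#'   (character vector of planted DEG identifiers).
#' @examples
#' sim <- genExpression(synthConfig(nGenes = 100, nDE = 10, seed = 1))
#' sim$truth
#' @export
genExpression <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  withr::with_seed(.substream(cfg, 1L), {
    n <- cfg@nCase + cfg@nControl
    genes <- sprintf("gene_%04d", seq_len(cfg@nGenes))
    samples <- c(sprintf("case_%02d", seq_len(cfg@nCase)),
                 sprintf("ctrl_%02d", seq_len(cfg@nControl)))
    group <- rep(c("case", "control"), c(cfg@nCase, cfg@nControl))
    base <- rnorm(cfg@nGenes, mean = 7, sd = 1)
    m <- matrix(rnorm(cfg@nGenes * n, sd = cfg@noiseSd), cfg@nGenes, n,
                dimnames = list(genes, samples)) + base
    de <- genes[seq_len(cfg@nDE)]
    if (cfg@nDE > 0L)
      m[de, group == "case"] <- m[de, group == "case"] + cfg@deLog2fc
    list(dataset = expressionDataset(m, group), truth = de)
  })
}

#' Simulate a tissue atlas with planted tissue-specific genes
#'
#' Planted genes get a single dominant tissue at `specificityFold` times the
#' background (so they pass both specificity rules by construction); all
#' other genes have near-uniform profiles.
#'
#' @param cfg a [SynthConfig-class]; requires `specificityFold > 10`
#'   whenever `nSpecific > 0`.
#' @return a list with `atlas` (a [TissueAtlas-class]), `truth` (planted
#'   specific genes) and `truthSystem` (their planted organ systems).
#' @export
genTissueAtlas <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  if (cfg@nSpecific > 0L && cfg@specificityFold <= 10)
    stop("specificityFold must exceed 10 to plant specific genes")
  withr::with_seed(.substream(cfg, 2L), {
    genes <- sprintf("gene_%04d", seq_len(cfg@nGenes))
    sysmap <- defaultSystemMap()
    tissues <- sprintf("tissue_%02d", seq_len(cfg@nTissues))
    systems <- setNames(
      rep(unique(sysmap$system), length.out = cfg@nTissues), tissues)
    # background noise kept within [0.8, 1.2] so planted profiles cannot
    # violate either screening rule
    m <- matrix(runif(cfg@nGenes * cfg@nTissues, 0.8, 1.2) * 5,
                cfg@nGenes, cfg@nTissues, dimnames = list(genes, tissues))
    specific <- genes[seq_len(cfg@nSpecific)]
    top <- sample(tissues, cfg@nSpecific, replace = TRUE)
    for (i in seq_along(specific))
      m[specific[i], top[i]] <- 5 * cfg@specificityFold
    list(atlas = tissueAtlas(m, systems), truth = specific,
         truthSystem = setNames(unname(systems[top]), specific))
  })
}

#' Simulate a scored interaction graph with planted dense modules
#'
#' An Erdos-Renyi background at `ppiPBackground` plus planted node blocks
#' whose internal edge probability is `moduleP`.  Every edge carries a
#' combined score in (0, 1]; planted-block edges are scored high so the
#' standard 0.4 score filter keeps them.
#'
#' @param cfg a [SynthConfig-class].
#' @param nodeIds optional node names (defaults to the generator's gene IDs).
#' @return a list with `edges` (data.frame node_a, node_b, combined_score),
#'   `graph` (igraph of all generated edges) and `truth` (list of planted
#'   module membership vectors).
#' @export
genPPI <- function(cfg, nodeIds = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  withr::with_seed(.substream(cfg, 3L), {
    n <- cfg@ppiNBackground
    if (is.null(nodeIds)) nodeIds <- sprintf("gene_%04d", seq_len(n))
    stopifnot(length(nodeIds) == n)
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < cfg@ppiPBackground
    truth <- list()
    offset <- 0L
    inModule <- logical(nrow(pairs))
    for (k in seq_along(cfg@moduleSizes)) {
      sz <- cfg@moduleSizes[k]
      members <- seq.int(offset + 1L, offset + sz)
      offset <- offset + sz
      sel <- pairs[, 1] %in% members & pairs[, 2] %in% members
      keep[sel] <- runif(sum(sel)) < cfg@moduleP
      inModule <- inModule | sel
      truth[[paste0("module_", k)]] <- nodeIds[members]
    }
    a <- nodeIds[pairs[keep, 1]]
    b <- nodeIds[pairs[keep, 2]]
    score <- ifelse(inModule[keep], runif(sum(keep), 0.7, 0.99),
                    runif(sum(keep), 0.41, 0.95))
    edges <- data.frame(node_a = a, node_b = b, combined_score = score,
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$combined_score <- edges$combined_score
    list(edges = edges, graph = g, truth = truth)
  })
}

#' Simulate per-source miRNA target prediction lists
#'
#' Each miRNA is paired with one target gene and planted into exactly the
#' number of prediction sources given by the overlap profile; the ground
#' truth consensus is the support >= `minSupport` set.
#'
#' @param cfg a [SynthConfig-class]; `overlapProfile` may be a named integer
#'   vector (miRNA -> number of supporting sources).  When empty, 20 miRNAs
#'   get supports drawn uniformly from 0..nSources.
#' @param geneIds candidate target genes (each miRNA is assigned one).
#' @param mirnaIds optional miRNA identifiers (defaults to the profile
#'   names or `miR-1 ...`).
#' @param minSupport consensus threshold used for the returned ground truth.
#' @return list with `sources` (list of data.frame(source, mirna, gene)),
#'   `pairs` (the full mirna/gene/support table) and `truth` (miRNAs with
#'   support >= minSupport).
#' @export
genPredictions <- function(cfg, geneIds, mirnaIds = NULL, minSupport = 4L) {
  stopifnot(is(cfg, "SynthConfig"), length(geneIds) >= 1L)
  withr::with_seed(.substream(cfg, 4L), {
    prof <- cfg@overlapProfile
    if (!length(prof)) {
      mirnaIds <- if (is.null(mirnaIds)) sprintf("miR-%d", 1:20) else mirnaIds
      prof <- setNames(sample(0:cfg@nSources, length(mirnaIds),
                              replace = TRUE), mirnaIds)
    } else if (is.null(names(prof))) {
      names(prof) <- if (is.null(mirnaIds))
        sprintf("miR-%d", seq_along(prof)) else mirnaIds
    }
    stopifnot(all(prof >= 0L), all(prof <= cfg@nSources))
    srcNames <- sprintf("source_%d", seq_len(cfg@nSources))
    gene <- setNames(sample(geneIds, length(prof), replace = TRUE),
                     names(prof))
    rows <- lapply(names(prof), function(mi) {
      s <- prof[[mi]]
      if (s == 0L) return(NULL)
      data.frame(source = sample(srcNames, s), mirna = mi,
                 gene = gene[[mi]], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    sources <- lapply(srcNames, function(sn) {
      if (is.null(tab)) return(data.frame(source = character(),
                                          mirna = character(),
                                          gene = character()))
      out <- tab[tab$source == sn, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    names(sources) <- srcNames
    list(sources = sources,
         pairs = data.frame(mirna = names(prof), gene = unname(gene),
                            support = unname(prof),
                            stringsAsFactors = FALSE),
         truth = names(prof)[prof >= minSupport])
  })
}

#' Simulate survival records linked to the expression of one gene
#'
#' Event times are exponential with per-sample log-hazard
#' `hazardBeta * z`, where `z` is the standardized expression of `gene`.
#' Censoring is an independent exponential race calibrated so that the
#' expected censored fraction equals `censorRate` exactly.
#'
#' @param cfg a [SynthConfig-class].
#' @param dataset an [ExpressionDataset-class] (only case samples are kept
#'   when both groups are present, mirroring a patient cohort; if a single
#'   group is present all samples are used).
#' @param gene gene identifier present in `dataset`.
#' @return data.frame(sample, time, event) with `time` in months.
#' @export
genSurvival <- function(cfg, dataset, gene) {
  stopifnot(is(cfg, "SynthConfig"), is(dataset, "ExpressionDataset"))
  m <- exprValues(dataset)
  if (!gene %in% rownames(m)) stop("gene '", gene, "' not in dataset")
  grp <- sampleGroups(dataset)
  keep <- if (all(c("case", "control") %in% grp)) grp == "case"
          else rep(TRUE, length(grp))
  x <- m[gene, keep]
  z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  withr::with_seed(.substream(cfg, 5L), {
    rate <- exp(cfg@hazardBeta * z) / 36      # baseline median ~ 25 months
    t_event <- rexp(length(z), rate)
    if (cfg@censorRate > 0) {
      cRate <- rate * cfg@censorRate / (1 - cfg@censorRate)
      t_cens <- rexp(length(z), cRate)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, length(z))
      time <- t_event
    }
    data.frame(sample = names(x), time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate case-control genotypes at a planted allele-frequency ratio
#'
#' Genotypes are drawn under Hardy-Weinberg within each group, with control
#' minor-allele frequency `controlMaf` and case frequency
#' `rrAllele * controlMaf`.
#'
#' @param cfg a [SynthConfig-class]; `nCaseSubjects`/`nControlSubjects`
#'   default to the conventional 30 + 30 genotyping arm.
#' @param nCaseSubjects,nControlSubjects group sizes.
#' @param snp,alleles labels for the returned table.
#' @return a list with `table` (a [GenotypeTable-class]), `subjects`
#'   (per-subject data.frame: subject, group, snp, genotype) and
#'   `truth` (the planted frequency ratio).
#' @export
genGenotypes <- function(cfg, nCaseSubjects = 30L, nControlSubjects = 30L,
                         snp = "rs0001", alleles = c("G", "C")) {
  stopifnot(is(cfg, "SynthConfig"))
  withr::with_seed(.substream(cfg, 6L), {
    pCase <- cfg@rrAllele * cfg@controlMaf
    pCtrl <- cfg@controlMaf
    draw <- function(n, p) {
      probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
      as.vector(rmultinom(1, n, probs))
    }
    caseCts <- draw(nCaseSubjects, pCase)
    ctrlCts <- draw(nControlSubjects, pCtrl)
    geno <- c(paste0(alleles[1], alleles[1]),
              paste0(alleles[1], alleles[2]),
              paste0(alleles[2], alleles[2]))
    subjects <- data.frame(
      subject = sprintf("subj_%03d", seq_len(nCaseSubjects + nControlSubjects)),
      group = rep(c("case", "control"), c(nCaseSubjects, nControlSubjects)),
      snp = snp,
      genotype = c(rep(geno, caseCts), rep(geno, ctrlCts)),
      stringsAsFactors = FALSE)
    list(table = genotypeTable(snp, alleles, caseCts, ctrlCts),
         subjects = subjects, truth = cfg@rrAllele)
  })
}
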