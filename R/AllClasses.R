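#' @import methods
#' @importFrom stats median p.adjust pchisq phyper pnorm pt qnorm quantile
#'   rbinom rexp rnorm runif sd setNames fisher.test rmultinom
#' @importFrom utils read.csv read.delim write.csv write.table head
NULL

#' Configuration for the synthetic-data generators
#'
#' One object holds every knob of the planted-truth simulators: the
#' case/control expression design, the tissue atlas, the interaction graph,
#' the miRNA prediction sources, survival and genotype generation.  All
#' randomness flows from the single `seed` through independent substreams per
#' generator, so adding one generator never perturbs another's draws.
#'
#' Defaults mirror a small two-cohort microarray screen: 5 cases vs 4
#' controls, planted log2 effect 2.0, per-gene noise SD 0.5 (log2 units), a
#' 30 + 30 genotyping arm with control minor-allele frequency 1/12 and a
#' planted case/control allele-frequency ratio of 3.
#'
#' @slot nGenes,nCase,nControl,nDE integer design sizes; `nDE` planted DEGs.
#' @slot deLog2fc planted case-vs-control shift, log2 units.
#' @slot noiseSd per-gene Gaussian SD, log2 units.
#' @slot nTissues,nSpecific,specificityFold tissue-atlas design; the planted
#'   fold must exceed 10 for a gene to pass the specificity screen.
#' @slot ppiNBackground,ppiPBackground,moduleSizes,moduleP interaction-graph
#'   design: Erdos-Renyi background with planted dense blocks.
#' @slot nSources,overlapProfile miRNA prediction sources and per-miRNA
#'   source support (named integer vector, or empty for a default draw).
#' @slot hazardBeta log-hazard per SD of expression; `censorRate` fraction
#'   censored.
#' @slot rrAllele planted case/control minor-allele frequency ratio;
#'   `controlMaf` the control-group minor-allele frequency.
#' @slot seed integer RNG seed.
#' @export
setClass("SynthConfig", representation(
  nGenes = "integer", nCase = "integer", nControl = "integer",
  nDE = "integer", deLog2fc = "numeric", noiseSd = "numeric",
  nTissues = "integer", nSpecific = "integer", specificityFold = "numeric",
  ppiNBackground = "integer", ppiPBackground = "numeric",
  moduleSizes = "integer", moduleP = "numeric",
  nSources = "integer", overlapProfile = "integer",
  hazardBeta = "numeric", censorRate = "numeric",
  rrAllele = "numeric", controlMaf = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  pos <- c(nGenes = object@nGenes, nCase = object@nCase,
           nControl = object@nControl, nTissues = object@nTissues,
           nSources = object@nSources)
  if (any(pos <= 0L)) msg <- c(msg, "all design counts must be positive")
  if (object@nDE < 0L || object@nDE > object@nGenes)
    msg <- c(msg, "nDE must lie in [0, nGenes]")
  if (object@nSpecific > object@nGenes)
    msg <- c(msg, "nSpecific must not exceed nGenes")
  if (length(object@moduleSizes) &&
      any(object@moduleSizes > object@ppiNBackground))
    msg <- c(msg, "planted module sizes must not exceed ppiNBackground")
  if (object@moduleP <= object@ppiPBackground)
    msg <- c(msg, "moduleP must exceed ppiPBackground (planted blocks denser)")
  if (object@censorRate < 0 || object@censorRate >= 1)
    msg <- c(msg, "censorRate must lie in [0, 1)")
  if (object@rrAllele * object@controlMaf > 1)
    msg <- c(msg, "rrAllele * controlMaf must not exceed 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a [SynthConfig-class]
#'
#' @param nGenes,nCase,nControl,nDE,deLog2fc,noiseSd expression design.
#' @param nTissues,nSpecific,specificityFold tissue-atlas design.
#' @param ppiNBackground,ppiPBackground,moduleSizes,moduleP graph design.
#' @param nSources,overlapProfile prediction-source design.
#' @param hazardBeta,censorRate survival design.
#' @param rrAllele,controlMaf genotype design.
#' @param seed integer RNG seed.
#' @return a validated `SynthConfig`.
#' @examples
#' cfg <- synthConfig(nGenes = 200, nDE = 10, seed = 1)
#' @export
synthConfig <- function(nGenes = 1000L, nCase = 5L, nControl = 4L,
                        nDE = 50L, deLog2fc = 2.0, noiseSd = 0.5,
                        nTissues = 18L, nSpecific = 20L,
                        specificityFold = 100,
                        ppiNBackground = 120L, ppiPBackground = 0.02,
                        moduleSizes = c(14L, 8L), moduleP = 0.9,
                        nSources = 5L, overlapProfile = integer(),
                        hazardBeta = 1.5, censorRate = 0.2,
                        rrAllele = 3.0, controlMaf = 5 / 60,
                        seed = 1L) {
  new("SynthConfig",
      nGenes = as.integer(nGenes), nCase = as.integer(nCase),
      nControl = as.integer(nControl), nDE = as.integer(nDE),
      deLog2fc = deLog2fc, noiseSd = noiseSd,
      nTissues = as.integer(nTissues), nSpecific = as.integer(nSpecific),
      specificityFold = specificityFold,
      ppiNBackground = as.integer(ppiNBackground),
      ppiPBackground = ppiPBackground,
      moduleSizes = as.integer(moduleSizes), moduleP = moduleP,
      nSources = as.integer(nSources),
      overlapProfile = {
        op <- as.integer(overlapProfile)
        names(op) <- names(overlapProfile)
        op
      },
      hazardBeta = hazardBeta, censorRate = censorRate,
      rrAllele = rrAllele, controlMaf = controlMaf,
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n",
      "  expression: ", object@nGenes, " genes, ", object@nCase, " cases vs ",
      object@nControl, " controls, ", object@nDE, " planted DEGs (log2FC ",
      object@deLog2fc, ", SD ", object@noiseSd, ")\n",
      "  atlas: ", object@nTissues, " tissues, ", object@nSpecific,
      " planted specific genes (fold ", object@specificityFold, ")\n",
      "  graph: ", object@ppiNBackground, " nodes, p = ",
      object@ppiPBackground, "; planted blocks {",
      paste(object@moduleSizes, collapse = ", "), "} at p = ",
      object@moduleP, "\n",
      "  genotypes: ratio ", object@rrAllele, " at control MAF ",
      signif(object@controlMaf, 3), "; seed ", object@seed, "\n", sep = "")
})

#' Case-control expression dataset
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' validity pins down what every downstream stage assumes: a single `exprs`
#' assay of finite log2-scale values, unique gene identifiers, and a
#' per-sample `group` column restricted to `case` / `control`.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "exprs"))))
    msg <- c(msg, "expression values must be finite")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  grp <- SummarizedExperiment::colData(object)$group
  if (is.null(grp) || !all(grp %in% c("case", "control")))
    msg <- c(msg, "colData$group must label every sample 'case' or 'control'")
  if (length(msg)) msg else TRUE
})

#' Construct an [ExpressionDataset-class]
#'
#' @param values numeric gene x sample matrix (log2 scale) with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param group character vector, one of `"case"`/`"control"` per sample.
#' @param dataset optional provenance label recorded per sample.
#' @return an `ExpressionDataset`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expressionDataset(m, c("case", "case", "control", "control"))
#' @export
expressionDataset <- function(values, group, dataset = NA_character_) {
  values <- as.matrix(values)
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             dataset = rep(dataset, length.out = ncol(values)),
                             row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("ExpressionDataset", se)
}

#' Expression matrix and group labels of an [ExpressionDataset-class]
#'
#' @param x an `ExpressionDataset`.
#' @return `exprValues`: the log2 matrix; `sampleGroups`: named character
#'   vector of `"case"`/`"control"` labels.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname exprValues
#' @export
sampleGroups <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x))
}

setMethod("show", "ExpressionDataset", function(object) {
  grp <- sampleGroups(object)
  cat("ExpressionDataset: ", nrow(object), " genes x ", ncol(object),
      " samples (", sum(grp == "case"), " case / ",
      sum(grp == "control"), " control)\n", sep = "")
})

#' Gene x tissue expression atlas
#'
#' Linear-scale expression of genes across tissues plus a tissue-to-organ
#' system mapping; the substrate of the tissue-specificity screen.
#'
#' @slot values non-negative gene x tissue matrix, linear scale.
#' @slot systemOf named character vector mapping each tissue (names) to
#'   exactly one organ system.
#' @export
setClass("TissueAtlas",
         representation(values = "matrix", systemOf = "character"))

setValidity("TissueAtlas", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "atlas values must be >= 0")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "tissue (column) names are required")
  if (!all(colnames(object@values) %in% names(object@systemOf)))
    msg <- c(msg, "every tissue must map to exactly one organ system")
  if (length(msg)) msg else TRUE
})

#' Construct a [TissueAtlas-class]
#'
#' @param values gene x tissue matrix, linear scale, dimnames set.
#' @param systemOf named character vector tissue -> organ system.
#' @return a `TissueAtlas`.
#' @export
tissueAtlas <- function(values, systemOf) {
  new("TissueAtlas", values = as.matrix(values),
      systemOf = setNames(as.character(systemOf), names(systemOf)))
}

setMethod("show", "TissueAtlas", function(object) {
  cat("TissueAtlas: ", nrow(object@values), " genes x ",
      ncol(object@values), " tissues across ",
      length(unique(object@systemOf[colnames(object@values)])),
      " organ systems\n", sep = "")
})

#' Per-group genotype counts for one SNP
#'
#' Case and control genotype counts at a biallelic SNP, the unit of the
#' allele-association stage.  Rows are groups, columns the genotypes
#' `mm` (homozygous minor), `Mm` (heterozygous), `MM` (homozygous major).
#'
#' @slot snp SNP identifier.
#' @slot alleles length-2 character, `c(minor, major)` symbols.
#' @slot counts 2 x 3 integer matrix, rows `case`/`control`, columns
#'   `mm`/`Mm`/`MM`.
#' @export
setClass("GenotypeTable",
         representation(snp = "character", alleles = "character",
                        counts = "matrix"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (length(object@alleles) != 2L)
    msg <- c(msg, "alleles must be c(minor, major)")
  cts <- object@counts
  if (!identical(dim(cts), c(2L, 3L)) ||
      !identical(rownames(cts), c("case", "control")) ||
      !identical(colnames(cts), c("mm", "Mm", "MM")))
    msg <- c(msg, "counts must be 2x3 with rows case/control, cols mm/Mm/MM")
  else if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Construct a [GenotypeTable-class]
#'
#' @param snp SNP identifier.
#' @param alleles `c(minor, major)` allele symbols.
#' @param caseCounts,controlCounts length-3 integer vectors of genotype
#'   counts in order (mm, Mm, MM).
#' @return a `GenotypeTable`.
#' @examples
#' genotypeTable("rs463946", c("G", "C"), c(2, 11, 17), c(1, 3, 26))
#' @export
genotypeTable <- function(snp, alleles, caseCounts, controlCounts) {
  cts <- rbind(case = as.numeric(caseCounts),
               control = as.numeric(controlCounts))
  colnames(cts) <- c("mm", "Mm", "MM")
  new("GenotypeTable", snp = as.character(snp),
      alleles = as.character(alleles), counts = cts)
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable ", object@snp, " (minor ", object@alleles[1],
      ", major ", object@alleles[2], ")\n", sep = "")
  print(object@counts)
})
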