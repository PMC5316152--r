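#' Simulation effect configuration
#'
#' Holds every knob of the synthetic-data generator: library depth, the
#' negative-binomial noise model, planted transcriptional and
#' translational-efficiency effects, planted 5'UTR ribosome-loading classes,
#' and the codon-dependent (KQE) translational suppression slope.
#'
#' The noise model is `var = mu + phi * mu^2` with `phi =
#' dispersionSlope / sqrt(mu)`, i.e. the squared coefficient of variation in
#' excess of Poisson decays as `1/sqrt(mu)` — strong mean-dependence, which is
#' exactly what the neighbourhood-based noise estimator downstream is built
#' for. `dispersionSlope = 0` gives Poisson counts.
#'
#' Planted loading classes apply to translationally up-regulated genes only:
#' each TE-up gene is assigned class1/class2/class3 with probabilities
#' `classProbs`, and its per-condition 5'UTR footprint fraction is taken from
#' `classUtr5Fractions` instead of the background `utr5ReadFraction`.
#'
#' @slot nGenes number of genes to simulate.
#' @slot meanDepth mean reads per gene per library.
#' @slot dispersionSlope negative-binomial dispersion slope (see Details).
#' @slot exprSdLog sdlog of the lognormal relative-expression distribution
#'   (normalized to mean 1).
#' @slot fracTxUp,fracTxDown fractions of genes with planted transcriptional
#'   up/down fold changes of size `txEffect` (down genes get `1/txEffect`).
#' @slot txEffect transcriptional effect size (fold, > 1).
#' @slot fracTeUp,fracTeDown fractions with planted translational-efficiency
#'   changes of size `teEffect` (down genes get `1/teEffect`).
#' @slot teEffect translational-efficiency effect size (fold, > 1).
#' @slot utr5ReadFraction background fraction of footprint reads placed in the
#'   5'UTR, both conditions.
#' @slot classProbs length-3 probabilities of class1/class2/class3 among TE-up
#'   genes (need not sum to 1; the remainder stays background/class-free).
#' @slot classUtr5Fractions 3x2 numeric matrix, rows class1..class3, columns
#'   SD/MetR: per-condition 5'UTR footprint fractions planted for each class.
#' @slot kqeSlope log2 TE decrement per unit combined K/Q/E codon frequency.
#' @slot kqeSet gene ids the KQE suppression applies to; `character(0)` means
#'   all genes when `kqeSlope != 0`.
#' @slot readLenFp,readLenMrna emitted read lengths (nt) for footprint and
#'   mRNA BED intervals.
#' @slot collapsePositions collapse identical read positions into one BED line
#'   with the multiplicity in the score field.
#' @slot mirrorStrand place half the genes on the minus strand.
#' @slot seed integer seed; identical configuration implies identical output.
#' @exportClass EffectConfig
setClass("EffectConfig",
  representation(
    nGenes = "integer", meanDepth = "numeric", dispersionSlope = "numeric",
    exprSdLog = "numeric",
    fracTxUp = "numeric", fracTxDown = "numeric", txEffect = "numeric",
    fracTeUp = "numeric", fracTeDown = "numeric", teEffect = "numeric",
    utr5ReadFraction = "numeric", classProbs = "numeric",
    classUtr5Fractions = "matrix",
    kqeSlope = "numeric", kqeSet = "character",
    readLenFp = "integer", readLenMrna = "integer",
    collapsePositions = "logical", mirrorStrand = "logical",
    seed = "integer"
  )
)

setValidity("EffectConfig", function(object) {
  msg <- character()
  fr <- c(object@fracTxUp, object@fracTxDown, object@fracTeUp,
          object@fracTeDown, object@utr5ReadFraction,
          as.numeric(object@classUtr5Fractions), object@classProbs)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0, 1]")
  if (object@fracTxUp + object@fracTxDown > 1)
    msg <- c(msg, "fracTxUp + fracTxDown must not exceed 1")
  if (object@fracTeUp + object@fracTeDown > 1)
    msg <- c(msg, "fracTeUp + fracTeDown must not exceed 1")
  if (object@txEffect <= 0 || object@teEffect <= 0)
    msg <- c(msg, "effect folds must be positive")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@dispersionSlope < 0)
    msg <- c(msg, "dispersionSlope must be non-negative")
  if (!identical(dim(object@classUtr5Fractions), c(3L, 2L)))
    msg <- c(msg, "classUtr5Fractions must be a 3x2 matrix")
  if (length(object@classProbs) != 3L || sum(object@classProbs) > 1 + 1e-12)
    msg <- c(msg, "classProbs must be 3 probabilities summing to <= 1")
  if (object@readLenFp < 1L || object@readLenMrna < 1L)
    msg <- c(msg, "read lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an [EffectConfig-class] for the read simulator
#'
#' Defaults describe a null experiment (no planted effects) at moderate depth
#' with mean-dependent negative-binomial noise; see the class documentation
#' for the meaning of each field.
#'
#' @param nGenes,meanDepth,dispersionSlope,exprSdLog,fracTxUp,fracTxDown
#'   see [EffectConfig-class].
#' @param txEffect,fracTeUp,fracTeDown,teEffect,utr5ReadFraction,classProbs
#'   see [EffectConfig-class].
#' @param classUtr5Fractions,kqeSlope,kqeSet,readLenFp,readLenMrna
#'   see [EffectConfig-class].
#' @param collapsePositions,mirrorStrand,seed see [EffectConfig-class].
#' @return a validated `EffectConfig` object.
#' @examples
#' cfg <- effectConfig(nGenes = 100, meanDepth = 50, seed = 1)
#' @export
effectConfig <- function(nGenes, meanDepth = 200, dispersionSlope = 0.3,
                         exprSdLog = 0.5,
                         fracTxUp = 0, fracTxDown = 0, txEffect = 4,
                         fracTeUp = 0, fracTeDown = 0, teEffect = 4,
                         utr5ReadFraction = 0.008,
                         classProbs = c(1, 1, 1) / 3,
                         classUtr5Fractions = rbind(
                           class1 = c(SD = 0.30, MetR = 0.05),
                           class2 = c(SD = 0.05, MetR = 0.30),
                           class3 = c(SD = 0.04, MetR = 0.04)),
                         kqeSlope = 0, kqeSet = character(0),
                         readLenFp = 28L, readLenMrna = 50L,
                         collapsePositions = TRUE, mirrorStrand = FALSE,
                         seed = 1L) {
  new("EffectConfig",
      nGenes = as.integer(nGenes), meanDepth = as.numeric(meanDepth),
      dispersionSlope = as.numeric(dispersionSlope),
      exprSdLog = as.numeric(exprSdLog),
      fracTxUp = fracTxUp, fracTxDown = fracTxDown, txEffect = txEffect,
      fracTeUp = fracTeUp, fracTeDown = fracTeDown, teEffect = teEffect,
      utr5ReadFraction = utr5ReadFraction,
      classProbs = as.numeric(classProbs),
      classUtr5Fractions = as.matrix(classUtr5Fractions),
      kqeSlope = kqeSlope, kqeSet = as.character(kqeSet),
      readLenFp = as.integer(readLenFp), readLenMrna = as.integer(readLenMrna),
      collapsePositions = collapsePositions, mirrorStrand = mirrorStrand,
      seed = as.integer(seed))
}

setMethod("show", "EffectConfig", function(object) {
  cat("EffectConfig:", object@nGenes, "genes, mean depth",
      object@meanDepth, "\n")
  cat("  NB dispersion slope:", object@dispersionSlope,
      "| expression sdlog:", object@exprSdLog, "\n")
  cat(sprintf("  planted tx: %.3f up / %.3f down x %g-fold\n",
              object@fracTxUp, object@fracTxDown, object@txEffect))
  cat(sprintf("  planted TE: %.3f up / %.3f down x %g-fold\n",
              object@fracTeUp, object@fracTeDown, object@teEffect))
  cat("  background 5'UTR footprint fraction:", object@utr5ReadFraction, "\n")
  if (object@kqeSlope != 0)
    cat("  KQE slope:", object@kqeSlope, "log2/unit frequency on",
        if (length(object@kqeSet)) paste(length(object@kqeSet), "genes")
        else "all genes", "\n")
  cat("  seed:", object@seed, "\n")
})

#' Per-gene, per-region, per-library read counts
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' the output of [buildCountTable()]. Rows are genes; the four columns are the
#' libraries SD/MetR x mRNA/footprint; assays `cds`, `utr5` and `utr3` hold
#' region-wise read counts (the `cds` assay already has the TSS exclusion
#' window applied). `colData` carries `condition`, `assayType` and
#' `libraryTotal` (the total read weight in the source file, assigned or not);
#' `metadata()$diagnostics` tallies unassigned, wrong-strand and ambiguous
#' reads per library.
#'
#' @aliases RiboCountExperiment-class
#' @exportClass RiboCountExperiment
setClass("RiboCountExperiment", contains = "SummarizedExperiment")

setValidity("RiboCountExperiment", function(object) {
  msg <- character()
  if (!all(c("cds", "utr5", "utr3") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays must include cds, utr5 and utr3")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "assayType", "libraryTotal") %in% colnames(cd)))
    msg <- c(msg, "colData must have condition, assayType, libraryTotal")
  for (a in intersect(c("cds", "utr5", "utr3"),
                      SummarizedExperiment::assayNames(object))) {
    m <- SummarizedExperiment::assay(object, a)
    if (any(m < 0)) msg <- c(msg, sprintf("assay %s has negative counts", a))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RiboCountExperiment", function(object) {
  cat("RiboCountExperiment:", nrow(object), "genes x", ncol(object),
      "libraries\n")
  cat("  libraries:", paste(colnames(object), collapse = ", "), "\n")
  cat("  library totals:",
      paste(SummarizedExperiment::colData(object)$libraryTotal,
            collapse = ", "), "\n")
})
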