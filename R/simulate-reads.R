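#' Simulate aligned reads for two conditions x two assays
#'
#' Draws per-gene read counts for the four libraries (SD/MetR x
#' mRNA/footprint) from a negative-binomial model with mean-dependent
#' dispersion (`var = mu + phi mu^2`, `phi = dispersionSlope / sqrt(mu)`),
#' applies the planted effects from `cfg`, places read 5' ends within each
#' gene, and returns the reads together with a ground-truth table.
#'
#' Count means: the SD mRNA mean is `meanDepth x expression_g` (lognormal
#' relative expression, mean 1); the MetR mRNA mean is additionally multiplied
#' by the gene's planted transcriptional fold change; footprint means carry
#' the transcriptional fold change times the planted
#' translational-efficiency fold change. If `kqeSlope` is nonzero, genes in
#' `kqeSet` (all genes when empty) have `log2(true_te_fc)` decremented by
#' `kqeSlope x` their combined K/Q/E codon frequency.
#'
#' Placement: mRNA read 5' ends are uniform over the whole transcript;
#' footprint P-site positions are uniform over the CDS except for a
#' per-condition fraction placed uniformly in the 5'UTR (the background
#' `utr5ReadFraction`, or the planted class pattern for class1/2/3 genes).
#' Emitted intervals are fixed-length BED-style reads whose 5' end is chosen
#' so that the quantifier's P-site offset (`psiteOffset`, footprints only)
#' recovers the placed position exactly.
#'
#' @param models gene model data.frame from [simulateGeneModels()]; must be
#'   non-overlapping. A `kqe_freq` column (or `sequences`) is required when
#'   `cfg@kqeSlope != 0`.
#' @param cfg an [EffectConfig-class] object.
#' @param sequences optional CDS [Biostrings::DNAStringSet] used to compute
#'   K/Q/E codon frequencies when `models` lacks a `kqe_freq` column.
#' @param psiteOffset P-site offset (nt) the downstream quantifier will apply
#'   to footprint reads.
#' @param withTallies also return the generator's per-gene region placement
#'   tallies (an oracle for the quantifier); disable to save time in large
#'   simulation sweeps.
#' @return a list with
#'   \describe{
#'     \item{reads}{named list of [GenomicRanges::GRanges] (`SD.mRNA`,
#'       `MetR.mRNA`, `SD.footprint`, `MetR.footprint`) with a `weight`
#'       metadata column (collapsed read multiplicity).}
#'     \item{truth}{data.frame `gene_id`, `true_tx_fc`, `true_te_fc`,
#'       `true_class` (class1/class2/class3/none), `in_kqe_set`.}
#'     \item{tallies}{data.frame of the generator's own per-gene, per-library
#'       region placements (`utr5`, `cds`, `utr3`, and `cds_excluded`, the
#'       CDS placements falling inside the default TSS exclusion window) —
#'       an oracle for the quantifier.}
#'   }
#' @examples
#' gm <- simulateGeneModels(20, seed = 1)
#' sim <- simulateReads(gm$models, effectConfig(20, meanDepth = 50, seed = 1))
#' sim$truth[1:3, ]
#' @export
simulateReads <- function(models, cfg, sequences = NULL, psiteOffset = 15L,
                          withTallies = TRUE) {
  stopifnot(is(cfg, "EffectConfig"))
  validObject(cfg)
  validateGeneModels(models, requireNonOverlapping = TRUE)
  n <- nrow(models)
  if (n != cfg@nGenes)
    stopf("models has %d genes but cfg expects %d", n, cfg@nGenes)

  kqeFreq <- NULL
  if (cfg@kqeSlope != 0) {
    if (!is.null(models$kqe_freq)) kqeFreq <- models$kqe_freq
    else if (!is.null(sequences))
      kqeFreq <- codonFrequencies(sequences)$freq_KQE[
        match(models$gene_id, names(sequences))]
    else stopf("kqeSlope != 0 needs models$kqe_freq or sequences")
  }

  withSeed(cfg@seed, {
    expr <- rlnorm(n, meanlog = -cfg@exprSdLog^2 / 2, sdlog = cfg@exprSdLog)

    ## planted effects
    txFc <- rep(1, n)
    nUp <- round(cfg@fracTxUp * n); nDown <- round(cfg@fracTxDown * n)
    pick <- sample.int(n, nUp + nDown)
    txFc[pick[seq_len(nUp)]] <- cfg@txEffect
    if (nDown > 0) txFc[pick[nUp + seq_len(nDown)]] <- 1 / cfg@txEffect

    teFc <- rep(1, n)
    nUp <- round(cfg@fracTeUp * n); nDown <- round(cfg@fracTeDown * n)
    pick <- sample.int(n, nUp + nDown)
    teUp <- pick[seq_len(nUp)]
    teFc[teUp] <- cfg@teEffect
    if (nDown > 0) teFc[pick[nUp + seq_len(nDown)]] <- 1 / cfg@teEffect

    ## loading classes among TE-up genes
    class <- rep("none", n)
    if (length(teUp)) {
      p <- cfg@classProbs
      class[teUp] <- sample(c("class1", "class2", "class3", "none"),
                            length(teUp), replace = TRUE,
                            prob = c(p, max(0, 1 - sum(p))))
    }
    fUtr5 <- cbind(SD = rep(cfg@utr5ReadFraction, n),
                   MetR = rep(cfg@utr5ReadFraction, n))
    for (k in 1:3) {
      cl <- class == paste0("class", k)
      fUtr5[cl, "SD"] <- cfg@classUtr5Fractions[k, 1]
      fUtr5[cl, "MetR"] <- cfg@classUtr5Fractions[k, 2]
    }

    ## KQE-dependent TE suppression
    inKqe <- rep(FALSE, n)
    if (cfg@kqeSlope != 0) {
      inKqe <- if (length(cfg@kqeSet)) models$gene_id %in% cfg@kqeSet
               else rep(TRUE, n)
      teFc[inKqe] <- 2^(log2(teFc[inKqe]) -
                          cfg@kqeSlope * kqeFreq[inKqe])
    }

    mu <- list(
      SD.mRNA = cfg@meanDepth * expr,
      MetR.mRNA = cfg@meanDepth * expr * txFc,
      SD.footprint = cfg@meanDepth * expr,
      MetR.footprint = cfg@meanDepth * expr * txFc * teFc)

    plus <- models$strand == "+"
    ext <- geneExtents(models)
    u5lo <- ifelse(plus, models$tss, models$cds_start)
    u5len <- utr5Length(models)
    cdslo <- ifelse(plus, models$cds_start, models$cds_end)
    cdslen <- cdsLength(models)

    drawCounts <- function(m) {
      if (cfg@dispersionSlope == 0) return(rpois(n, m))
      rnbinom(n, mu = m, size = sqrt(m) / cfg@dispersionSlope)
    }
    # uniform integer positions within [lo, lo + len)
    unif <- function(lo, len, times) {
      tot <- sum(times)
      rep(lo, times) + as.integer(floor(runif(tot) * rep(len, times)))
    }

    reads <- list(); tallies <- list()
    for (lib in LIBRARIES) {
      cond <- sub("\\..*", "", lib)
      assay <- sub(".*\\.", "", lib)
      cnt <- drawCounts(mu[[lib]])
      if (assay == "footprint") {
        f <- ifelse(u5len > 0, fUtr5[, cond], 0)
        nU <- rbinom(n, cnt, f)
        nC <- cnt - nU
        posU <- unif(u5lo, pmax(u5len, 1L), nU)
        posC <- unif(cdslo, cdslen, nC)
        pos <- c(posU, posC)
        geneIdx <- c(rep(seq_len(n), nU), rep(seq_len(n), nC))
        region <- rep(c("utr5", "cds"), c(sum(nU), sum(nC)))
      } else {
        pos <- unif(ext$lo, ext$hi - ext$lo, cnt)
        geneIdx <- rep(seq_len(n), cnt)
        region <- NULL
        if (withTallies) {
          # region of each placement, for the oracle tally
          p <- plus[geneIdx]
          cs <- models$cds_start[geneIdx]
          ce <- models$cds_end[geneIdx]
          region <- rep("utr3", length(pos))
          region[(p & pos < ce) | (!p & pos >= ce)] <- "cds"
          region[(p & pos < cs) | (!p & pos >= cs)] <- "utr5"
        }
      }

      if (withTallies)
        tallies[[lib]] <- .placementTally(geneIdx, region, pos, models, n,
                                          lib, psiteOffset)
      ## convert placed 5'/P-site positions (0-based) to BED intervals
      len <- if (assay == "footprint") cfg@readLenFp else cfg@readLenMrna
      off <- if (assay == "footprint") as.integer(psiteOffset) else 0L
      isPlus <- plus[geneIdx]
      bedStart <- integer(length(pos))
      bedStart[isPlus] <- pos[isPlus] - off
      bedStart[!isPlus] <- pos[!isPlus] + off + 1L - len
      chromIdx <- match(models$chrom[geneIdx], unique(models$chrom))
      strandCode <- 1L + !isPlus  # 1 = "+", 2 = "-"
      weight <- rep(1L, length(pos))
      if (cfg@collapsePositions && length(pos)) {
        key <- (bedStart * 2L + (strandCode - 1L)) +
          (chromIdx - 1L) * (4L * max(bedStart + len + 2L))
        o <- order(key)
        k <- key[o]
        firstIdx <- o[c(TRUE, k[-1] != k[-length(k)])]
        weight <- as.integer(tabulate(cumsum(c(TRUE, k[-1] != k[-length(k)]))))
        bedStart <- bedStart[firstIdx]
        strandCode <- strandCode[firstIdx]
        chromIdx <- chromIdx[firstIdx]
      }
      gr <- GenomicRanges::GRanges(
        seqnames = unique(models$chrom)[chromIdx],
        ranges = IRanges::IRanges(start = bedStart + 1L,
                                  width = len),
        strand = c("+", "-")[strandCode])
      gr$weight <- weight
      reads[[lib]] <- gr
    }

    truth <- data.frame(gene_id = models$gene_id, true_tx_fc = txFc,
                        true_te_fc = teFc, true_class = class,
                        in_kqe_set = inKqe, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth,
         tallies = if (withTallies) do.call(rbind, tallies) else NULL)
  })
}

# per-gene region tally of placed positions, including how many CDS
# placements fall inside the default 50-nt TSS exclusion window
.placementTally <- function(geneIdx, region, pos, models, n, lib,
                            psiteOffset, tssExclusion = 50L) {
  tab <- function(sel) tabulate(geneIdx[sel], nbins = n)
  plus <- (models$strand == "+")[geneIdx]
  tss <- models$tss[geneIdx]
  dist <- numeric(length(pos))
  dist[plus] <- pos[plus] - tss[plus]
  dist[!plus] <- (tss[!plus] - 1L) - pos[!plus]
  inExcl <- region == "cds" & dist < tssExclusion
  data.frame(gene_id = models$gene_id, library = lib,
             utr5 = tab(region == "utr5"), cds = tab(region == "cds"),
             utr3 = tab(region == "utr3"), cds_excluded = tab(inExcl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a complete ground-truthed experiment
#'
#' Convenience wrapper: simulates gene models and CDS sequences (seeded with
#' `cfg@seed`), then reads (seeded with `cfg@seed + 1`).
#'
#' @param cfg an [EffectConfig-class].
#' @param utr5Mean,cdsMeanCodons,utr3Mean,kqeBeta passed to
#'   [simulateGeneModels()].
#' @param psiteOffset passed to [simulateReads()].
#' @return a list with `models`, `sequences`, `reads`, `truth`, `tallies`.
#' @export
simulateExperiment <- function(cfg, utr5Mean = 60, cdsMeanCodons = 300,
                               utr3Mean = 120, kqeBeta = c(9, 41),
                               psiteOffset = 15L) {
  gm <- simulateGeneModels(cfg@nGenes, utr5Mean = utr5Mean,
                           cdsMeanCodons = cdsMeanCodons,
                           utr3Mean = utr3Mean, kqeBeta = kqeBeta,
                           mirrorStrand = cfg@mirrorStrand, seed = cfg@seed)
  cfg2 <- cfg
  cfg2@seed <- cfg@seed + 1L
  sim <- simulateReads(gm$models, cfg2, sequences = gm$sequences,
                       psiteOffset = psiteOffset)
  c(gm, sim)
}

#' Read / write BED6 read files
#'
#' BED6 (0-based half-open) via `rtracklayer`; the score column carries the
#' collapsed read multiplicity (`weight`). On import, missing or zero scores
#' are treated as weight 1 (one line per read).
#'
#' @param gr a [GenomicRanges::GRanges] with a `weight` metadata column.
#' @param path file path.
#' @return `readBed` returns a `GRanges` with a `weight` column.
#' @export
writeBed <- function(gr, path) {
  out <- gr
  out$score <- if (!is.null(out$weight)) out$weight else 1L
  out$weight <- NULL
  names(out) <- NULL
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stopf("malformed BED file %s: %s",
                                           path, conditionMessage(e)))
  w <- gr$score
  if (is.null(w)) w <- rep(1L, length(gr))
  w[is.na(w) | w < 1] <- 1L
  gr$weight <- as.integer(w)
  gr$score <- NULL
  gr
}
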