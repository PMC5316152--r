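#' Gene model tables
#'
#' Gene models are plain data.frames with columns `gene_id`, `chrom`,
#' `strand`, `tss`, `cds_start`, `cds_end`, `utr3_end`. All coordinates are
#' 0-based, half-open boundaries stated in transcript order:
#'
#' * plus strand: `tss <= cds_start < cds_end <= utr3_end`; the 5'UTR is
#'   `[tss, cds_start)`, the CDS `[cds_start, cds_end)`, the 3'UTR
#'   `[cds_end, utr3_end)`.
#' * minus strand the ordering mirrors (`tss >= cds_start > cds_end >=
#'   utr3_end`): the 5'UTR occupies genomic `[cds_start, tss)`, the CDS
#'   `[cds_end, cds_start)` and the 3'UTR `[utr3_end, cds_end)`; the
#'   transcription start site is the base at `tss - 1`.
#'
#' CDS lengths are divisible by 3 and at least 30 nt.
#'
#' @name gene-models
NULL

KQE_CODONS <- c("AAA", "AAG", "CAA", "CAG", "GAA", "GAG")
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  STOP_CODONS)
NON_KQE_SENSE <- setdiff(SENSE_CODONS, KQE_CODONS)

#' Validate a gene model table
#'
#' Checks column presence, transcript-order coordinate invariants, CDS length
#' divisibility, and (optionally) that genes do not overlap on any chromosome.
#'
#' @param models gene model data.frame (see [gene-models]).
#' @param requireNonOverlapping error if two genes on a chromosome overlap.
#' @return `models`, invisibly; errors describe the first offending gene.
#' @export
validateGeneModels <- function(models, requireNonOverlapping = FALSE) {
  need <- c("gene_id", "chrom", "strand", "tss", "cds_start", "cds_end",
            "utr3_end")
  miss <- setdiff(need, colnames(models))
  if (length(miss)) stopf("gene model table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(models$gene_id))
    stopf("duplicated gene_id: %s",
          models$gene_id[duplicated(models$gene_id)][1])
  if (!all(models$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  plus <- models$strand == "+"
  ok <- ifelse(plus,
    models$tss <= models$cds_start & models$cds_start < models$cds_end &
      models$cds_end <= models$utr3_end,
    models$tss >= models$cds_start & models$cds_start > models$cds_end &
      models$cds_end >= models$utr3_end)
  if (!all(ok))
    stopf("coordinate ordering violated for gene %s", models$gene_id[!ok][1])
  len <- abs(models$cds_end - models$cds_start)
  bad <- len %% 3L != 0L | len < 30L
  if (any(bad))
    stopf("CDS of gene %s is not a multiple of 3 of at least 30 nt",
          models$gene_id[bad][1])
  if (requireNonOverlapping) {
    ext <- geneExtents(models)
    for (ch in unique(ext$chrom)) {
      e <- ext[ext$chrom == ch, ]
      e <- e[order(e$lo), ]
      if (nrow(e) > 1 && any(e$lo[-1] < e$hi[-nrow(e)]))
        stopf("overlapping genes on %s", ch)
    }
  }
  invisible(models)
}

# genomic [lo, hi) extent of each gene (all regions)
geneExtents <- function(models) {
  data.frame(gene_id = models$gene_id, chrom = models$chrom,
             lo = pmin(models$tss, models$utr3_end),
             hi = pmax(models$tss, models$utr3_end),
             strand = models$strand, stringsAsFactors = FALSE)
}

utr5Length <- function(models) abs(models$tss - models$cds_start)
cdsLength <- function(models) abs(models$cds_end - models$cds_start)
utr3Length <- function(models) abs(models$utr3_end - models$cds_end)

#' Simulate non-overlapping gene models with CDS sequences
#'
#' Lays `nGenes` genes end to end (separated by `gap` nt) on a synthetic
#' chromosome and draws region lengths from gamma distributions: 5'UTR mean
#' `utr5Mean` (may be 0), CDS length `cdsMeanCodons` codons on average (at
#' least 10), 3'UTR mean `utr3Mean`. Each CDS sequence starts with ATG, ends
#' with a stop codon and contains no internal stop; internal codons are drawn
#' with a per-gene combined K/Q/E codon frequency sampled from
#' `Beta(kqeBeta[1], kqeBeta[2])` (default mean 0.18, sd 0.054, yeast-like),
#' so codon composition varies across genes.
#'
#' @param nGenes number of genes (>= 1).
#' @param utr5Mean,cdsMeanCodons,utr3Mean positive length parameters (nt,
#'   codons, nt).
#' @param kqeBeta two positive Beta shape parameters for the per-gene K/Q/E
#'   codon frequency.
#' @param gap intergenic spacing in nt.
#' @param chrom chromosome name.
#' @param mirrorStrand place every second gene on the minus strand.
#' @param seed integer seed; same seed, same output.
#' @return a list with `models` (gene model data.frame, plus a `kqe_freq`
#'   column with the realized combined K/Q/E codon frequency) and `sequences`
#'   (a [Biostrings::DNAStringSet] of CDS sequences named by `gene_id`).
#' @examples
#' gm <- simulateGeneModels(5, seed = 1)
#' gm$models
#' @export
simulateGeneModels <- function(nGenes, utr5Mean = 60, cdsMeanCodons = 300,
                               utr3Mean = 120, kqeBeta = c(9, 41),
                               gap = 200L, chrom = "chrS",
                               mirrorStrand = FALSE, seed = 1L) {
  if (nGenes < 1) stopf("nGenes must be >= 1")
  if (utr5Mean < 0 || cdsMeanCodons <= 0 || utr3Mean < 0)
    stopf("length parameters must be positive")
  if (any(kqeBeta <= 0)) stopf("kqeBeta shapes must be positive")
  withSeed(seed, {
    utr5 <- as.integer(round(rgamma(nGenes, shape = 2,
                                    scale = max(utr5Mean, 1e-9) / 2)))
    codons <- pmax(10L, as.integer(round(
      rgamma(nGenes, shape = 4, scale = cdsMeanCodons / 4))))
    utr3 <- as.integer(round(rgamma(nGenes, shape = 2,
                                    scale = max(utr3Mean, 1e-9) / 2)))
    cds <- 3L * codons
    strand <- rep("+", nGenes)
    if (mirrorStrand && nGenes > 1) strand[seq(2, nGenes, by = 2)] <- "-"

    total <- utr5 + cds + utr3
    lo <- 1000L + c(0L, cumsum(total[-nGenes] + gap))[seq_len(nGenes)]
    hi <- lo + total
    plus <- strand == "+"
    tss <- ifelse(plus, lo, hi)
    cds_start <- ifelse(plus, lo + utr5, hi - utr5)
    cds_end <- ifelse(plus, lo + utr5 + cds, hi - utr5 - cds)
    utr3_end <- ifelse(plus, hi, lo)
    ids <- sprintf("g%04d", seq_len(nGenes))

    kqe <- rbeta(nGenes, kqeBeta[1], kqeBeta[2])
    nInternal <- codons - 2L
    geneOf <- rep.int(seq_len(nGenes), nInternal)
    isKqe <- runif(length(geneOf)) < kqe[geneOf]
    internal <- character(length(geneOf))
    internal[isKqe] <- KQE_CODONS[sample.int(6L, sum(isKqe), replace = TRUE)]
    internal[!isKqe] <- NON_KQE_SENSE[
      sample.int(length(NON_KQE_SENSE), sum(!isKqe), replace = TRUE)]
    mid <- vapply(split(internal, factor(geneOf, levels = seq_len(nGenes))),
                  paste, character(1), collapse = "")
    seqs <- paste0("ATG", mid,
                   STOP_CODONS[sample.int(3L, nGenes, replace = TRUE)])
    sequences <- Biostrings::DNAStringSet(setNames(seqs, ids))

    models <- data.frame(
      gene_id = ids, chrom = chrom, strand = strand,
      tss = as.integer(tss), cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end), utr3_end = as.integer(utr3_end),
      stringsAsFactors = FALSE)
    models$kqe_freq <- codonFrequencies(sequences)$freq_KQE
    validateGeneModels(models, requireNonOverlapping = TRUE)
    list(models = models, sequences = sequences)
  })
}

#' Read / write a gene model table
#'
#' TSV with header `gene_id, chrom, strand, tss, cds_start, cds_end,
#' utr3_end` (extra columns are preserved).
#'
#' @param path file path.
#' @return `readGeneModels` returns a validated gene model data.frame.
#' @export
readGeneModels <- function(path) {
  validateGeneModels(readTsv(path))
}

#' @rdname readGeneModels
#' @param models gene model data.frame.
#' @export
writeGeneModels <- function(models, path) {
  validateGeneModels(models)
  writeTsv(models, path)
}
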