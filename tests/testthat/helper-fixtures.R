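# shared fixture builders and independent oracles

# one plus-strand gene model row
toyModel <- function(gene_id = "g1", tss = 0L, cds_start = 60L,
                     cds_end = 360L, utr3_end = 420L, strand = "+",
                     chrom = "chrT") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = tss, cds_start = cds_start, cds_end = cds_end,
             utr3_end = utr3_end, stringsAsFactors = FALSE)
}

# GRanges reads from 0-based half-open BED coordinates
bedReads <- function(start, end, strand = "+", weight = 1L,
                     chrom = "chrT") {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(start)),
                               IRanges::IRanges(start + 1L, end),
                               strand = rep_len(strand, length(start)))
  gr$weight <- as.integer(rep_len(weight, length(gr)))
  gr
}

# a RiboCountExperiment with prescribed CDS counts (matrix genes x 4
# libraries) and library totals, bypassing read counting
countExperiment <- function(cds, utr5 = NULL, utr3 = NULL, totals = NULL,
                            models = NULL) {
  libs <- c("SD.mRNA", "MetR.mRNA", "SD.footprint", "MetR.footprint")
  colnames(cds) <- libs
  if (is.null(utr5)) utr5 <- cds * 0L
  if (is.null(utr3)) utr3 <- cds * 0L
  colnames(utr5) <- colnames(utr3) <- libs
  if (is.null(totals)) totals <- colSums(cds) + colSums(utr5) + colSums(utr3)
  if (is.null(models)) {
    n <- nrow(cds)
    models <- data.frame(
      gene_id = rownames(cds), chrom = "chrT", strand = "+",
      tss = seq_len(n) * 1000L, cds_start = seq_len(n) * 1000L + 60L,
      cds_end = seq_len(n) * 1000L + 360L,
      utr3_end = seq_len(n) * 1000L + 420L, stringsAsFactors = FALSE)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cds = cds, utr5 = utr5, utr3 = utr3),
    rowData = S4Vectors::DataFrame(models, row.names = rownames(cds)),
    colData = S4Vectors::DataFrame(
      condition = sub("\\..*", "", libs),
      assayType = sub(".*\\.", "", libs),
      libraryTotal = as.numeric(totals), row.names = libs))
  methods::new("RiboCountExperiment", se)
}

# brute-force per-read counting oracle: loops over reads and genes,
# independent of the package's vectorized engine
bruteForceCounts <- function(gr, models, assay, offset = 15L,
                             tssExclusion = 50L) {
  out <- matrix(0L, nrow(models), 3,
                dimnames = list(models$gene_id, c("cds", "utr5", "utr3")))
  for (i in seq_along(gr)) {
    s0 <- GenomicRanges::start(gr)[i] - 1L
    e0 <- GenomicRanges::end(gr)[i]
    st <- as.character(GenomicRanges::strand(gr)[i])
    ch <- as.character(GenomicRanges::seqnames(gr)[i])
    off <- if (assay == "footprint") offset else 0L
    p <- if (st == "+") s0 + off else e0 - 1L - off
    w <- gr$weight[i]
    for (j in seq_len(nrow(models))) {
      m <- models[j, ]
      if (m$chrom != ch || m$strand != st) next
      if (m$strand == "+") {
        if (p >= m$tss && p < m$cds_start) out[j, "utr5"] <- out[j, "utr5"] + w
        if (p >= m$cds_start && p < m$cds_end && (p - m$tss) >= tssExclusion)
          out[j, "cds"] <- out[j, "cds"] + w
        if (p >= m$cds_end && p < m$utr3_end)
          out[j, "utr3"] <- out[j, "utr3"] + w
      } else {
        if (p >= m$cds_start && p < m$tss) out[j, "utr5"] <- out[j, "utr5"] + w
        if (p >= m$cds_end && p < m$cds_start &&
            ((m$tss - 1L) - p) >= tssExclusion)
          out[j, "cds"] <- out[j, "cds"] + w
        if (p >= m$utr3_end && p < m$cds_end)
          out[j, "utr3"] <- out[j, "utr3"] + w
      }
    }
  }
  out
}

# exact rank-sum z by full permutation enumeration (mid-p convention),
# feasible for <= ~12 genes
exactRankZ <- function(values, members) {
  r <- rank(values)
  inSet <- names(values) %in% members
  m <- sum(inSet)
  obs <- sum(r[inSet])
  all <- utils::combn(length(values), m)
  sums <- colSums(matrix(r[all], nrow = m))
  pOne <- (sum(sums > obs) + 0.5 * sum(sums == obs)) / length(sums)
  stats::qnorm(1 - pOne)
}

# mirror a model table and reads through position C - x on one chromosome
mirrorModels <- function(models, C) {
  data.frame(gene_id = models$gene_id, chrom = models$chrom,
             strand = ifelse(models$strand == "+", "-", "+"),
             tss = C - models$tss, cds_start = C - models$cds_start,
             cds_end = C - models$cds_end, utr3_end = C - models$utr3_end,
             stringsAsFactors = FALSE)
}

mirrorReads <- function(gr, C) {
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges((C - e0) + 1L, C - s0),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                    "-", "+"))
  out$weight <- gr$weight
  out
}
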