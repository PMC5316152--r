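#' Assign each read its counting position
#'
#' Footprint reads are counted at their P-site: the biological 5' end shifted
#' `offset` nt toward the 3' end (plus strand: BED start + offset; minus
#' strand: (BED end - 1) - offset). mRNA reads are counted at their
#' unshifted biological 5' end. Positions are returned 0-based.
#'
#' @param read a [GenomicRanges::GRanges] of reads (any length).
#' @param assay "mRNA" or "footprint".
#' @param offset P-site offset in nt (footprint only), non-negative and
#'   smaller than every read length.
#' @return integer vector of 0-based genomic counting positions.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 128), "+")
#' assignPosition(gr, "footprint")  # 115
#' @export
assignPosition <- function(read, assay = c("mRNA", "footprint"),
                           offset = 15L) {
  assay <- match.arg(assay)
  if (offset < 0) stopf("offset must be non-negative")
  start0 <- GenomicRanges::start(read) - 1L
  end0 <- GenomicRanges::end(read)  # half-open upper bound
  minus <- as.logical(GenomicRanges::strand(read) == "-")
  if (assay == "mRNA") offset <- 0L
  if (any(offset >= end0 - start0))
    stopf("offset %d is not smaller than every read length", offset)
  as.integer(ifelse(minus, end0 - 1L - offset, start0 + offset))
}

# region classification of 0-based positions against gene models (rows
# aligned with `geneIdx`). Integer codes: 1 cds (exclusion window applied),
# 2 utr5, 3 utr3, 4 cds-but-excluded, 0 outside any region.
.classifyPositions <- function(pos, models, geneIdx, tssExclusion, anchor) {
  plus <- (models$strand == "+")[geneIdx]
  tss <- models$tss[geneIdx]
  cs <- models$cds_start[geneIdx]
  ce <- models$cds_end[geneIdx]
  u3 <- models$utr3_end[geneIdx]
  # transcript-oriented signed coordinates: flip the axis for minus strand
  sgn <- 1 - 2 * !plus
  tpos <- sgn * pos
  ttss <- sgn * tss + !plus   # minus strand: [a, b) maps to [-b + 1, -a + 1)
  tcs <- sgn * cs + !plus
  tce <- sgn * ce + !plus
  tu3 <- sgn * u3 + !plus
  out <- integer(length(pos))
  out[tpos >= tce & tpos < tu3] <- 3L
  out[tpos >= ttss & tpos < tcs] <- 2L
  inCds <- tpos >= tcs & tpos < tce
  anch <- if (anchor == "tss") ttss else tcs
  out[inCds] <- c(4L, 1L)[((tpos - anch)[inCds] >= tssExclusion) + 1L]
  out
}

# core counting engine for one library: positions -> per-gene region counts.
# Disjoint gene models (the usual case) are matched by sorted interval
# lookup; overlapping annotations fall back to findOverlaps, where a
# position hitting more than one gene is assigned to neither (ambiguous).
.countLibrary <- function(gr, assay, models, offset, tssExclusion, anchor) {
  n <- nrow(models)
  zero <- data.frame(gene_id = models$gene_id,
                     cds = integer(n), utr5 = integer(n), utr3 = integer(n),
                     stringsAsFactors = FALSE)
  diag <- c(unassigned = 0, wrong_strand = 0, ambiguous = 0)
  total <- if (length(gr)) sum(gr$weight) else 0L
  if (!length(gr))
    return(list(counts = zero, diagnostics = diag, total = total))

  pos <- assignPosition(gr, assay, offset)
  w <- gr$weight
  posChrom <- as.vector(GenomicRanges::seqnames(gr))
  posStrand <- as.vector(GenomicRanges::strand(gr))
  ext <- geneExtents(models)
  chroms <- unique(ext$chrom)
  span <- max(ext$hi) + 2

  disjoint <- TRUE
  for (ch in chroms) {
    e <- ext[ext$chrom == ch, ]
    o <- order(e$lo)
    if (nrow(e) > 1 && any(e$lo[o][-1] < e$hi[o][-nrow(e)])) {
      disjoint <- FALSE
      break
    }
  }

  if (disjoint) {
    # chromosome-offset keys linearize (chrom, pos) into one axis
    chIdx <- match(posChrom, chroms)
    posKey <- (chIdx - 1) * span + pos
    geneLo <- (match(ext$chrom, chroms) - 1) * span + ext$lo
    geneHi <- (match(ext$chrom, chroms) - 1) * span + ext$hi
    o <- order(geneLo)
    slot <- findInterval(posKey, geneLo[o])
    geneIdx <- ifelse(slot >= 1 & !is.na(chIdx), o[pmax(slot, 1)], NA)
    hit <- !is.na(geneIdx) & posKey < geneHi[pmax(geneIdx, 1, na.rm = TRUE)]
    hit[is.na(hit)] <- FALSE
    diag["unassigned"] <- sum(w[!hit])
    keep <- which(hit)
    geneIdx <- geneIdx[keep]
  } else {
    extGR <- GenomicRanges::GRanges(ext$chrom,
                                    IRanges::IRanges(ext$lo + 1L, ext$hi),
                                    strand = ext$strand)
    posGR <- GenomicRanges::GRanges(posChrom,
                                    IRanges::IRanges(pos + 1L, pos + 1L))
    ov <- GenomicRanges::findOverlaps(posGR, extGR, ignore.strand = TRUE)
    nHits <- tabulate(S4Vectors::queryHits(ov), nbins = length(gr))
    diag["unassigned"] <- sum(w[nHits == 0])
    ambig <- nHits > 1
    diag["ambiguous"] <- sum(w[ambig])
    qh <- S4Vectors::queryHits(ov)
    keep <- qh[!ambig[qh]]
    geneIdx <- S4Vectors::subjectHits(ov)[!ambig[qh]]
  }

  sameStrand <- posStrand[keep] == models$strand[geneIdx]
  diag["wrong_strand"] <- sum(w[keep[!sameStrand]])
  keep <- keep[sameStrand]; geneIdx <- geneIdx[sameStrand]

  region <- .classifyPositions(pos[keep], models, geneIdx, tssExclusion,
                               anchor)
  cnt <- zero
  wk <- as.numeric(w[keep])
  for (code in 1:3) {
    sel <- region == code
    cnt[[c("cds", "utr5", "utr3")[code]]] <- as.integer(
      rowsum(c(wk[sel], numeric(n)), c(geneIdx[sel], seq_len(n)))[, 1])
  }
  list(counts = cnt, diagnostics = diag, total = total)
}

#' Count one gene's reads by region
#'
#' Applies the P-site offset (footprints) and tallies assigned positions into
#' the gene's CDS, 5'UTR and 3'UTR. CDS counting honours the TSS exclusion
#' window: a position contributes to `cds` only if it lies at least
#' `tssExclusion` nt downstream of the transcription start site in transcript
#' coordinates (`anchor = "cds"` instead anchors the window at the start
#' codon). UTR counting ignores the window. Reads on the wrong strand are
#' ignored and reported in the `diagnostics` attribute.
#'
#' @param reads [GenomicRanges::GRanges] with a `weight` column (weight 1 is
#'   assumed when absent).
#' @param model a single-row gene model data.frame.
#' @param assay "mRNA" or "footprint".
#' @param offset P-site offset (nt).
#' @param tssExclusion exclusion window length (nt).
#' @param anchor "tss" (default) or "cds": where the exclusion window starts.
#' @return named integer vector `c(cds, utr5, utr3)` with a `diagnostics`
#'   attribute.
#' @export
countGene <- function(reads, model, assay = c("mRNA", "footprint"),
                      offset = 15L, tssExclusion = 50L,
                      anchor = c("tss", "cds")) {
  assay <- match.arg(assay); anchor <- match.arg(anchor)
  stopifnot(nrow(model) == 1)
  validateGeneModels(model)
  if (is.null(reads$weight)) reads$weight <- rep(1L, length(reads))
  res <- .countLibrary(reads, assay, model, offset, tssExclusion, anchor)
  out <- c(cds = res$counts$cds, utr5 = res$counts$utr5,
           utr3 = res$counts$utr3)
  attr(out, "diagnostics") <- res$diagnostics
  out
}

#' Build the per-gene, per-region count table
#'
#' Counts all four libraries against the gene models and assembles a
#' [RiboCountExperiment-class]: rows are genes, columns the libraries
#' `SD.mRNA`, `MetR.mRNA`, `SD.footprint`, `MetR.footprint`, assays `cds`
#' (TSS exclusion applied), `utr5` and `utr3`. `libraryTotal` is the total
#' read weight of each input file whether assigned or not. Positions hitting
#' no gene, the wrong strand, or more than one gene are tallied per library
#' in `metadata()$diagnostics` (ambiguous positions are assigned to no gene).
#'
#' @param reads named list (names `SD.mRNA`, `MetR.mRNA`, `SD.footprint`,
#'   `MetR.footprint`) of read `GRanges` with `weight` columns, or a named
#'   character vector of BED6 paths read via [readBed()].
#' @param models gene model data.frame.
#' @param offset,tssExclusion,anchor see [countGene()].
#' @return a [RiboCountExperiment-class].
#' @export
buildCountTable <- function(reads, models, offset = 15L, tssExclusion = 50L,
                            anchor = c("tss", "cds")) {
  anchor <- match.arg(anchor)
  validateGeneModels(models)
  if (is.character(reads)) reads <- lapply(reads, readBed)
  miss <- setdiff(LIBRARIES, names(reads))
  if (length(miss))
    stopf("reads must cover all four libraries; missing: %s",
          paste(miss, collapse = ", "))

  n <- nrow(models)
  mk <- function() matrix(0L, n, 4, dimnames = list(models$gene_id, LIBRARIES))
  cds <- mk(); utr5 <- mk(); utr3 <- mk()
  totals <- setNames(numeric(4), LIBRARIES)
  diags <- list()
  for (lib in LIBRARIES) {
    assay <- sub(".*\\.", "", lib)
    gr <- reads[[lib]]
    if (is.null(gr$weight)) gr$weight <- rep(1L, length(gr))
    res <- .countLibrary(gr, assay, models, offset, tssExclusion, anchor)
    cds[, lib] <- res$counts$cds
    utr5[, lib] <- res$counts$utr5
    utr3[, lib] <- res$counts$utr3
    totals[lib] <- res$total
    diags[[lib]] <- res$diagnostics
  }
  if (any(totals == 0))
    warning("degenerate input: zero library total in ",
            paste(LIBRARIES[totals == 0], collapse = ", "))

  colData <- S4Vectors::DataFrame(
    condition = sub("\\..*", "", LIBRARIES),
    assayType = sub(".*\\.", "", LIBRARIES),
    libraryTotal = as.numeric(totals),
    row.names = LIBRARIES)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cds = cds, utr5 = utr5, utr3 = utr3),
    rowData = S4Vectors::DataFrame(models, row.names = models$gene_id),
    colData = colData,
    metadata = list(diagnostics = do.call(rbind, diags),
                    parameters = list(offset = offset,
                                      tssExclusion = tssExclusion,
                                      anchor = anchor)))
  methods::new("RiboCountExperiment", se)
}

#' Accessors for [RiboCountExperiment-class]
#'
#' `cdsCounts`, `utr5Counts` and `utr3Counts` return the per-gene x library
#' count matrices; `libraryTotals` the named per-library total read weights.
#'
#' @param x a `RiboCountExperiment`.
#' @return matrix (counts) or named numeric vector (totals).
#' @export
cdsCounts <- function(x) SummarizedExperiment::assay(x, "cds")

#' @rdname cdsCounts
#' @export
utr5Counts <- function(x) SummarizedExperiment::assay(x, "utr5")

#' @rdname cdsCounts
#' @export
utr3Counts <- function(x) SummarizedExperiment::assay(x, "utr3")

#' @rdname cdsCounts
#' @export
libraryTotals <- function(x)
  setNames(SummarizedExperiment::colData(x)$libraryTotal, colnames(x))

#' Write a count table as TSV
#'
#' One row per gene with region counts for each library; per-library totals
#' are repeated as `total_<library>` columns so the file round-trips
#' losslessly.
#'
#' @param x a [RiboCountExperiment-class].
#' @param path output path.
#' @export
writeCountTable <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (lib in colnames(x)) {
    df[[paste0("cds_", lib)]] <- cdsCounts(x)[, lib]
    df[[paste0("utr5_", lib)]] <- utr5Counts(x)[, lib]
    df[[paste0("utr3_", lib)]] <- utr3Counts(x)[, lib]
  }
  for (lib in colnames(x))
    df[[paste0("total_", lib)]] <- libraryTotals(x)[lib]
  writeTsv(df, path)
}
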