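#' 5'UTR-to-CDS footprint ratio
#'
#' Plain ratio of footprint counts; undefined (NA) when the CDS count is
#' zero, in which case the gene is excluded from ratio summaries.
#'
#' @param utr5Count,cdsCount non-negative integer counts (vectorized).
#' @return numeric ratio, `NA` where `cdsCount == 0`.
#' @export
utrCdsRatio <- function(utr5Count, cdsCount) {
  if (any(utr5Count < 0) || any(cdsCount < 0)) stopf("counts must be >= 0")
  ifelse(cdsCount == 0, NA_real_, utr5Count / cdsCount)
}

#' Classify a 5'UTR ribosome-loading change
#'
#' Compares the library-normalized fold change of CDS footprints against that
#' of 5'UTR footprints on the log2 scale: `d = log2(fc_cds) - log2(fc_utr5)`.
#' Genes whose coding region gains footprints at least `delta` log2 units
#' faster than the 5'UTR are class1 (extra initiation at the canonical start,
#' the GCN4-like pattern); genes whose 5'UTR gains faster are class2
#' (non-canonical loading upstream, XBP1-like); the remainder, within the
#' diagonal band, are class3 (uniform change).
#'
#' @param fcUtr5,fcCds positive fold changes (vectorized).
#' @param delta half-width of the diagonal band in log2 units (default 1,
#'   i.e. two-fold).
#' @return character vector: "class1", "class2" or "class3".
#' @export
classifyLoading <- function(fcUtr5, fcCds, delta = 1) {
  if (any(fcUtr5 <= 0) || any(fcCds <= 0)) stopf("folds must be positive")
  if (delta <= 0) stopf("delta must be positive")
  d <- log2(fcCds) - log2(fcUtr5)
  ifelse(d > delta, "class1", ifelse(d < -delta, "class2", "class3"))
}

#' Per-gene 5'UTR occupancy table with loading classes
#'
#' For every gene with footprint counts, computes the 5'UTR/CDS footprint
#' ratio in each condition, the library-normalized fold changes of the two
#' regions (pseudocount applied before the ratio), the TE group (up: te_z >
#' `teZCutoff`; down: te_z < -`teZCutoff`; other), and — for TE-up genes with
#' at least `minEvidence` footprints (5'UTR + CDS) in each condition — the
#' loading class from [classifyLoading()]. Counts come from the `utr5` and
#' `cds` assays of the count table; the TSS exclusion window applies to the
#' CDS counts only (5'UTR occupancy is the signal of interest here, so it is
#' never masked).
#'
#' @param counts a [RiboCountExperiment-class].
#' @param te TE table from [teTable()].
#' @param delta diagonal band half-width, log2 units (default 1).
#' @param teZCutoff TE z-score cutoff defining the up/down groups (default 2).
#' @param minEvidence minimum utr5 + cds footprints per condition for class
#'   assignment (default 16).
#' @param pseudocount added to region counts before fold changes (default 0.5).
#' @return data.frame `gene_id, ratio_sd, ratio_metr, fc_utr5, fc_cds,
#'   utr5_length, te_group, loading_class`.
#' @export
utrTable <- function(counts, te, delta = 1, teZCutoff = 2,
                     minEvidence = 16L, pseudocount = 0.5) {
  models <- as.data.frame(SummarizedExperiment::rowData(counts))
  u5 <- utr5Counts(counts); cc <- cdsCounts(counts)
  tot <- libraryTotals(counts)
  uS <- u5[, "SD.footprint"]; uM <- u5[, "MetR.footprint"]
  cS <- cc[, "SD.footprint"]; cM <- cc[, "MetR.footprint"]
  nS <- tot["SD.footprint"]; nM <- tot["MetR.footprint"]

  fcU <- ((uM + pseudocount) / nM) / ((uS + pseudocount) / nS)
  fcC <- ((cM + pseudocount) / nM) / ((cS + pseudocount) / nS)

  tz <- setNames(te$te_z, te$gene_id)[rownames(cc)]
  group <- rep("other", nrow(cc))
  group[!is.na(tz) & tz > teZCutoff] <- "up"
  group[!is.na(tz) & tz < -teZCutoff] <- "down"

  cls <- rep("unassigned", nrow(cc))
  eligible <- group == "up" &
    (uS + cS) >= minEvidence & (uM + cM) >= minEvidence
  if (any(eligible))
    cls[eligible] <- classifyLoading(fcU[eligible], fcC[eligible], delta)

  data.frame(gene_id = rownames(cc),
             ratio_sd = utrCdsRatio(uS, cS),
             ratio_metr = utrCdsRatio(uM, cM),
             fc_utr5 = fcU, fc_cds = fcC,
             utr5_length = utr5Length(models),
             te_group = group, loading_class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled and median 5'UTR/CDS ratios by TE group
#'
#' Summarizes [utrTable()] output per TE group and condition: the pooled
#' ratio (sum of 5'UTR counts over sum of CDS counts) and the median of
#' per-gene ratios (genes with zero CDS counts excluded). Designated outlier
#' genes — e.g. a GCN4-like gene whose 5'UTR occupancy collapses under
#' restriction — can be excluded by id.
#'
#' @param records output of [utrTable()].
#' @param counts the [RiboCountExperiment-class] the records came from.
#' @param excludeIds gene ids to drop before summarizing.
#' @return data.frame `te_group, condition, n_genes, pooled_ratio,
#'   median_ratio`; groups with no genes are absent.
#' @export
groupRatioSummary <- function(records, counts, excludeIds = character()) {
  keep <- !(records$gene_id %in% excludeIds)
  records <- records[keep, , drop = FALSE]
  u5 <- utr5Counts(counts)[records$gene_id, , drop = FALSE]
  cc <- cdsCounts(counts)[records$gene_id, , drop = FALSE]
  rows <- list()
  for (g in c("up", "down", "other")) {
    sel <- records$te_group == g
    if (!any(sel)) next
    for (cond in CONDITIONS) {
      lib <- paste0(cond, ".footprint")
      ratios <- if (cond == "SD") records$ratio_sd[sel]
                else records$ratio_metr[sel]
      rows[[paste(g, cond)]] <- data.frame(
        te_group = g, condition = cond, n_genes = sum(sel),
        pooled_ratio = sum(u5[sel, lib]) / sum(cc[sel, lib]),
        median_ratio = median(ratios, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
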