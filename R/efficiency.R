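#' Translational-efficiency change
#'
#' The TE change of a gene is the ratio of its footprint fold change to its
#' mRNA fold change: a pure transcriptional change (both folds equal) gives
#' 1, a gene whose ribosome occupancy rises beyond its transcript level gives
#' a ratio above 1.
#'
#' @param fcFp footprint fold change(s), > 0.
#' @param fcMrna mRNA fold change(s), > 0.
#' @return te_ratio = fcFp / fcMrna.
#' @examples
#' teChange(4, 2)  # 2
#' @export
teChange <- function(fcFp, fcMrna) {
  if (any(fcFp <= 0) || any(fcMrna <= 0))
    stopf("fold changes must be positive")
  fcFp / fcMrna
}

#' Fill translational-efficiency z-scores
#'
#' `te_z = log2_te / SD(log2_te)` over the included genes (sample SD, n-1).
#' The z-score is not mean-centered by default — median-normalized fold
#' changes already center log2 TE near zero — but `center = TRUE` subtracts
#' the mean first. If the SD is below 1e-12 all z-scores are 0.
#'
#' @param records data.frame with a `log2_te` column (see [teTable()]).
#' @param center subtract the mean log2 TE before scaling.
#' @return `records` with a `te_z` column filled.
#' @export
teZScores <- function(records, center = FALSE) {
  if (nrow(records) < 2) stopf("need at least 2 genes for TE z-scores")
  x <- records$log2_te
  mu <- if (center) mean(x) else 0
  s <- sd(x)
  records$te_z <- if (s < 1e-12) rep(0, length(x)) else (x - mu) / s
  records
}

#' Translational-efficiency table
#'
#' Joins the per-assay fold-change tables on the genes passing the read
#' filter in \emph{both} assays, computes the TE ratio (footprint fold change
#' over mRNA fold change) and its z-score.
#'
#' @param fcMrna,fcFp fold-change tables from [foldChangeTable()] for the
#'   mRNA and footprint assays.
#' @param center see [teZScores()].
#' @return data.frame `gene_id, fc_mrna, fc_fp, te_ratio, log2_te, te_z`
#'   ordered by `gene_id`.
#' @export
teTable <- function(fcMrna, fcFp, center = FALSE) {
  m <- merge(fcMrna[, c("gene_id", "F")], fcFp[, c("gene_id", "F")],
             by = "gene_id", suffixes = c("_mrna", "_fp"))
  if (nrow(m) < 2)
    stopf("fewer than 2 genes pass the read filter in both assays")
  out <- data.frame(gene_id = m$gene_id,
                    fc_mrna = m$F_mrna, fc_fp = m$F_fp,
                    te_ratio = teChange(m$F_fp, m$F_mrna),
                    stringsAsFactors = FALSE)
  out$log2_te <- log2(out$te_ratio)
  out <- teZScores(out, center = center)
  out[order(out$gene_id), , drop = FALSE]
}
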