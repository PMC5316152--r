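#' Filter genes by combined raw read count
#'
#' Reliable fold-change estimation needs read support, so genes with fewer
#' than `minTotal` raw CDS reads summed over the two conditions (for the
#' given assay) are excluded. The boundary is inclusive: a gene with exactly
#' `minTotal` combined reads is retained.
#'
#' @param counts a [RiboCountExperiment-class].
#' @param assay "mRNA" or "footprint".
#' @param minTotal minimum combined raw CDS reads (default 128).
#' @return character vector of retained gene ids (possibly empty).
#' @export
filterLowCounts <- function(counts, assay = c("footprint", "mRNA"),
                            minTotal = 128L) {
  assay <- match.arg(assay)
  cc <- cdsCounts(counts)
  combined <- cc[, paste0("SD.", assay)] + cc[, paste0("MetR.", assay)]
  rownames(cc)[combined >= minTotal]
}

#' Median-normalized fold changes
#'
#' Per-gene MetR/SD ratio of library-size-normalized CDS counts, with a
#' symmetric pseudocount on both conditions, rescaled so that the median fold
#' change over the filtered genes is exactly 1 (even gene counts use the
#' midpoint median).
#'
#' @param counts a [RiboCountExperiment-class].
#' @param assay "mRNA" or "footprint".
#' @param genes gene ids to use (typically from [filterLowCounts()]).
#' @param pseudocount added to the raw count of each condition before the
#'   ratio (default 0.5).
#' @return named numeric vector of normalized fold changes `F` (MetR/SD).
#' @export
normalizedFoldChanges <- function(counts, assay = c("footprint", "mRNA"),
                                  genes, pseudocount = 0.5) {
  assay <- match.arg(assay)
  if (length(genes) == 0) stopf("empty gene list")
  cc <- cdsCounts(counts)[genes, , drop = FALSE]
  tot <- libraryTotals(counts)
  nSD <- tot[paste0("SD.", assay)]
  nMetR <- tot[paste0("MetR.", assay)]
  if (nSD <= 0 || nMetR <= 0)
    stopf("degenerate input: zero library total for assay %s", assay)
  r <- ((cc[, paste0("MetR.", assay)] + pseudocount) / nMetR) /
       ((cc[, paste0("SD.", assay)] + pseudocount) / nSD)
  setNames(r / median(r), genes)
}

# deterministic k-nearest neighbourhood (self plus k genes with the most
# similar combined read counts, distance ties broken by gene_id order);
# returns an index matrix rows = genes, cols = k+1 members
.sigmaNeighbourhoods <- function(combined, ids, k) {
  n <- length(combined)
  if (n < k + 1) stopf("local sigma needs at least k+1 = %d genes, got %d; use a smaller k",
                       k + 1, n)
  o <- order(combined, ids)
  x <- combined[o]
  nb <- matrix(0L, n, k + 1L)
  l <- 1L
  for (j in seq_len(n)) {
    # contiguous window [l, l+k] around position j minimizing max distance
    if (j > l + k) l <- j - k
    while (l + k < n && (x[l + k + 1L] - x[j]) < (x[j] - x[l])) l <- l + 1L
    lo <- l; hi <- l + k
    dmax <- max(x[j] - x[lo], x[hi] - x[j])
    # candidates at the maximal distance may tie with genes just outside the
    # window; re-select those slots by gene_id order among all tied genes
    inner <- which(abs(x[lo:hi] - x[j]) < dmax) + lo - 1L
    inner <- union(j, inner)  # the gene itself always belongs
    if (length(inner) < k + 1L) {
      tlo <- lo; thi <- hi
      while (tlo > 1L && x[j] - x[tlo - 1L] == dmax) tlo <- tlo - 1L
      while (thi < n && x[thi + 1L] - x[j] == dmax) thi <- thi + 1L
      tied <- setdiff(tlo:thi, inner)
      tied <- tied[abs(x[tied] - x[j]) == dmax]
      tied <- tied[order(ids[o[tied]])]
      sel <- c(inner, tied[seq_len(k + 1L - length(inner))])
    } else sel <- inner
    nb[o[j], ] <- o[sort(sel)]
  }
  nb
}

#' Empirical local noise estimate for a gene's fold change
#'
#' Collects the `k` other genes with the most similar combined read count and
#' returns the sample standard deviation (denominator n-1, about the
#' neighbourhood mean) of the log2 fold changes of those `k + 1` genes,
#' floored at `sigmaFloor`. Distance ties are broken by gene id order. Genes
#' with similar counts share similar counting noise, so this neighbourhood SD
#' estimates the null spread of the gene's own log fold change.
#'
#' @param geneId gene to estimate sigma for.
#' @param foldChanges named vector of normalized fold changes `F`.
#' @param combinedReads named vector of combined raw reads (same genes).
#' @param k neighbourhood size excluding the gene itself (default 100).
#' @param sigmaFloor lower bound on sigma, log2 units (default 0.05).
#' @param center "mean" (default) computes the SD about the neighbourhood
#'   mean; "zero" computes the root mean square about zero with the same
#'   n-1 denominator.
#' @return sigma (log2 units, >= `sigmaFloor`).
#' @export
localSigma <- function(geneId, foldChanges, combinedReads, k = 100L,
                       sigmaFloor = 0.05, center = c("mean", "zero")) {
  center <- match.arg(center)
  ids <- names(foldChanges)
  nb <- .sigmaNeighbourhoods(as.numeric(combinedReads[ids]), ids, k)
  i <- match(geneId, ids)
  if (is.na(i)) stopf("gene %s is not among the filtered genes", geneId)
  lf <- log2(foldChanges[nb[i, ]])
  s <- if (center == "mean") sd(lf) else sqrt(sum(lf^2) / (length(lf) - 1))
  max(s, sigmaFloor)
}

#' Fold-change z statistic and p-value
#'
#' `z = log2(F) / sigma` with `sigma` on the log2 scale (the statistic is
#' invariant to the logarithm base as long as numerator and sigma share it);
#' the two-sided p-value is `2 * pnorm(-|z|)`.
#'
#' @param F normalized fold change (> 0), vectorized.
#' @param sigma noise estimate on the log2 scale (>= sigma floor).
#' @return data.frame with columns `z` and `p`.
#' @examples
#' foldChangeZ(4, 1)  # z = 2, p ~ 0.0455
#' @export
foldChangeZ <- function(F, sigma) {
  if (any(F <= 0)) stopf("fold changes must be positive")
  if (any(sigma <= 0)) stopf("sigma must be positive")
  z <- log2(F) / sigma
  data.frame(z = z, p = 2 * pnorm(-abs(z)))
}

#' Fold changes with local-noise z-scores for one assay
#'
#' The per-assay differential-expression table: filters genes by combined
#' raw CDS reads, computes median-normalized fold changes, the local
#' neighbourhood noise estimate, the z statistic and two-sided normal
#' p-values. A Benjamini-Hochberg adjusted column `padj` is appended as an
#' optional extra (the thresholds used elsewhere in the pipeline are on
#' fold changes and z-scores, not FDR).
#'
#' @param counts a [RiboCountExperiment-class].
#' @param assay "footprint" or "mRNA".
#' @param minTotal combined-read filter threshold (default 128).
#' @param k sigma neighbourhood size (default 100; capped at the number of
#'   filtered genes minus one with a warning).
#' @param pseudocount see [normalizedFoldChanges()].
#' @param sigmaFloor,center see [localSigma()].
#' @return data.frame `gene_id, assay, combined_reads, F, log2F, sigma, z, p,
#'   padj` ordered by `gene_id`.
#' @export
foldChangeTable <- function(counts, assay = c("footprint", "mRNA"),
                            minTotal = 128L, k = 100L, pseudocount = 0.5,
                            sigmaFloor = 0.05, center = c("mean", "zero")) {
  assay <- match.arg(assay); center <- match.arg(center)
  genes <- filterLowCounts(counts, assay, minTotal)
  if (length(genes) < 2)
    stopf("fewer than 2 genes pass the %d-read filter for assay %s",
          minTotal, assay)
  if (length(genes) < k + 1) {
    warning(sprintf("only %d filtered genes; reducing k from %d to %d",
                    length(genes), k, length(genes) - 1L))
    k <- length(genes) - 1L
  }
  F <- normalizedFoldChanges(counts, assay, genes, pseudocount)
  cc <- cdsCounts(counts)[genes, , drop = FALSE]
  combined <- setNames(cc[, paste0("SD.", assay)] +
                         cc[, paste0("MetR.", assay)], genes)
  nb <- .sigmaNeighbourhoods(as.numeric(combined), genes, k)
  lf <- log2(F)
  sigma <- vapply(seq_along(genes), function(i) {
    v <- lf[nb[i, ]]
    s <- if (center == "mean") sd(v) else sqrt(sum(v^2) / (length(v) - 1))
    max(s, sigmaFloor)
  }, numeric(1))
  zp <- foldChangeZ(F, sigma)
  out <- data.frame(gene_id = genes, assay = assay,
                    combined_reads = as.integer(combined),
                    F = as.numeric(F), log2F = as.numeric(lf),
                    sigma = sigma, z = zp$z, p = zp$p,
                    padj = stats::p.adjust(zp$p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}
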