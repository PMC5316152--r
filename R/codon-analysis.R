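#' Per-gene K/Q/E/M codon frequencies
#'
#' Counts in-frame codons of each CDS and reports the frequencies of the
#' lysine (AAA/AAG), glutamine (CAA/CAG), glutamate (GAA/GAG) and methionine
#' (ATG) codons, plus their combined K+Q+E frequency. These are the codons
#' decoded by tRNAs whose wobble-uridine thiolation depends on sulfur
#' availability, so KQE-rich genes are candidates for thiolation-mediated
#' translational repression.
#'
#' Conventions: sequences must be in frame (length divisible by 3) and start
#' with ATG; a terminal stop codon is excluded from both numerator and
#' denominator unless `includeStop = TRUE`; codons containing ambiguous
#' nucleotides are dropped from both; an internal stop codon is an error
#' naming the gene.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or named character vector)
#'   of CDS sequences named by gene id.
#' @param includeStop keep a terminal stop codon in the denominator.
#' @return data.frame with columns `gene_id`, `n_codons`, `freq_K`, `freq_Q`,
#'   `freq_E`, `freq_KQE`, `freq_M`.
#' @examples
#' codonFrequencies(Biostrings::DNAStringSet(c(gene1 = "ATGAAACAAGAATGA")))
#' @export
codonFrequencies <- function(sequences, includeStop = FALSE) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stopf("sequences must be named by gene id")
  w <- Biostrings::width(sequences)
  bad <- w %% 3L != 0L
  if (any(bad)) stopf("CDS length of %s is not divisible by 3", ids[bad][1])
  if (any(w < 3L)) stopf("CDS of %s is shorter than one codon",
                         ids[w < 3L][1])
  first <- as.character(Biostrings::subseq(sequences, 1L, 3L))
  if (!all(first == "ATG"))
    stopf("CDS of %s does not start with ATG", ids[first != "ATG"][1])

  # in-frame codon counts; triplets containing non-ACGT letters are ignored,
  # which implements the drop-ambiguous-codons rule
  counts <- Biostrings::trinucleotideFrequency(sequences, step = 3L)
  last <- as.character(Biostrings::subseq(sequences, w - 2L, w))
  if (!includeStop) {
    isStop <- last %in% STOP_CODONS
    if (any(isStop)) {
      idx <- cbind(which(isStop), match(last[isStop], colnames(counts)))
      counts[idx] <- counts[idx] - 1L
    }
  }
  internalStop <- rowSums(counts[, STOP_CODONS, drop = FALSE]) >
    (if (includeStop) 1L else 0L)
  # a retained terminal stop is legitimate; anything beyond that is internal
  if (includeStop) {
    internalStop <- rowSums(counts[, STOP_CODONS, drop = FALSE]) -
      (last %in% STOP_CODONS) > 0L
  }
  if (any(internalStop))
    stopf("internal stop codon in CDS of %s", ids[internalStop][1])

  n <- rowSums(counts)
  if (any(n < 1)) stopf("no countable codons in CDS of %s", ids[n < 1][1])
  fr <- function(cod) rowSums(counts[, cod, drop = FALSE]) / n
  data.frame(
    gene_id = ids, n_codons = as.integer(n),
    freq_K = fr(c("AAA", "AAG")), freq_Q = fr(c("CAA", "CAG")),
    freq_E = fr(c("GAA", "GAG")),
    freq_KQE = fr(KQE_CODONS), freq_M = fr("ATG"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate codon frequency with translational-efficiency change
#'
#' Pearson correlation between a per-gene codon frequency (K, Q, E, combined
#' KQE, or M) and the log2 translational-efficiency change, over the genes
#' present in both tables. The two-sided p-value comes from the t
#' distribution with n - 2 degrees of freedom. A negative r for KQE-rich
#' genes is the signature of thiolation-limited translation.
#'
#' @param stats output of [codonFrequencies()].
#' @param te output of [teTable()] (needs `gene_id` and `log2_te`).
#' @param variable which frequency to correlate: "KQE", "K", "Q", "E" or "M".
#' @param useLog2 correlate against `log2_te` (default) or the raw `te_ratio`.
#' @return one-row data.frame with `variable`, `r`, `p`, `n`.
#' @export
correlateFrequencyTE <- function(stats, te,
                                 variable = c("KQE", "K", "Q", "E", "M"),
                                 useLog2 = TRUE) {
  variable <- match.arg(variable)
  col <- paste0("freq_", variable)
  m <- merge(stats[, c("gene_id", col)],
             te[, c("gene_id", if (useLog2) "log2_te" else "te_ratio")],
             by = "gene_id")
  if (nrow(m) < 3) stopf("need at least 3 genes in common, got %d", nrow(m))
  x <- m[[col]]
  y <- m[[3L]]
  if (sd(x) < 1e-15)
    stopf("codon frequency %s is constant across genes; r undefined", variable)
  n <- nrow(m)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(variable = variable, r = r, p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Contrast a gene set's codon usage and TE change against the background
#'
#' For a designated gene set (e.g. ribosome biogenesis genes) computes the
#' signed rank-sum z of members vs non-members on the combined KQE codon
#' frequency and on the log2 TE change, plus Pearson correlations between the
#' two variables within the members, within the complement, and over all
#' genes. The complement-only correlation reproduces the exclusion analysis:
#' if the KQE-TE association is confined to the set, removing the set should
#' abolish it.
#'
#' @param stats output of [codonFrequencies()].
#' @param te output of [teTable()].
#' @param members character vector of member gene ids.
#' @return a list with `freq_z`, `te_z`, `n_members`, `r_members`,
#'   `r_complement`, `r_all`.
#' @export
genesetCodonContrast <- function(stats, te, members) {
  m <- merge(stats[, c("gene_id", "freq_KQE")],
             te[, c("gene_id", "log2_te")], by = "gene_id")
  inSet <- m$gene_id %in% members
  if (!any(inSet) || all(inSet))
    stopf("members and complement must both be nonempty among scored genes")
  safeCor <- function(x, y)
    if (length(x) >= 3 && sd(x) > 1e-15 && sd(y) > 1e-15) cor(x, y)
    else NA_real_
  list(
    freq_z = moduleZscore(setNames(m$freq_KQE, m$gene_id),
                          m$gene_id[inSet]),
    te_z = moduleZscore(setNames(m$log2_te, m$gene_id), m$gene_id[inSet]),
    n_members = sum(inSet),
    r_members = safeCor(m$freq_KQE[inSet], m$log2_te[inSet]),
    r_complement = safeCor(m$freq_KQE[!inSet], m$log2_te[!inSet]),
    r_all = safeCor(m$freq_KQE, m$log2_te))
}
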