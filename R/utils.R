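#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom stats rnbinom rpois rlnorm rgamma rbeta rbinom runif median
#'   sd pnorm qnorm pt cor setNames p.adjust
#' @importFrom utils read.delim write.table head tail
NULL

CONDITIONS <- c("SD", "MetR")
ASSAYS <- c("mRNA", "footprint")
LIBRARIES <- c("SD.mRNA", "MetR.mRNA", "SD.footprint", "MetR.footprint")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write a tab-separated table
#'
#' Plain-text TSV with a header, no quoting, no row names; the on-disk format
#' used for all tabular pipeline outputs. Deterministic for identical input.
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by [writeTsv()]
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
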