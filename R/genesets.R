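#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated — set name, description, then member
#' gene ids.
#'
#' @param path file path.
#' @return `readGmt` returns a named list of character vectors; descriptions
#'   are kept in the `description` attribute of each element.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("malformed GMT line %d in %s (need name, description, >=1 gene)",
            i, path)
    members <- unique(f[-(1:2)])
    attr(members, "description") <- f[2]
    out[[f[1]]] <- members
  }
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors of gene ids.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(d)) "na" else d, as.character(sets[[nm]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Signed rank-sum z-score of a gene set
#'
#' Wilcoxon-Mann-Whitney comparison of the fold changes of member genes
#' against all non-members, via the normal approximation with tie-corrected
#' variance and no continuity correction. The sign is chosen so that members
#' with systematically larger values give z > 0 (collective induction) and
#' smaller values give z < 0 (repression). Because the statistic depends on
#' the values only through their ranks, scoring fold changes or log fold
#' changes gives the identical z.
#'
#' @param values named numeric vector (gene id -> fold change or any
#'   monotone transform thereof) defining the scoring universe.
#' @param members character vector of member gene ids; ids outside `values`
#'   are ignored.
#' @return the signed z-score (0 when the tie-corrected variance vanishes).
#' @export
moduleZscore <- function(values, members) {
  ids <- names(values)
  if (is.null(ids)) stopf("values must be named by gene id")
  inSet <- ids %in% members
  n1 <- sum(inSet); n2 <- sum(!inSet)
  if (n1 == 0 || n2 == 0)
    stopf("members and non-members must both be nonempty (got %d vs %d)",
          n1, n2)
  r <- rank(values)
  N <- n1 + n2
  U <- sum(r[inSet]) - n1 * (n1 + 1) / 2
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tieTerm)
  if (v <= 0) return(0)
  (U - n1 * n2 / 2) / sqrt(v)
}

#' Score every gene set against a fold-change profile
#'
#' Applies [moduleZscore()] to each set in a GMT-style list. The scoring
#' universe is the genes named in `foldChanges` (typically those passing the
#' read filter); memberships outside the universe are dropped before the
#' minimum-size check, and sets with fewer than `minSize` scorable members —
#' or with an empty complement — are skipped and reported in the `skipped`
#' attribute.
#'
#' @param foldChanges named numeric vector of fold changes.
#' @param gmt named list of gene sets (see [readGmt()]).
#' @param minSize minimum scorable members (default 15).
#' @param assay label copied into the output (default "footprint").
#' @return data.frame `module_id, assay, n_members_scored, z, direction`
#'   sorted by `|z|` descending (ties by module id), with a `skipped`
#'   attribute naming the sets not scored and why.
#' @export
scoreAllModules <- function(foldChanges, gmt, minSize = 15L,
                            assay = "footprint") {
  universe <- names(foldChanges)
  rows <- list(); skipped <- character()
  for (nm in names(gmt)) {
    members <- intersect(gmt[[nm]], universe)
    if (length(members) < minSize) {
      skipped[nm] <- sprintf("only %d scorable members (< %d)",
                             length(members), minSize)
      next
    }
    if (length(members) == length(universe)) {
      skipped[nm] <- "empty complement: set covers the whole universe"
      next
    }
    z <- moduleZscore(foldChanges, members)
    rows[[nm]] <- data.frame(module_id = nm, assay = assay,
                             n_members_scored = length(members), z = z,
                             direction = if (z > 0) "up" else "down",
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(module_id = character(), assay = character(),
                         n_members_scored = integer(), z = numeric(),
                         direction = character(), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$z), out$module_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
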