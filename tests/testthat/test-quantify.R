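test_that("position assignment follows the P-site convention", {
  # BED [100, 128) on + -> 115; on - -> 112; mRNA 5' end unshifted
  fpPlus <- bedReads(100L, 128L, "+")
  fpMinus <- bedReads(100L, 128L, "-")
  mr <- bedReads(100L, 150L, "+")
  expect_equal(assignPosition(fpPlus, "footprint", 15L), 115L)
  expect_equal(assignPosition(fpMinus, "footprint", 15L), 112L)
  expect_equal(assignPosition(mr, "mRNA"), 100L)
  expect_equal(assignPosition(fpPlus, "footprint", 0L), 100L)
  expect_error(assignPosition(fpPlus, "footprint", 28L), "read length")
  expect_error(assignPosition(fpPlus, "footprint", -1L), "non-negative")
})

test_that("CDS counting honours the TSS exclusion window", {
  m <- toyModel(tss = 0L, cds_start = 60L, cds_end = 300L, utr3_end = 360L)
  # footprint assigned to 70 (>= 50 from TSS, inside CDS)
  r <- bedReads(70L - 15L, 70L - 15L + 28L, "+")
  expect_equal(unname(countGene(r, m, "footprint")["cds"]), 1L)

  m2 <- toyModel(tss = 0L, cds_start = 21L, cds_end = 300L, utr3_end = 360L)
  # assigned position 30: inside CDS but only 30 nt from the TSS
  r2 <- bedReads(30L - 15L, 30L - 15L + 28L, "+")
  cnt <- countGene(r2, m2, "footprint")
  expect_equal(unname(cnt["cds"]), 0L)
  expect_equal(unname(cnt["utr5"]), 0L)
  # with a 25-nt window the anchor matters: 30 nt from the TSS but only
  # 9 nt from the start codon
  expect_equal(unname(countGene(r2, m2, "footprint",
                                tssExclusion = 25L)["cds"]), 1L)
  expect_equal(unname(countGene(r2, m2, "footprint", anchor = "cds",
                                tssExclusion = 25L)["cds"]), 0L)
})

test_that("UTR counting ignores the exclusion window", {
  m <- toyModel(tss = 0L, cds_start = 60L, cds_end = 300L, utr3_end = 360L)
  r <- bedReads(30L - 15L, 30L - 15L + 28L, "+")  # assigned 30, in 5'UTR
  cnt <- countGene(r, m, "footprint")
  expect_equal(unname(cnt["utr5"]), 1L)
})

test_that("wrong-strand reads are ignored but tallied", {
  m <- toyModel()
  r <- bedReads(100L, 128L, "-")
  cnt <- countGene(r, m, "footprint")
  expect_equal(sum(cnt), 0L)
  expect_equal(unname(attr(cnt, "diagnostics")["wrong_strand"]), 1)
})

test_that("vectorized counting equals the brute-force oracle exactly", {
  gm <- simulateGeneModels(60, seed = 21, mirrorStrand = TRUE)
  cfg <- effectConfig(60, meanDepth = 40, fracTeUp = 0.2, teEffect = 4,
                      mirrorStrand = TRUE, seed = 21)
  sim <- simulateReads(gm$models, cfg)
  for (lib in c("SD.footprint", "MetR.mRNA")) {
    assay <- sub(".*\\.", "", lib)
    ct <- buildCountTable(sim$reads, gm$models)
    bf <- bruteForceCounts(sim$reads[[lib]], gm$models, assay)
    expect_identical(unname(cdsCounts(ct)[, lib]), unname(bf[, "cds"]))
    expect_identical(unname(utr5Counts(ct)[, lib]), unname(bf[, "utr5"]))
    expect_identical(unname(utr3Counts(ct)[, lib]), unname(bf[, "utr3"]))
  }
})

test_that("counting matches the generator's internal placement tallies", {
  gm <- simulateGeneModels(50, seed = 22, mirrorStrand = TRUE)
  cfg <- effectConfig(50, meanDepth = 80, fracTeUp = 0.3, teEffect = 4,
                      mirrorStrand = TRUE, seed = 22)
  sim <- simulateReads(gm$models, cfg)
  ct <- buildCountTable(sim$reads, gm$models)
  for (lib in colnames(ct)) {
    t <- sim$tallies[sim$tallies$library == lib, ]
    t <- t[match(rownames(ct), t$gene_id), ]
    expect_identical(unname(cdsCounts(ct)[, lib]),
                     as.integer(t$cds - t$cds_excluded))
    expect_identical(unname(utr5Counts(ct)[, lib]), as.integer(t$utr5))
    expect_identical(unname(utr3Counts(ct)[, lib]), as.integer(t$utr3))
  }
})

test_that("read order does not affect the count table", {
  gm <- simulateGeneModels(30, seed = 23)
  cfg <- effectConfig(30, meanDepth = 50, seed = 23)
  sim <- simulateReads(gm$models, cfg)
  shuffled <- lapply(sim$reads, function(gr) {
    set.seed(1); gr[sample(length(gr))]
  })
  a <- buildCountTable(sim$reads, gm$models)
  b <- buildCountTable(shuffled, gm$models)
  expect_identical(cdsCounts(a), cdsCounts(b))
  expect_identical(utr5Counts(a), utr5Counts(b))
})

test_that("mirroring all coordinates and strands leaves counts unchanged", {
  gm <- simulateGeneModels(30, seed = 24)
  cfg <- effectConfig(30, meanDepth = 50, seed = 24)
  sim <- simulateReads(gm$models, cfg)
  C <- max(gm$models$utr3_end) + 5000L
  mm <- mirrorModels(gm$models, C)
  mr <- lapply(sim$reads, mirrorReads, C = C)
  a <- buildCountTable(sim$reads, gm$models)
  b <- buildCountTable(mr, mm)
  expect_identical(unname(cdsCounts(a)), unname(cdsCounts(b)))
  expect_identical(unname(utr5Counts(a)), unname(utr5Counts(b)))
  expect_identical(unname(utr3Counts(a)), unname(utr3Counts(b)))
})

test_that("offset-zero footprint counting equals mRNA counting", {
  gm <- simulateGeneModels(30, seed = 25, mirrorStrand = TRUE)
  cfg <- effectConfig(30, meanDepth = 50, mirrorStrand = TRUE, seed = 25)
  sim <- simulateReads(gm$models, cfg)
  gr <- sim$reads$SD.footprint
  same <- list(SD.mRNA = gr, MetR.mRNA = gr, SD.footprint = gr,
               MetR.footprint = gr)
  ct <- buildCountTable(same, gm$models, offset = 0L)
  expect_identical(unname(cdsCounts(ct)[, "SD.footprint"]),
                   unname(cdsCounts(ct)[, "SD.mRNA"]))
  expect_identical(unname(utr5Counts(ct)[, "SD.footprint"]),
                   unname(utr5Counts(ct)[, "SD.mRNA"]))
})

test_that("region counts never exceed the weight at the locus", {
  gm <- simulateGeneModels(40, seed = 26)
  cfg <- effectConfig(40, meanDepth = 60, seed = 26)
  sim <- simulateReads(gm$models, cfg)
  ct <- buildCountTable(sim$reads, gm$models)
  for (lib in colnames(ct)) {
    perGene <- cdsCounts(ct)[, lib] + utr5Counts(ct)[, lib] +
      utr3Counts(ct)[, lib]
    expect_true(all(perGene <= libraryTotals(ct)[lib]))
  }
})

test_that("empty input yields a zero table flagged as degenerate", {
  gm <- simulateGeneModels(5, seed = 27)
  empty <- bedReads(integer(0), integer(0))
  reads <- list(SD.mRNA = empty, MetR.mRNA = empty, SD.footprint = empty,
                MetR.footprint = empty)
  expect_warning(ct <- buildCountTable(reads, gm$models), "degenerate")
  expect_true(all(cdsCounts(ct) == 0))
  expect_true(all(libraryTotals(ct) == 0))
})

test_that("missing library or missing BED file is a clear error", {
  gm <- simulateGeneModels(5, seed = 28)
  expect_error(buildCountTable(list(SD.mRNA = bedReads(1L, 29L)), gm$models),
               "missing")
  expect_error(readBed(tempfile()), "not found")
})

test_that("ambiguous positions on overlapping annotations count to neither gene", {
  a <- toyModel("a")
  b <- toyModel("b", tss = 100L, cds_start = 160L, cds_end = 400L,
                utr3_end = 460L)
  m <- rbind(a, b)  # overlap in [100, 420)
  r <- bedReads(200L - 15L, 200L - 15L + 28L, "+")  # assigned 200, in both
  reads <- list(SD.mRNA = r, MetR.mRNA = r, SD.footprint = r,
                MetR.footprint = r)
  ct <- buildCountTable(reads, m)
  expect_true(all(cdsCounts(ct) == 0))
  expect_equal(unname(S4Vectors::metadata(ct)$diagnostics[, "ambiguous"]),
               rep(1, 4))
})
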