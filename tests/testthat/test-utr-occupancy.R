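test_that("the 5'UTR/CDS ratio follows the division contract", {
  expect_equal(utrCdsRatio(4L, 100L), 0.04)
  expect_equal(utrCdsRatio(0L, 100L), 0)
  expect_true(is.na(utrCdsRatio(5L, 0L)))
  expect_error(utrCdsRatio(-1L, 5L), ">= 0")
})

test_that("loading classes follow the diagonal band rule", {
  expect_equal(classifyLoading(2, 8, delta = 1), "class1")
  expect_equal(classifyLoading(8, 2, delta = 1), "class2")
  expect_equal(classifyLoading(3, 3, delta = 1), "class3")
  expect_equal(classifyLoading(3, 3, delta = 0.01), "class3")
  # swapping the folds maps class1 <-> class2 and fixes class3
  set.seed(61)
  u <- 2^rnorm(100); c <- 2^rnorm(100)
  a <- classifyLoading(u, c)
  b <- classifyLoading(c, u)
  expect_identical(b[a == "class1"], rep("class2", sum(a == "class1")))
  expect_identical(b[a == "class2"], rep("class1", sum(a == "class2")))
  expect_identical(b[a == "class3"], rep("class3", sum(a == "class3")))
  expect_error(classifyLoading(0, 1), "positive")
})

test_that("identical counts in both conditions give equal group summaries", {
  cds <- matrix(100L, 4, 4, dimnames = list(paste0("g", 1:4), NULL))
  u5 <- matrix(4L, 4, 4, dimnames = list(paste0("g", 1:4), NULL))
  ct <- countExperiment(cds, utr5 = u5, totals = rep(1000, 4))
  te <- data.frame(gene_id = paste0("g", 1:4), te_z = c(3, 3, 0, -3))
  tab <- utrTable(ct, te)
  expect_equal(tab$ratio_sd, tab$ratio_metr)
  sm <- groupRatioSummary(tab, ct)
  for (g in unique(sm$te_group)) {
    s <- sm[sm$te_group == g, ]
    expect_equal(s$pooled_ratio[1], s$pooled_ratio[2])
    expect_equal(s$pooled_ratio[1], 0.04)
  }
})

test_that("excluding an outlier only changes its own group", {
  set.seed(62)
  cds <- matrix(rpois(40, 200), 10, 4,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
  u5 <- matrix(rpois(40, 8), 10, 4,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  ct <- countExperiment(cds, utr5 = u5, totals = rep(5000, 4))
  te <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   te_z = c(3, 3, 3, rep(0, 6), -3))
  tab <- utrTable(ct, te)
  full <- groupRatioSummary(tab, ct)
  drop1 <- groupRatioSummary(tab, ct, excludeIds = "g01")  # an "up" gene
  other <- full$te_group != "up"
  expect_equal(drop1$pooled_ratio[other], full$pooled_ratio[other])
  expect_false(isTRUE(all.equal(drop1$pooled_ratio[!other],
                                full$pooled_ratio[!other])))
})

test_that("classes are only assigned to TE-up genes with enough evidence", {
  cds <- matrix(c(100L, 100L, 100L, 400L,
                  100L, 100L, 100L, 400L,
                  3L,   3L,   3L,  12L), 3, 4, byrow = TRUE,
                dimnames = list(c("up", "flat", "sparse"), NULL))
  u5 <- matrix(c(30L, 30L, 30L, 6L,
                 30L, 30L, 30L, 30L,
                 2L,  2L,  2L,  1L), 3, 4, byrow = TRUE,
               dimnames = list(c("up", "flat", "sparse"), NULL))
  ct <- countExperiment(cds, utr5 = u5, totals = rep(1000, 4))
  te <- data.frame(gene_id = c("up", "flat", "sparse"), te_z = c(3, 0, 3))
  tab <- utrTable(ct, te)
  expect_identical(tab$te_group, c("up", "other", "up"))
  expect_identical(tab$loading_class[tab$gene_id == "up"], "class1")
  expect_identical(tab$loading_class[tab$gene_id == "flat"], "unassigned")
  expect_identical(tab$loading_class[tab$gene_id == "sparse"], "unassigned")
})

test_that("planted 5'UTR occupancy levels are recovered from reads", {
  gm <- simulateGeneModels(400, seed = 63, utr5Mean = 120)
  cfg <- effectConfig(400, meanDepth = 500, fracTeUp = 0.1, teEffect = 4,
                      utr5ReadFraction = 0.008,
                      classUtr5Fractions = rbind(class1 = c(0.04, 0.04),
                                                 class2 = c(0.04, 0.04),
                                                 class3 = c(0.04, 0.04)),
                      seed = 63)
  sim <- simulateReads(gm$models, cfg)
  ct <- buildCountTable(sim$reads, gm$models)
  te <- teTable(foldChangeTable(ct, "mRNA"), foldChangeTable(ct, "footprint"))
  tab <- utrTable(ct, te)
  sm <- groupRatioSummary(tab, ct)
  up_sd <- sm$pooled_ratio[sm$te_group == "up" & sm$condition == "SD"]
  other_sd <- sm$pooled_ratio[sm$te_group == "other" & sm$condition == "SD"]
  # planted contrast 0.04 vs 0.008 (ratios shrink slightly because the
  # denominator CDS excludes the first 50 nt window)
  expect_gt(up_sd, 0.03)
  expect_lt(abs(other_sd - 0.008) / 0.008, 0.35)
  expect_gt(up_sd / other_sd, 3)
})
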