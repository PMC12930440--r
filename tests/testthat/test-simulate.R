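test_that("condition generator is deterministic and validates feasibility", {
  spec <- syntheticSpec(nGenes = 1300L)
  s1 <- simConditionTables(spec, seed = 3)
  s2 <- simConditionTables(spec, seed = 3)
  expect_identical(lapply(s1$tables, as.data.frame),
                   lapply(s2$tables, as.data.frame))
  expect_length(s1$tables, 8L)
  # infeasible correlation targets error before sampling
  bad <- syntheticSpec(nGenes = 1300L, withinTimeCorr = 0.99, noiseSd = 2)
  expect_error(simConditionTables(bad, seed = 1), "infeasible")
})

test_that("null-gene p-values are uniform and null calling matches theory", {
  spec0 <- syntheticSpec(nGenes = 4000L, signalFraction = 0)
  sim <- simConditionTables(spec0, seed = 5)
  p <- pValues(sim$tables[[1]])
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  # expected false-positive rate of the default cutoffs under the null:
  # member iff p < 0.01 and |lfc| > 1.5, i.e. |z| > 1.5 / noiseSd = 3
  sig <- callSignature(sim$tables[[1]], signatureThresholds(0.01, 1.5))
  expRate <- 2 * pnorm(-max(qnorm(1 - 0.01 / 2), 1.5 / spec0@noiseSd))
  expect_lt(abs(length(sig) - 4000 * expRate),
            3 * sqrt(4000 * expRate * (1 - expRate)) + 3)
})

test_that("planted cross-condition correlation signs are realized", {
  spec <- syntheticSpec(nGenes = 1500L)
  sim <- simConditionTables(spec, seed = 8)
  lfc <- sapply(sim$tables, function(tb) unname(log2FoldChange(tb)))
  sameT <- cor(lfc[, "HNK_6h_gene"], lfc[, "LSD_6h_gene"],
               method = "spearman")
  diffT <- cor(lfc[, "HNK_6h_gene"], lfc[, "HNK_24h_gene"],
               method = "spearman")
  expect_gt(sameT, 0)
  expect_lt(diffT, 0)
})

test_that("cross-modal generator plants the expected overlap structure", {
  spec <- syntheticSpec(nGenes = 2000L)
  sim <- simCrossModalPair(spec, seed = 10)
  uni <- universeIds(sim$universe)
  # the called gene signature within the universe is exactly the planted A
  gU <- SigConcord:::.restrictTable(sim$neuronal, uni)
  sg <- callSignature(gU, signatureThresholds(0.05, 0), uni)
  expect_setequal(members(sg), sim$truth$A)
  # planted protein sets are recovered by FDR calling within the universe
  pU <- SigConcord:::.restrictTable(mapProteinTable(sim$csfSeries[[5]],
                                                    sim$map), uni)
  pU@stats$adj_p <- bhFDR(pU@stats$p_value)
  sp <- callSignature(pU, signatureThresholds(0.05, 0, useAdjusted = TRUE),
                      uni)
  planted <- sim$truth$universeGenes[match(sim$truth$B[[5]],
    sim$map@protein[seq_len(1235)])]
  expect_setequal(members(sp), planted)
  # enrichment ramp peaks at the configured index
  expect_equal(which.max(sim$truth$expectedOverlap), 5L)
  expect_equal(max(sim$truth$enrichment), spec@crossmodalEnrichment)
})

test_that("cross-modal generator determinism and null behaviour", {
  spec <- syntheticSpec(nGenes = 1500L, crossmodalEnrichment = 1)
  s1 <- simCrossModalPair(spec, seed = 4)
  s2 <- simCrossModalPair(spec, seed = 4)
  expect_identical(as.data.frame(s1$neuronal), as.data.frame(s2$neuronal))
  expect_identical(s1$truth$A, s2$truth$A)
  expect_true(all(s1$truth$coupling == 0))
  expect_true(all(s1$truth$enrichment == 1))
})

test_that("simulated inputs round-trip through the TSV dialects", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 1400L), seed = 20)
  dir <- tempfile("simio")
  manifest <- writeSimulatedInputs(sim, dir)
  expect_true(file.exists(manifest))
  man <- read.delim(manifest)
  expect_identical(nrow(man), 6L)
  back <- readDifferentialTable(file.path(dir, "neuronal.tsv"),
                                agent = "HNK", timepointHours = 24)
  expect_identical(as.data.frame(back)$log2fc,
                   as.data.frame(sim$neuronal)$log2fc)
  m <- readCrossModalMap(file.path(dir, "mapping.tsv"))
  expect_setequal(paste(m@gene, m@protein),
                  paste(sim$map@gene, sim$map@protein))
})

test_that("many-to-many noise pairs stay within the mapped universe", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 1400L), seed = 21,
                           extraPairs = 50L)
  expect_gt(length(sim$map@gene), 1235L)
  expect_identical(length(sim$universe), 1235L)
})
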