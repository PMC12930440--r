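test_that("universe construction intersects mapped and tested ids", {
  m <- crossModalMap(c("g1", "g2"), c("p1", "p2"))
  u <- buildUniverse(c("g1", "g2", "g3"), c("p1", "p2"), m)
  expect_setequal(universeIds(u), c("g1", "g2"))
  expect_identical(u@provenance, "cross-modal")
  expect_identical(u@nUnmappedGenes, 1L)  # g3
  # a gene mapping to two present proteins collapses to one entry
  m2 <- crossModalMap(c("g1", "g1", "g2"), c("p1", "p2", "p3"))
  u2 <- buildUniverse(c("g1", "g2"), c("p1", "p2", "p3"), m2)
  expect_setequal(universeIds(u2), c("g1", "g2"))
  expect_error(buildUniverse("gX", "pX", m), "empty")
})

test_that("universe construction is order-independent and idempotent", {
  set.seed(2)
  genes <- sprintf("G%03d", 1:50)
  prots <- sprintf("P%03d", 1:30)
  m <- crossModalMap(sample(genes, 25), sample(prots, 25))
  u1 <- buildUniverse(genes, prots, m)
  u2 <- buildUniverse(rev(genes), sample(prots), m)
  expect_setequal(universeIds(u1), universeIds(u2))
  u3 <- buildUniverse(universeIds(u1), prots, m)
  expect_setequal(universeIds(u3), universeIds(u1))
})

test_that("generator realizes the printed universe arithmetic", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 3000L), seed = 4)
  expect_identical(length(sim$universe), 1235L)
  expect_identical(sim$universe@nGenes, 3000L)
  expect_identical(sim$universe@nProteins, 1461L)
})

test_that("protein tables collapse to gene space per policy", {
  tab <- differentialTable(c("p1", "p2", "p3"), c(1, 2, 3),
                           c(0.5, 0.01, 0.2), modality = "protein")
  m <- crossModalMap(c("g1", "g1", "g2"), c("p1", "p2", "p3"))
  best <- mapProteinTable(tab, m)
  expect_equal(unname(log2FoldChange(best)["g1"]), 2)  # p2 has smaller p
  m@collapsePolicy <- "first"
  first <- mapProteinTable(tab, m)
  expect_equal(unname(log2FoldChange(first)["g1"]), 1)
  m@collapsePolicy <- "mean_lfc"
  avg <- mapProteinTable(tab, m)
  expect_equal(unname(log2FoldChange(avg)["g1"]), 1.5)
  expect_equal(unname(pValues(avg)["g1"]), 0.01)
})

test_that("temporal profile equals standalone statistics at one timepoint", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 2000L), seed = 6)
  uni <- universeIds(sim$universe)
  prof <- temporalConcordance(sim$neuronal, sim$csfSeries, sim$map,
                              universe = sim$universe, nPerm = 500,
                              seed = 31)
  pr <- profileTable(prof)
  t <- 5L
  gU <- SigConcord:::.restrictTable(sim$neuronal, uni)
  pU <- SigConcord:::.restrictTable(mapProteinTable(sim$csfSeries[[t]],
                                                    sim$map), uni)
  pU@stats$adj_p <- bhFDR(pU@stats$p_value)
  sg <- callSignature(gU, signatureThresholds(0.05, 0), uni)
  sp <- callSignature(pU, signatureThresholds(0.05, 0, useAdjusted = TRUE),
                      uni)
  ct <- overlapCounts(sg, sp, uni)
  expect_identical(pr$overlap[t], ct@a)
  expect_identical(pr$nGeneSig[t], length(sg))
  expect_identical(pr$nProteinSig[t], length(sp))
  common <- intersect(members(sg), members(sp))
  res <- spearmanRhoP(log2FoldChange(gU)[common], log2FoldChange(pU)[common])
  expect_equal(pr$rho[t], res@rho)
  expect_equal(pr$p[t], res@p)
  # q column is the BH adjustment of the defined correlation p-values
  def <- !is.na(pr$p)
  expect_equal(pr$q[def], bhFDR(pr$p[def]))
})

test_that("identical tables under an identity map give rho 1", {
  ids <- sprintf("G%03d", 1:80)
  set.seed(8)
  lfc <- rnorm(80, sd = 2)
  p <- runif(80)^3
  gene <- differentialTable(ids, lfc, p, agent = "HNK", timepointHours = 24)
  prot <- differentialTable(ids, lfc, p, agent = "CSF", timepointHours = 2,
                            modality = "protein")
  m <- crossModalMap(ids, ids)
  prof <- profileTable(temporalConcordance(gene, list(prot), m,
                                           nPerm = 200, seed = 1))
  expect_equal(prof$rho[1], 1)
  expect_identical(prof$kAgree[1], prof$overlap[1])
})

test_that("null series yields a flat, unenriched profile", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 2000L,
                                         crossmodalEnrichment = 1),
                           seed = 12)
  pr <- profileTable(temporalConcordance(sim$neuronal, sim$csfSeries,
                                         sim$map, universe = sim$universe,
                                         nPerm = 400, seed = 2))
  # no timepoint should show extreme enrichment; |rho| stays small
  expect_true(all(pr$overlapP > 1 / 401))
  expect_true(all(abs(pr$rho) < 0.5, na.rm = TRUE))
})

test_that("profiles are reproducible given a seed and tolerate small overlaps", {
  sim <- simCrossModalPair(syntheticSpec(nGenes = 2000L), seed = 14)
  p1 <- profileTable(temporalConcordance(sim$neuronal, sim$csfSeries,
                                         sim$map, universe = sim$universe,
                                         nPerm = 300, seed = 77))
  p2 <- profileTable(temporalConcordance(sim$neuronal, sim$csfSeries,
                                         sim$map, universe = sim$universe,
                                         nPerm = 300, seed = 77))
  expect_identical(p1, p2)
  # fewer than 3 overlapping analytes -> NA correlation, pipeline continues
  ids <- sprintf("G%03d", 1:60)
  gene <- differentialTable(ids, c(2, 2, rep(0.1, 58)),
                            c(0.001, 0.002, runif(58, 0.5, 1)),
                            agent = "HNK", timepointHours = 24)
  prot <- differentialTable(ids, c(2, 2, rep(0.1, 58)),
                            c(1e-6, 1e-6, runif(58, 0.5, 1)),
                            modality = "protein", timepointHours = 4)
  prof <- profileTable(temporalConcordance(gene, list(prot),
                                           crossModalMap(ids, ids),
                                           nPerm = 100, seed = 3))
  expect_true(is.na(prof$rho[1]))
  expect_identical(prof$overlap[1], 2L)
})
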