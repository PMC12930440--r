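test_that("differential tables read from TSV with contract errors", {
  tab <- readDifferentialTable(tinyDiffTSV(), agent = "HNK",
                               timepointHours = 24)
  expect_s4_class(tab, "DifferentialTable")
  expect_length(tab, 3L)
  expect_identical(analyteIds(tab), c("GRN", "NECTIN2", "PDIA1"))
  expect_identical(conditionLabel(tab), "HNK_24h_gene")

  noP <- writeTempTSV(c("analyte\tlog2fc", "GRN\t1.2"))
  expect_error(readDifferentialTable(noP), "pvalue")

  dup <- writeTempTSV(c("analyte\tlog2fc\tpvalue",
                        "GRN\t1.2\t0.01", "GRN\t0.5\t0.2"))
  expect_error(readDifferentialTable(dup), "GRN")

  badNum <- writeTempTSV(c("analyte\tlog2fc\tpvalue",
                           "GRN\t1.2\t0.01", "TP53\toops\t0.2",
                           "MAPT\t0.3\t0.5"))
  expect_warning(tab2 <- readDifferentialTable(badNum), "rows 2")
  expect_length(tab2, 2L)
})

test_that("write/read round trip is bit-comparable for finite values", {
  set.seed(7)
  tab <- differentialTable(sprintf("G%03d", 1:50), rnorm(50),
                           runif(50), runif(50), agent = "DOI",
                           timepointHours = 6)
  path <- tempfile(fileext = ".tsv")
  writeDifferentialTable(tab, path)
  back <- readDifferentialTable(path, agent = "DOI", timepointHours = 6)
  expect_identical(back@stats$analyte_id, tab@stats$analyte_id)
  expect_identical(back@stats$log2fc, tab@stats$log2fc)
  expect_identical(back@stats$p_value, tab@stats$p_value)
  expect_identical(back@stats$adj_p, tab@stats$adj_p)
})

test_that("low-expression filter applies strict CPM and sample cutoffs", {
  m <- rbind(kept_exact5 = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.0),
             all_zero = rep(0, 6),
             only4 = c(0.2, 0.2, 0.2, 0.2, 0, 0),
             boundary = rep(0.1, 6))  # 0.1 is not > 0.1
  expect_identical(filterLowExpression(m, 0.1, 5), "kept_exact5")
  # invariant under column permutation
  perm <- m[, c(4, 1, 6, 2, 5, 3)]
  expect_identical(filterLowExpression(perm, 0.1, 5),
                   filterLowExpression(m, 0.1, 5))
  expect_identical(filterLowExpression(matrix(numeric(), 0, 0)), character())
  expect_error(filterLowExpression(m, 0.1, 7), "minSamples")
})

test_that("signature calling uses strict cutoffs and sign directions", {
  tab <- differentialTable(c("up", "atLfc", "pFail", "down", "zero"),
                           c(2.0, 1.5, -3.0, -2.2, 0),
                           c(0.005, 0.005, 0.02, 0.004, 0.001))
  sig <- callSignature(tab, signatureThresholds(0.01, 1.5))
  expect_setequal(members(sig), c("up", "down"))
  expect_identical(unname(directions(sig)[c("up", "down")]), c(1L, -1L))
  # strict boundary: |log2fc| = cutoff and p = cutoff are excluded
  tab2 <- differentialTable("x", 1.5, 0.01)
  expect_length(members(callSignature(tab2, signatureThresholds(0.01, 1.5))), 0L)
  # zero log2fc is never a member even with lfcCutoff = 0
  sig0 <- callSignature(tab, signatureThresholds(0.01, 0))
  expect_false("zero" %in% members(sig0))
})

test_that("signature calling is monotone in both thresholds", {
  set.seed(11)
  tab <- differentialTable(sprintf("G%03d", 1:300), rnorm(300, sd = 2),
                           runif(300)^2)
  for (i in 1:10) {
    p1 <- runif(1, 0.001, 0.2); p2 <- min(p1 * runif(1, 1, 5), 0.99)
    l1 <- runif(1, 0, 2); l2 <- l1 * runif(1)
    strict <- members(callSignature(tab, signatureThresholds(p1, l1)))
    loose <- members(callSignature(tab, signatureThresholds(p2, l2)))
    expect_true(all(strict %in% loose))
  }
})

test_that("adjusted-p calling errors name offending analytes", {
  tab <- differentialTable(c("a", "b"), c(2, 3), c(0.001, 0.001),
                           adj_p = c(0.01, NA))
  expect_error(callSignature(tab, signatureThresholds(useAdjusted = TRUE)),
               "b")
  # missing raw stats are dropped and tallied, not errors
  tab2 <- differentialTable(c("a", "b"), c(2, NA), c(0.001, 0.001))
  sig <- callSignature(tab2, signatureThresholds(0.01, 1.5))
  expect_identical(sig@nDropped, 1L)
  expect_identical(members(sig), "a")
})

test_that("signature sets restrict to an attached universe", {
  tab <- differentialTable(c("a", "b", "c"), c(2, 2, 2), rep(0.001, 3))
  sig <- callSignature(tab, signatureThresholds(0.01, 1.5),
                       universe = c("a", "b"))
  expect_setequal(members(sig), c("a", "b"))
  expect_setequal(sig@universe, c("a", "b"))
})

test_that("signature sets survive a write/read round trip", {
  sig <- signatureSet(c("g1", "g2"), c(1L, -1L), condition = "HNK_24h_gene")
  path <- tempfile(fileext = ".tsv")
  writeSignatureSet(sig, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- readSignatureSet(path, condition = "HNK_24h_gene")
  expect_identical(members(back), members(sig))
  expect_identical(directions(back), directions(sig))
})
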