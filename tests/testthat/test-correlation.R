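test_that("Spearman rho follows the rank closed form and flags edge cases", {
  res <- spearmanRhoP(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res@rho, 1 - 6 * 4 / (5 * 24))  # Sum d^2 = 4 -> rho = 0.8
  expect_identical(res@method, "exact-enumeration")
  expect_equal(spearmanRhoP(1:10, (1:10)^3)@rho, 1)
  expect_equal(spearmanRhoP(1:10, rev(1:10))@rho, -1)
  expect_warning(resC <- spearmanRhoP(rep(1, 5), 1:5), "constant")
  expect_identical(resC@method, "undefined")
  expect_true(is.na(resC@rho))
  expect_error(spearmanRhoP(1:4, 1:5), "equal length")
  expect_error(spearmanRhoP(c(1, 2, Inf), 1:3), "finite")
})

test_that("Spearman p-values match cor.test on exact and approximate paths", {
  # exact path (n <= 8, no ties)
  ref <- suppressWarnings(cor.test(1:5, c(1, 3, 2, 5, 4),
                                   method = "spearman"))
  res <- spearmanRhoP(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res@p, ref$p.value, tolerance = 1e-10)
  # t-approximation path with ties
  set.seed(21)
  x <- round(rnorm(40), 1); y <- round(x + rnorm(40), 1)
  ref2 <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
  res2 <- spearmanRhoP(x, y)
  expect_identical(res2@method, "t-approximation")
  expect_equal(res2@rho, unname(ref2$estimate), tolerance = 1e-10)
  expect_equal(res2@p, ref2$p.value, tolerance = 1e-8)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearmanRhoP(x, y)
  expect_equal(spearmanRhoP(exp(x), y)@rho, base@rho)
  expect_equal(spearmanRhoP(x, 3 * y - 10)@rho, base@rho)
  expect_equal(spearmanRhoP(rank(x), y)@rho, base@rho)
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.3), 0.3)
  expect_equal(bhFDR(c(0.005, 0.1)), c(0.01, 0.1))
  # order preserved, elementwise >= input, and re-adjusting an already
  # flattened adjusted vector is a fixed point
  p <- c(0.04, 0.001, 0.8, 0.02)
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  flat <- bhFDR(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bhFDR(flat), flat)
  expect_error(bhFDR(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bhFDR(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("correlation matrix recovers identical and mirrored tables", {
  set.seed(9)
  ids <- sprintf("G%03d", 1:200)
  lfc <- rnorm(200, sd = 2)
  p <- 2 * pnorm(-abs(lfc) / 0.5)
  t1 <- differentialTable(ids, lfc, p, agent = "a", timepointHours = 6)
  t2 <- differentialTable(ids, lfc, p, agent = "b", timepointHours = 6)
  t3 <- differentialTable(ids, -lfc, p, agent = "a", timepointHours = 24)
  cm <- signatureCorrelationMatrix(list(t1, t2, t3),
                                   signatureThresholds(0.05, 0))
  expect_equal(cm@rho["a_6h_gene", "b_6h_gene"], 1)
  expect_equal(cm@rho["a_6h_gene", "a_24h_gene"], -1)
  expect_equal(diag(cm@rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm@rho, t(cm@rho))
})

test_that("correlation matrix permutes with table order and flags tiny overlaps", {
  set.seed(13)
  ids <- sprintf("G%03d", 1:100)
  mk <- function(agent, tp) differentialTable(ids, rnorm(100, sd = 2),
                                              runif(100)^2, agent = agent,
                                              timepointHours = tp)
  tabs <- list(mk("a", 6), mk("b", 6), mk("c", 24))
  sel <- signatureThresholds(0.2, 0)
  cm1 <- signatureCorrelationMatrix(tabs, sel)
  cm2 <- signatureCorrelationMatrix(tabs[c(3, 1, 2)], sel)
  expect_equal(cm2@rho[cm1@labels, cm1@labels], cm1@rho)
  # disjoint identifier spaces -> undefined entries, not errors
  t4 <- differentialTable(paste0("Z", 1:10), rnorm(10, sd = 3),
                          rep(0.001, 10), agent = "d", timepointHours = 6)
  cm3 <- signatureCorrelationMatrix(list(tabs[[1]], t4), sel)
  expect_true(is.na(cm3@rho[1, 2]))
  expect_identical(cm3@nShared[1, 2], 0L)
})
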