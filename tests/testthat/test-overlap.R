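test_that("overlap counts reproduce the cross-modal 2x2 arithmetic", {
  s <- paperOverlapSets()
  ct <- overlapCounts(s$A, s$B, s$universe)
  expect_identical(c(ct@a, ct@b, ct@c, ct@d), c(28L, 44L, 336L, 827L))
  expect_identical(universeSize(ct), 1235L)

  uni <- sprintf("g%02d", 1:10)
  empty <- overlapCounts(character(), uni[1:4], uni)
  expect_identical(c(empty@a, empty@b, empty@c, empty@d), c(0L, 0L, 4L, 6L))
  full <- overlapCounts(uni, uni, uni)
  expect_identical(c(full@a, full@b, full@c, full@d), c(10L, 0L, 0L, 0L))
  expect_error(overlapCounts(c(uni, "zz"), uni, uni), "outside the universe")
})

test_that("hypergeometric tail matches subset-enumeration oracle", {
  # N=10, |A|=3, |B|=4: enumerate all C(10,3) placements of A
  uni <- 1:10
  inB <- uni <= 4
  combos <- combn(10, 3)
  tailEnum <- mean(colSums(matrix(inB[combos], 3)) >= 2)
  expect_equal(tailEnum, 1 / 3)
  ct <- overlapCounts(paste0("u", 1:3), paste0("u", c(1, 2, 4, 5)),
                      paste0("u", 1:10))
  expect_identical(ct@a, 2L)
  expect_equal(hypergeometricP(ct), 1 / 3, tolerance = 1e-12)

  # closed-form summation oracle across a grid of configurations
  set.seed(3)
  for (i in 1:25) {
    N <- sample(5:60, 1)
    nA <- sample.int(N, 1); nB <- sample.int(N, 1)
    supp <- max(0, nA + nB - N):min(nA, nB)
    a <- supp[sample.int(length(supp), 1)]
    ct <- contingencyTable(a, nA - a, nB - a, N - nA - nB + a)
    expect_equal(hypergeometricP(ct), hyperTailOracle(N, nA, nB, a),
                 tolerance = 1e-10)
  }

  # degenerate support: only one possible overlap value -> p = 1
  ctDeg <- contingencyTable(5, 0, 0, 0)
  expect_equal(hypergeometricP(ctDeg), 1)

  # monotone in a for fixed margins
  ps <- sapply(0:3, function(a)
    hypergeometricP(contingencyTable(a, 3 - a, 4 - a, 10 - 7 + a)))
  expect_true(all(diff(ps) <= 0))
})

test_that("permutation p agrees with the exact tail and is reproducible", {
  uni <- paste0("u", 1:10)
  A <- uni[1:3]; B <- uni[c(1, 2, 4, 5)]
  p1 <- permutationOverlapP(A, B, uni, nPerm = 1e5, seed = 42)
  p2 <- permutationOverlapP(A, B, uni, nPerm = 1e5, seed = 42)
  expect_identical(p1, p2)
  expect_lt(abs(p1 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 1e5) + 1e-5)
  # maximal overlap always attained when A = B = U
  expect_equal(permutationOverlapP(uni, uni, uni, nPerm = 500, seed = 1), 1)
  expect_error(permutationOverlapP(A, B, uni, nPerm = 0), "nPerm")
})

test_that("odds ratio and Jaccard follow the 2x2 closed forms", {
  r <- oddsRatioJaccard(contingencyTable(28, 44, 336, 827))
  expect_equal(r$odds_ratio, (28 * 827) / (44 * 336), tolerance = 1e-12)
  expect_equal(r$jaccard, 28 / 408, tolerance = 1e-12)
  # symmetry under cell swap b <-> c (swapping A and B)
  r2 <- oddsRatioJaccard(contingencyTable(28, 336, 44, 827))
  expect_equal(r2$odds_ratio, r$odds_ratio)
  expect_equal(r2$jaccard, r$jaccard)
  expect_equal(oddsRatioJaccard(contingencyTable(3, 3, 3, 3))$odds_ratio, 1)
  # Haldane-Anscombe correction on zero cells
  expect_equal(oddsRatioJaccard(contingencyTable(2, 0, 1, 7))$odds_ratio,
               (2.5 * 7.5) / (0.5 * 1.5))
  expect_equal(oddsRatioJaccard(contingencyTable(0, 0, 0, 5))$jaccard, 0)
})

test_that("background agreement probability follows the product form", {
  uni <- sprintf("x%02d", 1:20)
  mk <- function(lfc) differentialTable(uni, lfc, rep(0.5, 20))
  # uA = 0.6, uB = 0.7 -> p0 = 0.42 + 0.12 = 0.54
  a <- mk(c(rep(1, 12), rep(-1, 8)))
  b <- mk(c(rep(1, 14), rep(-1, 6)))
  expect_equal(as.numeric(backgroundAgreementProb(a, b, uni)), 0.54)
  # uA = uB = 1 -> 1 ; uA = 0.5 -> 0.5 regardless of uB
  expect_equal(as.numeric(backgroundAgreementProb(mk(rep(1, 20)),
                                                  mk(rep(1, 20)), uni)), 1)
  half <- mk(rep(c(1, -1), 10))
  expect_equal(as.numeric(backgroundAgreementProb(half, b, uni)), 0.5)
  # zero log2fc excluded from numerator and denominator
  z <- mk(c(rep(1, 6), rep(-1, 4), rep(0, 10)))
  expect_equal(attr(backgroundAgreementProb(z, b, uni), "uA"), 0.6)
  expect_error(backgroundAgreementProb(mk(rep(0, 20)), b, uni), "empty")
})

test_that("directional concordance uses the exact binomial upper tail", {
  mkSig <- function(ids, dirs) signatureSet(ids, dirs)
  # 3 of 3 agree at p0 = 0.5 -> 0.125
  A <- mkSig(c("a", "b", "c"), c(1L, -1L, 1L))
  expect_equal(directionalConcordance(A, A, 0.5)@pBinom, 0.125)
  # closed-form binomial sum for the 25-of-28 configuration at p0 = 0.52
  # (verified against a 1e6-replicate Bernoulli simulation: 3.3e-5)
  oracle <- sum(choose(28, 25:28) * 0.52^(25:28) * 0.48^(3:0))
  B25 <- mkSig(sprintf("g%02d", 1:28), c(rep(1L, 25), rep(-1L, 3)))
  A28 <- mkSig(sprintf("g%02d", 1:28), rep(1L, 28))
  res <- directionalConcordance(A28, B25, 0.52)
  expect_identical(c(res@nOverlap, res@kAgree), c(28L, 25L))
  expect_equal(res@pBinom, oracle, tolerance = 1e-10)
  # degenerate nulls
  expect_equal(directionalConcordance(A, A, 1)@pBinom, 1)
  empty <- directionalConcordance(A, mkSig("zz", 1L), 0.5)
  expect_identical(empty@nOverlap, 0L)
  expect_equal(empty@pBinom, 1)
})

test_that("percentage overlap reports both denominator conventions", {
  ct <- contingencyTable(28, 44, 336, 827)
  po <- percentOverlap(ct)
  expect_equal(unname(po["pct_of_union"]), 100 * 28 / 408)
  expect_equal(unname(po["pct_of_smaller"]), 100 * 28 / 72)
})

test_that("overlapTest bundles consistent statistics", {
  s <- paperOverlapSets()
  res <- overlapTest(s$A, s$B, s$universe, nPerm = 2000, seed = 9)
  expect_equal(res@expectedOverlap, 72 * 364 / 1235, tolerance = 1e-12)
  expect_equal(res@pHyper, hyperTailOracle(1235, 72, 364, 28),
               tolerance = 1e-10)
  expect_identical(res@nPerm, 2000L)
  expect_identical(res@seed, 9L)
  expect_true(res@pPerm > 0 && res@pPerm <= 1)
})
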