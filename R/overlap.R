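## Overlap-statistics module: hypergeometric and permutation enrichment,
## odds ratio / Jaccard, directional concordance.

#' Construct a 2x2 overlap contingency table
#'
#' @param a overlap count, @param b in A only, @param c in B only,
#' @param d in neither.
#' @return a \linkS4class{ContingencyTable}.
#' @export
contingencyTable <- function(a, b, c, d) {
  new("ContingencyTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d))
}

#' @rdname ContingencyTable-class
#' @param x a \linkS4class{ContingencyTable}.
#' @export
universeSize <- function(x) x@a + x@b + x@c + x@d

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable (N = %d):\n", universeSize(object)))
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(c("in A", "not A"), c("in B", "not B")))
  print(m)
})

#' Overlap counts of two signatures over a universe
#'
#' @param A,B signature sets (\linkS4class{SignatureSet} or character
#'   vectors of analyte ids). Both must be subsets of the universe.
#' @param universe background ids (character vector or
#'   \linkS4class{AnalyteUniverse}).
#' @return a \linkS4class{ContingencyTable} with a = |A n B|, b = |A \\ B|,
#'   c = |B \\ A|, d = N - a - b - c.
#' @examples
#' u <- paste0("g", 1:10)
#' overlapCounts(u[1:3], u[2:5], u)
#' @export
overlapCounts <- function(A, B, universe) {
  a_ids <- .memberIds(A); b_ids <- .memberIds(B)
  uni <- .universeIds(universe)
  if (anyDuplicated(uni)) stop("universe ids must be unique")
  .checkInUniverse(a_ids, uni, "A")
  .checkInUniverse(b_ids, uni, "B")
  a <- length(intersect(a_ids, b_ids))
  b <- length(setdiff(a_ids, b_ids))
  c <- length(setdiff(b_ids, a_ids))
  d <- length(uni) - a - b - c
  contingencyTable(a, b, c, d)
}

.checkInUniverse <- function(ids, uni, label) {
  out <- setdiff(ids, uni)
  if (length(out))
    stop(sprintf("%d member(s) of %s outside the universe: %s", length(out),
                 label, paste(head(out, 10), collapse = ", ")))
}

#' Exact hypergeometric overlap p-value
#'
#' Upper-tail probability P(X >= a) of observing at least the seen overlap
#' when a set of size |A| is placed uniformly at random within the universe,
#' with |B| marked elements. Computed with the exact hypergeometric tail
#' (log-space stable summation via \code{\link[stats]{phyper}}).
#'
#' @param t a \linkS4class{ContingencyTable}.
#' @param alternative \code{"enrichment"} (P(X >= a), default) or
#'   \code{"depletion"} (P(X <= a)).
#' @return the tail probability.
#' @examples
#' hypergeometricP(contingencyTable(2, 1, 2, 5))  # = 1/3
#' @export
hypergeometricP <- function(t, alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  sizeA <- t@a + t@b
  sizeB <- t@a + t@c
  N <- universeSize(t)
  if (alternative == "enrichment")
    phyper(t@a - 1L, sizeB, N - sizeB, sizeA, lower.tail = FALSE)
  else
    phyper(t@a, sizeB, N - sizeB, sizeA, lower.tail = TRUE)
}

#' Permutation overlap p-value
#'
#' Draws \code{nPerm} uniform random subsets of size |A| from the universe
#' (holding B fixed; equivalent in distribution to resampling both sets
#' under the hypergeometric null) and estimates
#' p = (1 + #\{permuted overlap >= a\}) / (nPerm + 1). The +1 convention
#' avoids zero p-values. Reproducible given \code{seed}; the resampling loop
#' runs in compiled code against R's RNG.
#'
#' @inheritParams overlapCounts
#' @param nPerm number of permutations (>= 1).
#' @param seed optional integer seed applied locally (the caller's RNG state
#'   is restored afterwards).
#' @param alternative \code{"enrichment"} counts permuted overlaps >= the
#'   observed one; \code{"depletion"} counts <=.
#' @param midP if TRUE, ties with the observed overlap contribute half a
#'   count (mid-p). The default estimator is conservative
#'   (super-uniform under the null) because the overlap count is discrete;
#'   the mid-p variant is the appropriate one for calibration diagnostics,
#'   at the cost of no longer being a valid (always-conservative) p-value.
#' @return the permutation p-value.
#' @export
permutationOverlapP <- function(A, B, universe, nPerm = 10000L, seed = NULL,
                                alternative = c("enrichment", "depletion"),
                                midP = FALSE) {
  alternative <- match.arg(alternative)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  a_ids <- .memberIds(A); b_ids <- .memberIds(B)
  uni <- .universeIds(universe)
  .checkInUniverse(a_ids, uni, "A")
  .checkInUniverse(b_ids, uni, "B")
  counts <- .permOverlapCounts(length(uni), length(a_ids),
                               uni %in% b_ids, nPerm, seed)
  aObs <- length(intersect(a_ids, b_ids))
  strict <- if (alternative == "enrichment") sum(counts > aObs)
            else sum(counts < aObs)
  ties <- sum(counts == aObs)
  hits <- if (midP) strict + 0.5 * ties else strict + ties
  (1 + hits) / (nPerm + 1)
}

.permOverlapCounts <- function(N, nDraw, inB, nPerm, seed = NULL) {
  .withSeed(seed, function()
    perm_overlap_counts(as.integer(N), as.integer(nDraw),
                        as.logical(inB), as.integer(nPerm)))
}

## run code under a locally-set seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  code()
}

#' Odds ratio and Jaccard index of an overlap table
#'
#' OR = (a d)/(b c); when any cell is zero the Haldane-Anscombe correction
#' (+0.5 to all four cells) is applied. Jaccard = a/(a+b+c), defined as 0
#' for an empty union. Both are symmetric in A and B.
#'
#' @param t a \linkS4class{ContingencyTable}.
#' @return list with elements \code{odds_ratio} and \code{jaccard}.
#' @examples
#' oddsRatioJaccard(contingencyTable(28, 44, 336, 827))
#' @export
oddsRatioJaccard <- function(t) {
  cells <- c(t@a, t@b, t@c, t@d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  uni <- t@a + t@b + t@c
  jac <- if (uni > 0L) t@a / uni else 0
  list(odds_ratio = or, jaccard = jac)
}

#' Full overlap-enrichment test
#'
#' Convenience wrapper combining \code{\link{overlapCounts}},
#' \code{\link{hypergeometricP}}, \code{\link{permutationOverlapP}} and
#' \code{\link{oddsRatioJaccard}} into one \linkS4class{OverlapResult}.
#'
#' @inheritParams permutationOverlapP
#' @param nPerm permutations for the permutation p (set to 0 to skip it).
#' @return an \linkS4class{OverlapResult}.
#' @export
overlapTest <- function(A, B, universe, nPerm = 10000L, seed = NULL,
                        alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  ct <- overlapCounts(A, B, universe)
  orj <- oddsRatioJaccard(ct)
  pPerm <- NA_real_
  if (nPerm >= 1L)
    pPerm <- permutationOverlapP(A, B, universe, nPerm = nPerm, seed = seed,
                                 alternative = alternative)
  new("OverlapResult", contingency = ct,
      expectedOverlap = (ct@a + ct@b) * (ct@a + ct@c) / universeSize(ct),
      pHyper = hypergeometricP(ct, alternative),
      pPerm = pPerm, oddsRatio = orj$odds_ratio, jaccard = orj$jaccard,
      nPerm = as.integer(max(nPerm, 0L)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "OverlapResult", function(object) {
  ct <- object@contingency
  cat(sprintf("OverlapResult: a=%d b=%d c=%d d=%d (N=%d)\n",
              ct@a, ct@b, ct@c, ct@d, universeSize(ct)))
  cat(sprintf("  expected overlap %.2f | hypergeometric p %.3g | OR %.3g | Jaccard %.3g\n",
              object@expectedOverlap, object@pHyper, object@oddsRatio,
              object@jaccard))
  if (!is.na(object@pPerm))
    cat(sprintf("  permutation p %.3g (nPerm=%d, seed=%s)\n", object@pPerm,
                object@nPerm, ifelse(is.na(object@seed), "none", object@seed)))
})

#' Null agreement probability from background direction proportions
#'
#' For two differential tables restricted to a common universe, computes
#' p0 = uA uB + (1-uA)(1-uB) where uX is the proportion of universe analytes
#' with a positive log2 fold change in table X. This is the chance that two
#' independent analytes drawn with the background up/down proportions agree
#' in direction, and serves as the null parameter of
#' \code{\link{directionalConcordance}}. Analytes with zero or missing
#' log2fc are excluded from numerator and denominator; analytes missing from
#' either table are excluded and reported via an attribute.
#'
#' @param tableA,tableB \linkS4class{DifferentialTable}s (tableB typically
#'   already translated to the gene identifier space).
#' @param universe background ids (character or
#'   \linkS4class{AnalyteUniverse}).
#' @return p0, with attributes \code{uA}, \code{uB} and \code{nExcluded}.
#' @export
backgroundAgreementProb <- function(tableA, tableB, universe) {
  uni <- .universeIds(universe)
  upProp <- function(tab) {
    lfc <- log2FoldChange(tab)
    lfc <- lfc[names(lfc) %in% uni]
    lfc <- lfc[!is.na(lfc) & lfc != 0]
    if (!length(lfc)) stop("universe empty after exclusions")
    c(mean(lfc > 0), length(uni) - length(lfc))
  }
  a <- upProp(tableA); b <- upProp(tableB)
  p0 <- a[1] * b[1] + (1 - a[1]) * (1 - b[1])
  attr(p0, "uA") <- a[1]; attr(p0, "uB") <- b[1]
  attr(p0, "nExcluded") <- c(A = a[2], B = b[2])
  p0
}

#' Directional concordance of two signatures
#'
#' Counts how many analytes in A n B have the same fold-change direction in
#' both signatures and tests the count against Binomial(|A n B|, p0) with an
#' exact upper tail P(X >= k). p0 should come from
#' \code{\link{backgroundAgreementProb}} (the full tested background), not
#' from the significant analytes alone.
#'
#' @param A,B \linkS4class{SignatureSet}s with directions.
#' @param p0 null agreement probability in [0, 1].
#' @return a \linkS4class{ConcordanceResult}; an empty overlap gives
#'   nOverlap = 0 and pBinom = 1.
#' @export
directionalConcordance <- function(A, B, p0) {
  stopifnot(is(A, "SignatureSet"), is(B, "SignatureSet"))
  p0 <- as.numeric(p0)
  if (is.na(p0) || p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  common <- intersect(A@members, B@members)
  n <- length(common)
  if (n == 0L)
    return(new("ConcordanceResult", nOverlap = 0L, kAgree = 0L, p0 = p0,
               pBinom = 1))
  k <- sum(A@directions[common] == B@directions[common])
  pB <- pbinom(k - 1L, n, p0, lower.tail = FALSE)
  new("ConcordanceResult", nOverlap = as.integer(n), kAgree = as.integer(k),
      p0 = p0, pBinom = pB)
}

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: %d of %d agree in direction (null p0 = %.3g)\n",
              object@kAgree, object@nOverlap, object@p0))
  cat(sprintf("  exact binomial upper tail p = %.3g\n", object@pBinom))
})

#' Percentage overlap under both denominator conventions
#'
#' Reports the overlap as a percentage of the union and of the smaller set.
#'
#' @param t a \linkS4class{ContingencyTable}.
#' @return named numeric vector \code{pct_of_union}, \code{pct_of_smaller}.
#' @export
percentOverlap <- function(t) {
  uni <- t@a + t@b + t@c
  small <- min(t@a + t@b, t@a + t@c)
  c(pct_of_union = if (uni > 0) 100 * t@a / uni else 0,
    pct_of_smaller = if (small > 0) 100 * t@a / small else 0)
}
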