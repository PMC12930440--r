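## Correlation module: tie-aware Spearman, BH FDR, cross-condition matrices.

#' Spearman rank correlation with p-value
#'
#' rho is computed from average-ranked data (midranks for ties). The
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom;
#' for n <= 8 without ties the exact permutation distribution is enumerated
#' instead. A constant input vector yields a flagged result
#' (method \code{"undefined"}, rho = NA) rather than a silent NaN.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return a \linkS4class{CorrelationResult}.
#' @examples
#' spearmanRhoP(1:5, c(1, 3, 2, 5, 4))  # rho = 0.8
#' @export
spearmanRhoP <- function(x, y,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: rank correlation undefined")
    return(new("CorrelationResult", rho = NA_real_, p = NA_real_,
               n = as.integer(n), method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 8L && !ties) {
    perms <- .permutations(n)
    rhoNull <- apply(perms, 1L, function(p) cor(seq_len(n), p))
    eps <- 1e-12
    p <- switch(alternative,
                two.sided = mean(abs(rhoNull) >= abs(rho) - eps),
                greater = mean(rhoNull >= rho - eps),
                less = mean(rhoNull <= rho + eps))
    method <- "exact-enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
                two.sided = 2 * pt(-abs(tstat), n - 2),
                greater = pt(tstat, n - 2, lower.tail = FALSE),
                less = pt(tstat, n - 2))
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t-approximation"
  }
  new("CorrelationResult", rho = rho, p = p, n = as.integer(n),
      method = method)
}

## all permutations of 1:n as an (n!)-row matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: rho = %.4g, p = %.3g (n = %d, %s)\n",
              object@rho, object@p, object@n, object@method))
})

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates that all inputs lie in (0, 1] and applies the step-up
#' adjustment (capped at 1, input order preserved).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFDR <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Cross-condition correlation matrix of log2 fold changes
#'
#' Restricts to the union of analytes passing \code{selection} in any of the
#' supplied tables, then computes pairwise tie-aware Spearman correlations
#' of the log2fc vectors over the analytes shared by each pair. Pairs with
#' fewer than 3 shared analytes are flagged as undefined (NA).
#'
#' @param tables list of \linkS4class{DifferentialTable}s on a shared
#'   identifier space (>= 2).
#' @param selection a \linkS4class{SignatureThresholds} defining the union
#'   filter.
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
signatureCorrelationMatrix <- function(tables, selection) {
  if (length(tables) < 2L) stop("need at least two tables")
  stopifnot(all(vapply(tables, is, TRUE, "DifferentialTable")))
  labels <- vapply(tables, conditionLabel, "")
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "#")
  sel <- unique(unlist(lapply(tables, function(tb)
    members(callSignature(tb, selection)))))
  k <- length(tables)
  rho <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pmat <- rho
  nmat <- matrix(0L, k, k, dimnames = list(labels, labels))
  diag(rho) <- 1
  lfcs <- lapply(tables, function(tb) {
    v <- log2FoldChange(tb)
    v[names(v) %in% sel & !is.na(v)]
  })
  for (i in seq_len(k)) nmat[i, i] <- length(lfcs[[i]])
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    shared <- intersect(names(lfcs[[i]]), names(lfcs[[j]]))
    nmat[i, j] <- nmat[j, i] <- length(shared)
    if (length(shared) >= 3L) {
      res <- spearmanRhoP(lfcs[[i]][shared], lfcs[[j]][shared])
      rho[i, j] <- rho[j, i] <- res@rho
      pmat[i, j] <- pmat[j, i] <- res@p
    }
  }
  new("CorrelationMatrix", labels = labels, rho = rho, p = pmat,
      nShared = nmat, nSelected = length(sel))
}

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d conditions over %d selected analytes\n",
              length(object@labels), object@nSelected))
  print(round(object@rho, 3))
})

#' Write a correlation matrix as TSV
#'
#' @param x a \linkS4class{CorrelationMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCorrelationMatrix <- function(x, path) {
  out <- data.frame(condition = x@labels, x@rho, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
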