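## Synthetic-data module: generators with planted, recoverable ground truth.
##
## The generators are a stand-in for the real study data: Gaussian effects
## on the log2 scale with p-values derived from z-scores of the noisy
## effects, and directly constructed signature membership on the cross-modal
## side. They emulate the statistical structure the analysis assumes, not
## the raw-data-generating process.

#' Synthetic-data specification
#'
#' See \linkS4class{SyntheticSpec} for the meaning and defaults of every
#' parameter.
#'
#' @param ... named slots overriding the defaults.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @examples
#' syntheticSpec(nGenes = 2000L, crossmodalEnrichment = 1)
#' @export
syntheticSpec <- function(...) {
  args <- list(...)
  intSlots <- c("nGenes", "nProteins", "nMappable", "nGeneSig",
                "nProteinSig", "concordancePeakTimepoint")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SyntheticSpec"), args))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:\n")
  cat(sprintf("  %d genes, %d proteins, %d mappable\n", object@nGenes,
              object@nProteins, object@nMappable))
  cat(sprintf("  conditions: %s x %sh\n",
              paste(object@agents, collapse = "/"),
              paste(object@timepointsHours, collapse = "/")))
  cat(sprintf("  signal %.2f, effect sd %.2f, noise sd %.2f, corr %+.2f / %+.2f\n",
              object@signalFraction, object@effectSd, object@noiseSd,
              object@withinTimeCorr, object@acrossTimeCorr))
  cat(sprintf("  cross-modal: |A|=%d |B|=%d, enrichment %.2f, peak at t%d of %d\n",
              object@nGeneSig, object@nProteinSig,
              object@crossmodalEnrichment, object@concordancePeakTimepoint,
              length(object@csfHours)))
})

## Latent (pre-noise Pearson) correlation needed so that the *observed*
## log2fc vectors realize a target Spearman correlation: the Greiner
## identity rho_pearson = 2 sin(pi rho_spearman / 6) for Gaussian data,
## divided by the noise attenuation effSd^2 / (effSd^2 + noiseSd^2).
.latentCorr <- function(targetSpearman, effSd, noiseSd) {
  atten <- effSd^2 / (effSd^2 + noiseSd^2)
  2 * sin(pi * targetSpearman / 6) / atten
}

.geneIds <- function(n) sprintf("G%06d", seq_len(n))
.proteinIds <- function(n) sprintf("P%06d", seq_len(n))

#' Generate per-condition differential tables with planted correlation
#' structure
#'
#' True effects for a \code{signalFraction} of genes are drawn from a
#' multivariate normal whose correlation matrix realizes the target
#' within-timepoint and across-timepoint Spearman correlations of the
#' observed log2 fold changes (the latent correlations are inflated by the
#' Greiner rank-to-linear identity and by the noise attenuation factor, so
#' the targets refer to what \code{\link{signatureCorrelationMatrix}}
#' measures). Observed log2fc = truth + Gaussian noise; p-values are
#' two-sided normal tails of the noisy effect against the noise scale, so
#' null-gene p-values are exactly uniform. An infeasible correlation target
#' (non-positive-definite latent matrix) is an error raised before any
#' sampling.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed integer seed (applied locally).
#' @return list with \code{tables} (named list of
#'   \linkS4class{DifferentialTable}s, one per agent x timepoint),
#'   and \code{truth} (signal gene ids, true effect matrix, latent
#'   correlation matrix, condition grid).
#' @export
simConditionTables <- function(spec = syntheticSpec(), seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  conds <- expand.grid(agent = spec@agents, hours = spec@timepointsHours,
                       stringsAsFactors = FALSE)
  k <- nrow(conds)
  lw <- .latentCorr(spec@withinTimeCorr, spec@effectSd, spec@noiseSd)
  la <- .latentCorr(spec@acrossTimeCorr, spec@effectSd, spec@noiseSd)
  if (abs(lw) > 1 || abs(la) > 1)
    stop("correlation targets infeasible at this effect/noise ratio")
  R <- matrix(la, k, k)
  for (h in unique(conds$hours)) {
    idx <- which(conds$hours == h)
    R[idx, idx] <- lw
  }
  diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e)
    stop("latent correlation matrix is not positive definite"))
  .withSeed(seed, function() {
    ids <- .geneIds(spec@nGenes)
    ns <- round(spec@signalFraction * spec@nGenes)
    signalIdx <- sort(sample.int(spec@nGenes, ns))
    truth <- matrix(0, spec@nGenes, k)
    if (ns > 0)
      truth[signalIdx, ] <- (matrix(rnorm(ns * k), ns, k) %*% L) *
        spec@effectSd
    obs <- truth + matrix(rnorm(spec@nGenes * k, sd = spec@noiseSd),
                          spec@nGenes, k)
    p <- 2 * pnorm(-abs(obs) / spec@noiseSd)
    tables <- lapply(seq_len(k), function(j) {
      differentialTable(ids, obs[, j], p[, j], bhFDR(p[, j]),
                        agent = conds$agent[j],
                        timepointHours = conds$hours[j], modality = "gene")
    })
    names(tables) <- vapply(tables, conditionLabel, "")
    list(tables = tables,
         truth = list(signalIds = ids[signalIdx],
                      effects = truth[signalIdx, , drop = FALSE],
                      latent = R, conditions = conds))
  })
}

## ramp of the planted cross-modal signal across the CSF series:
## cubic rise to the peak index, linear decay after it
.peakRamp <- function(nT, peak) {
  t <- seq_len(nT)
  ifelse(t <= peak, (t / peak)^3, pmax(0, 1 - 0.6 * (t - peak)))
}

#' Generate a neuronal table, serial CSF protein tables and their mapping
#'
#' Constructs a cross-modal pair with planted overlap enrichment and
#' directional/quantitative concordance ramping to a chosen peak timepoint.
#' Within the mappable universe, a fixed gene signature A of size
#' \code{nGeneSig} is drawn; per CSF timepoint a protein signature B_t is
#' drawn so that the expected called overlap equals
#' \code{crossmodalEnrichment x |A||B|/N} at the peak (ramping from the
#' null expectation |A||B|/N). Gene and protein p-values are constructed so
#' that calling at the default thresholds (uncorrected p on the gene side,
#' FDR within the universe on the protein side) recovers A and B_t exactly.
#' Over the overlapping analytes two signals ramp with the peak: the
#' |log2fc| magnitudes are coupled with strength \code{peakCoupling x ramp},
#' and the fold-change direction agrees with probability ramping from the
#' background null up to \code{agreementAtPeak}; together these drive the
#' Spearman profile and the directional-concordance test. With
#' \code{crossmodalEnrichment <= 1} all couplings are zero and the pair is
#' an exact null. Background fold-change signs are positive with
#' probability \code{upProportion} on both sides, so the
#' directional-concordance null probability is
#' \code{up^2 + (1-up)^2} (0.52 at the default 0.6).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed integer seed (applied locally).
#' @param extraPairs number of additional random many-to-many mapping pairs
#'   appended to the injective base map.
#' @return list with \code{neuronal} (gene table), \code{csfSeries} (list of
#'   protein tables), \code{map} (\linkS4class{CrossModalMap}),
#'   \code{universe} (\linkS4class{AnalyteUniverse}) and \code{truth}
#'   (planted sets, ramps and expected overlaps).
#' @export
simCrossModalPair <- function(spec = syntheticSpec(), seed = 1L,
                              extraPairs = 0L) {
  stopifnot(is(spec, "SyntheticSpec"))
  N <- spec@nMappable
  nA <- spec@nGeneSig
  nB <- spec@nProteinSig
  nT <- length(spec@csfHours)
  w <- .peakRamp(nT, spec@concordancePeakTimepoint)
  e <- spec@crossmodalEnrichment
  eT <- if (e > 1) 1 + (e - 1) * w else rep(e, nT)
  kappaT <- if (e > 1) spec@peakCoupling * w else rep(0, nT)
  pIn <- eT * nB / N
  pOut <- nB * (1 - eT * nA / N) / (N - nA)
  if (any(pIn > 1 | pIn < 0 | pOut > 1 | pOut < 0))
    stop("infeasible enrichment for the requested signature sizes")
  .withSeed(seed, function() {
    geneIds <- .geneIds(spec@nGenes)
    protIds <- .proteinIds(spec@nProteins)
    uniGenes <- sort(sample(geneIds, N))
    mapProt <- sample(protIds, N)
    mapGene <- uniGenes
    if (extraPairs > 0L) {
      xg <- sample(uniGenes, extraPairs, replace = TRUE)
      xp <- sample(protIds, extraPairs, replace = TRUE)
      keep <- !(paste(xg, xp) %in% paste(mapGene, mapProt))
      mapGene <- c(mapGene, xg[keep]); mapProt <- c(mapProt, xp[keep])
      dup <- duplicated(paste(mapGene, mapProt))
      mapGene <- mapGene[!dup]; mapProt <- mapProt[!dup]
    }
    map <- crossModalMap(mapGene, mapProt)
    ## per-analyte Bernoulli membership: signature sizes fluctuate around
    ## their targets the way thresholded calling does under independence
    A <- uniGenes[runif(N) < nA / N]
    if (length(A) < 2L) A <- sample(uniGenes, 2L)
    inUni <- geneIds %in% uniGenes
    inA <- geneIds %in% A

    ## gene table: membership in A is encoded in the p-values so that the
    ## uncorrected cutoff recovers A exactly within the universe
    gSign <- ifelse(runif(spec@nGenes) < spec@upProportion, 1, -1)
    gMag <- ifelse(inA, abs(rnorm(spec@nGenes, 1.5, 0.6)) + 0.1,
                   abs(rnorm(spec@nGenes, 0, 0.4)) + 0.01)
    gLfc <- gSign * gMag
    gP <- numeric(spec@nGenes)
    gP[inA] <- runif(sum(inA), 0, 0.8 * spec@genePCutoff)
    gP[inUni & !inA] <- runif(sum(inUni & !inA), spec@genePCutoff, 1)
    gP[!inUni] <- runif(sum(!inUni))
    gP <- pmin(pmax(gP, .Machine$double.xmin), 1)
    neuronal <- differentialTable(geneIds, gLfc, gP, bhFDR(gP),
                                  agent = "HNK", timepointHours = 24,
                                  modality = "gene")
    glfcByGene <- setNames(gLfc, geneIds)
    sdRef <- stats::sd(glfcByGene[A])

    prot2gene <- setNames(mapGene[seq_len(N)], mapProt[seq_len(N)])
    Bt <- vector("list", nT)
    csf <- vector("list", nT)
    for (t in seq_len(nT)) {
      gOfP <- prot2gene[protIds]
      isMapped <- !is.na(gOfP)
      mappedInA <- isMapped & gOfP %in% A
      pb <- ifelse(mappedInA, pIn[t], pOut[t])
      pb[!isMapped] <- 0
      inB <- runif(spec@nProteins) < pb
      Bt[[t]] <- protIds[inB]
      pSign <- ifelse(runif(spec@nProteins) < spec@upProportion, 1, -1)
      pMag <- ifelse(inB, abs(rnorm(spec@nProteins, 0.8, 0.5)) + 0.05,
                     abs(rnorm(spec@nProteins, 0, 0.4)) + 0.01)
      pLfc <- pSign * pMag
      ## couple overlap analytes to the gene fold changes: magnitudes share
      ## a latent component, directions agree with a ramped probability
      ov <- which(inB & mappedInA)
      if (length(ov) && kappaT[t] > 0) {
        gv <- glfcByGene[gOfP[ov]]
        p0null <- spec@upProportion^2 + (1 - spec@upProportion)^2
        agreeT <- p0null + (spec@agreementAtPeak - p0null) * w[t]
        agree <- runif(length(ov)) < agreeT
        psign <- ifelse(agree, sign(gv), -sign(gv))
        ## direction-discordant analytes get weak magnitudes (a strong
        ## effect reversed across modalities is not the planted biology)
        pmag <- ifelse(agree,
                       kappaT[t] * abs(gv) +
                         sqrt(1 - kappaT[t]^2) *
                         abs(rnorm(length(ov), sd = sdRef)),
                       abs(rnorm(length(ov), sd = 0.3 * sdRef)) + 0.05)
        pLfc[ov] <- psign * pmag
      }
      pP <- numeric(spec@nProteins)
      pP[inB] <- runif(sum(inB), 0, 5e-3)
      pP[!inB] <- runif(sum(!inB), 0.1, 1)
      pP <- pmin(pmax(pP, .Machine$double.xmin), 1)
      csf[[t]] <- differentialTable(protIds, pLfc, pP, bhFDR(pP),
                                    agent = "ketamine",
                                    timepointHours = spec@csfHours[t],
                                    modality = "protein")
    }
    universe <- buildUniverse(geneIds, protIds, map)
    list(neuronal = neuronal, csfSeries = csf, map = map,
         universe = universe,
         truth = list(universeGenes = uniGenes, A = A, B = Bt,
                      ramp = w, enrichment = eT, coupling = kappaT,
                      expectedOverlap = eT * nA * nB / N,
                      peakIndex = spec@concordancePeakTimepoint))
  })
}

#' Generate a per-cell QC metrics table with planted outliers
#'
#' Inlier cells have log-normal UMI and gene counts (correlated) and
#' beta-distributed mitochondrial percentages; a planted outlier
#' subpopulation mixes high-mito cells, low-quality cells (UMI and genes
#' scaled down) and abnormally large cells (scaled up). Labels of the
#' planted outliers are returned alongside the table.
#'
#' @param nCells number of cells (>= 10).
#' @param outlierFraction fraction of planted outliers; must be < 0.5 so
#'   the median stays anchored to the inliers.
#' @param seed integer seed (applied locally).
#' @return list with \code{table} (data.frame: cell_id, n_genes, n_umi,
#'   pct_mito) and \code{truth} (data.frame: cell_id, is_outlier, type).
#' @export
simQCTable <- function(nCells = 2000L, outlierFraction = 0.05, seed = 1L) {
  if (nCells < 10L) stop("nCells must be >= 10")
  if (outlierFraction < 0 || outlierFraction >= 0.5)
    stop("outlierFraction must lie in [0, 0.5): the median must stay anchored to inliers")
  .withSeed(seed, function() {
    lu <- rnorm(nCells, log(8000), 0.11)
    umi <- exp(lu)
    genes <- exp(0.9 * lu + rnorm(nCells, 0, 0.05))
    mito <- 100 * rbeta(nCells, 16, 304)
    type <- rep("inlier", nCells)
    nOut <- round(outlierFraction * nCells)
    if (nOut > 0) {
      idx <- sample.int(nCells, nOut)
      kind <- sample(c("mito_high", "low_quality", "oversized"), nOut,
                     replace = TRUE)
      type[idx] <- kind
      mito[idx[kind == "mito_high"]] <- runif(sum(kind == "mito_high"), 20, 60)
      lowi <- idx[kind == "low_quality"]
      f <- runif(length(lowi), 0.1, 0.3)
      umi[lowi] <- umi[lowi] * f; genes[lowi] <- genes[lowi] * f
      highi <- idx[kind == "oversized"]
      f <- runif(length(highi), 3, 6)
      umi[highi] <- umi[highi] * f; genes[highi] <- genes[highi] * f
    }
    ids <- sprintf("cell%05d", seq_len(nCells))
    list(table = data.frame(cell_id = ids, n_genes = round(genes),
                            n_umi = round(umi), pct_mito = mito,
                            stringsAsFactors = FALSE),
         truth = data.frame(cell_id = ids, is_outlier = type != "inlier",
                            type = type, stringsAsFactors = FALSE))
  })
}

#' Write simulated inputs as the TSV dialects the analysis reads
#'
#' Materializes a \code{\link{simCrossModalPair}} result in a directory:
#' the neuronal table, one CSF table per timepoint, a two-column mapping
#' TSV, and a manifest (\code{csf_manifest.tsv}: path, hours).
#'
#' @param sim result of \code{\link{simCrossModalPair}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeSimulatedInputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeDifferentialTable(sim$neuronal, file.path(dir, "neuronal.tsv"))
  paths <- character(length(sim$csfSeries))
  hours <- numeric(length(sim$csfSeries))
  for (i in seq_along(sim$csfSeries)) {
    paths[i] <- sprintf("csf_t%02d.tsv", i)
    hours[i] <- sim$csfSeries[[i]]@timepointHours
    writeDifferentialTable(sim$csfSeries[[i]], file.path(dir, paths[i]))
  }
  writeCrossModalMap(sim$map, file.path(dir, "mapping.tsv"))
  manifest <- file.path(dir, "csf_manifest.tsv")
  write.table(data.frame(path = paths, hours = hours), manifest,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
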