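## S4 classes for signature comparison and cross-modal concordance.

#' Differential-statistics table for one condition
#'
#' One row per analyte (gene or protein) with its signed log2 fold change,
#' p-value and optionally an externally adjusted p-value, labelled by agent,
#' timepoint (hours) and modality. Missing \code{log2fc}/\code{p_value}
#' entries are tolerated in the table and excluded (and counted) at signature
#' calling.
#'
#' @slot agent character(1), treatment label (e.g. \code{"HNK"}).
#' @slot timepointHours numeric(1), timepoint in hours.
#' @slot modality character(1), \code{"gene"} or \code{"protein"}.
#' @slot stats data.frame with columns \code{analyte_id}, \code{log2fc},
#'   \code{p_value}, \code{adj_p}.
#' @exportClass DifferentialTable
setClass("DifferentialTable",
         representation(agent = "character",
                        timepointHours = "numeric",
                        modality = "character",
                        stats = "data.frame"))

setValidity("DifferentialTable", function(object) {
  msg <- character()
  st <- object@stats
  need <- c("analyte_id", "log2fc", "p_value", "adj_p")
  if (!all(need %in% names(st)))
    return(paste("stats must have columns:", paste(need, collapse = ", ")))
  if (length(object@agent) != 1L || length(object@modality) != 1L ||
      length(object@timepointHours) != 1L)
    msg <- c(msg, "agent, timepointHours and modality must be length 1")
  if (!object@modality %in% c("gene", "protein"))
    msg <- c(msg, "modality must be 'gene' or 'protein'")
  if (nrow(st) > 0) {
    if (anyNA(st$analyte_id) || any(!nzchar(st$analyte_id)))
      msg <- c(msg, "analyte_id must be nonempty")
    if (anyDuplicated(st$analyte_id))
      msg <- c(msg, "analyte_id must be unique within a table")
    pv <- st$p_value[!is.na(st$p_value)]
    if (length(pv) && (any(pv <= 0) || any(pv > 1)))
      msg <- c(msg, "p_value must lie in (0, 1]")
    ap <- st$adj_p[!is.na(st$adj_p)]
    if (length(ap) && (any(ap <= 0) || any(ap > 1)))
      msg <- c(msg, "adj_p must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Signature-calling thresholds
#'
#' @slot pCutoff numeric(1) in (0,1); membership requires p strictly below it.
#' @slot lfcCutoff numeric(1) >= 0; membership requires |log2fc| strictly
#'   above it.
#' @slot useAdjusted logical(1); if TRUE the adjusted p column is thresholded
#'   instead of the raw one.
#' @exportClass SignatureThresholds
setClass("SignatureThresholds",
         representation(pCutoff = "numeric",
                        lfcCutoff = "numeric",
                        useAdjusted = "logical"),
         prototype(pCutoff = 0.01, lfcCutoff = 1.5, useAdjusted = FALSE))

setValidity("SignatureThresholds", function(object) {
  msg <- character()
  if (length(object@pCutoff) != 1L || is.na(object@pCutoff) ||
      object@pCutoff <= 0 || object@pCutoff >= 1)
    msg <- c(msg, "pCutoff must be a single value in (0, 1)")
  if (length(object@lfcCutoff) != 1L || is.na(object@lfcCutoff) ||
      object@lfcCutoff < 0)
    msg <- c(msg, "lfcCutoff must be a single nonnegative value")
  if (length(object@useAdjusted) != 1L || is.na(object@useAdjusted))
    msg <- c(msg, "useAdjusted must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Direction-annotated signature set
#'
#' The analytes called differential for one condition, each annotated with
#' the sign of its log2 fold change.
#'
#' @slot condition character(1) condition label.
#' @slot members character vector of analyte ids.
#' @slot directions named integer vector (+1/-1), one entry per member.
#' @slot universe character vector of background ids (may be empty when no
#'   universe is attached).
#' @slot nDropped integer(1), records excluded for missing statistics.
#' @exportClass SignatureSet
setClass("SignatureSet",
         representation(condition = "character",
                        members = "character",
                        directions = "integer",
                        universe = "character",
                        nDropped = "integer"),
         prototype(universe = character(), nDropped = 0L))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be unique")
  if (length(object@directions) != length(object@members) ||
      !identical(sort(names(object@directions)), sort(object@members)))
    msg <- c(msg, "directions must be defined for every member and only members")
  if (length(object@directions) && !all(object@directions %in% c(-1L, 1L)))
    msg <- c(msg, "directions must be +1 or -1")
  if (length(object@universe) && !all(object@members %in% object@universe))
    msg <- c(msg, "members must be a subset of the attached universe")
  if (length(msg)) msg else TRUE
})

#' Background analyte universe
#'
#' The set of analytes that could in principle have been called differential;
#' the reference population for all enrichment nulls. Cross-modal universes
#' record the sizes of the gene and protein source sets and how many ids on
#' each side could not be mapped.
#'
#' @slot ids character vector of analyte ids.
#' @slot provenance \code{"single-modality"} or \code{"cross-modal"}.
#' @slot nGenes,nProteins integer(1) source-set sizes (cross-modal only; NA
#'   otherwise).
#' @slot nUnmappedGenes,nUnmappedProteins integer(1) ids without a usable
#'   mapping partner.
#' @exportClass AnalyteUniverse
setClass("AnalyteUniverse",
         representation(ids = "character",
                        provenance = "character",
                        nGenes = "integer",
                        nProteins = "integer",
                        nUnmappedGenes = "integer",
                        nUnmappedProteins = "integer"),
         prototype(provenance = "single-modality", nGenes = NA_integer_,
                   nProteins = NA_integer_, nUnmappedGenes = NA_integer_,
                   nUnmappedProteins = NA_integer_))

setValidity("AnalyteUniverse", function(object) {
  msg <- character()
  if (length(object@ids) == 0L)
    msg <- c(msg, "universe must be nonempty")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "universe ids must be unique")
  if (!object@provenance %in% c("single-modality", "cross-modal"))
    msg <- c(msg, "provenance must be 'single-modality' or 'cross-modal'")
  if (length(msg)) msg else TRUE
})

#' Gene-protein identifier mapping
#'
#' @slot gene,protein character vectors of equal length; row i is the pair
#'   (gene[i], protein[i]).
#' @slot collapsePolicy how many-to-many mappings are collapsed when a
#'   protein table is translated to gene space: \code{"best_p"} (smallest
#'   p-value wins), \code{"first"} (first listed pair), or \code{"mean_lfc"}
#'   (mean log2fc, smallest p).
#' @exportClass CrossModalMap
setClass("CrossModalMap",
         representation(gene = "character",
                        protein = "character",
                        collapsePolicy = "character"),
         prototype(collapsePolicy = "best_p"))

setValidity("CrossModalMap", function(object) {
  msg <- character()
  if (length(object@gene) != length(object@protein))
    msg <- c(msg, "gene and protein vectors must have equal length")
  if (anyDuplicated(paste(object@gene, object@protein, sep = "\r")))
    msg <- c(msg, "duplicate gene-protein pairs")
  if (!object@collapsePolicy %in% c("best_p", "first", "mean_lfc"))
    msg <- c(msg, "collapsePolicy must be 'best_p', 'first' or 'mean_lfc'")
  if (length(msg)) msg else TRUE
})

#' 2x2 overlap contingency table
#'
#' Cell a = in both signatures, b = in A only, c = in B only, d = in neither;
#' N = a+b+c+d is the universe size.
#'
#' @slot a,b,c,d integer(1) nonnegative counts.
#' @exportClass ContingencyTable
setClass("ContingencyTable",
         representation(a = "integer", b = "integer",
                        c = "integer", d = "integer"))

setValidity("ContingencyTable", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0L))
    return("all four cells must be nonnegative integers")
  TRUE
})

#' Overlap-enrichment result
#'
#' @slot contingency the \linkS4class{ContingencyTable}.
#' @slot expectedOverlap (a+b)(a+c)/N under the hypergeometric null.
#' @slot pHyper exact hypergeometric upper-tail p-value.
#' @slot pPerm permutation p-value (NA when not computed).
#' @slot oddsRatio,jaccard association summaries of the 2x2 table.
#' @slot nPerm,seed permutation settings (NA when not computed).
#' @exportClass OverlapResult
setClass("OverlapResult",
         representation(contingency = "ContingencyTable",
                        expectedOverlap = "numeric",
                        pHyper = "numeric",
                        pPerm = "numeric",
                        oddsRatio = "numeric",
                        jaccard = "numeric",
                        nPerm = "integer",
                        seed = "integer"),
         prototype(pPerm = NA_real_, nPerm = NA_integer_, seed = NA_integer_))

#' Directional-concordance result
#'
#' @slot nOverlap number of analytes in both signatures.
#' @slot kAgree number of those whose fold-change signs agree.
#' @slot p0 null agreement probability from background up/down proportions.
#' @slot pBinom exact binomial upper-tail p-value P(X >= kAgree).
#' @slot pPerm optional permutation p-value (NA when not computed).
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
         representation(nOverlap = "integer",
                        kAgree = "integer",
                        p0 = "numeric",
                        pBinom = "numeric",
                        pPerm = "numeric"),
         prototype(pPerm = NA_real_))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (object@kAgree < 0L || object@kAgree > object@nOverlap)
    msg <- c(msg, "kAgree must lie in [0, nOverlap]")
  if (is.na(object@p0) || object@p0 < 0 || object@p0 > 1)
    msg <- c(msg, "p0 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Spearman correlation result
#'
#' @slot rho rank correlation (NA when undefined, e.g. constant input).
#' @slot p two-sided p-value.
#' @slot n number of pairs.
#' @slot method \code{"t-approximation"}, \code{"exact-enumeration"} or
#'   \code{"undefined"} (constant input).
#' @exportClass CorrelationResult
setClass("CorrelationResult",
         representation(rho = "numeric", p = "numeric",
                        n = "integer", method = "character"))

#' Cross-condition correlation matrix
#'
#' Pairwise Spearman correlation of signed log2 fold changes over analytes
#' passing the selection thresholds in any condition, restricted pairwise to
#' shared analytes.
#'
#' @slot labels condition labels (row/column order).
#' @slot rho symmetric correlation matrix (diagonal 1).
#' @slot p matrix of two-sided p-values.
#' @slot nShared matrix of pairwise analyte counts.
#' @slot nSelected number of analytes in the selection union.
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
         representation(labels = "character",
                        rho = "matrix",
                        p = "matrix",
                        nShared = "matrix",
                        nSelected = "integer"))

#' Temporal concordance profile
#'
#' Per-CSF-timepoint overlap, enrichment, directional agreement and rank
#' correlation of a fixed transcriptomic signature against serial proteomic
#' differential tables, with BH correction of the correlation p-values
#' across the series.
#'
#' @slot profile data.frame with one row per timepoint (see
#'   \code{\link{temporalConcordance}} for columns).
#' @slot universeSize size of the cross-modal background.
#' @slot nPerm,seed permutation settings.
#' @exportClass TemporalProfile
setClass("TemporalProfile",
         representation(profile = "data.frame",
                        universeSize = "integer",
                        nPerm = "integer",
                        seed = "integer"))

#' MAD filter rule
#'
#' @slot metric column of the QC table the rule applies to.
#' @slot nMads number of (scaled) MADs defining the outlier threshold.
#' @slot sides \code{"upper"}, \code{"lower"} or \code{"both"}.
#' @slot scaleConstant MAD scale factor (1.4826 for normal consistency).
#' @exportClass MADFilterSpec
setClass("MADFilterSpec",
         representation(metric = "character",
                        nMads = "numeric",
                        sides = "character",
                        scaleConstant = "numeric"),
         prototype(nMads = 3, sides = "both", scaleConstant = 1.4826))

setValidity("MADFilterSpec", function(object) {
  msg <- character()
  if (object@nMads <= 0) msg <- c(msg, "nMads must be positive")
  if (!object@sides %in% c("upper", "lower", "both"))
    msg <- c(msg, "sides must be 'upper', 'lower' or 'both'")
  if (object@scaleConstant <= 0)
    msg <- c(msg, "scaleConstant must be positive")
  if (length(msg)) msg else TRUE
})

#' QC filter report
#'
#' @slot kept cell ids passing every rule.
#' @slot removed named list: cell id -> character vector of failed rules.
#' @slot thresholds data.frame of per-rule thresholds actually applied.
#' @exportClass FilterReport
setClass("FilterReport",
         representation(kept = "character",
                        removed = "list",
                        thresholds = "data.frame"))

#' Synthetic-data specification
#'
#' Parameters of the synthetic differential-statistics generator. Defaults
#' emulate the structure of the study the package is designed around: ~20k
#' genes assayed in 4 agents x 2 timepoints, a 1461-protein CSF panel with
#' 1235 analytes mappable to the tested gene universe, strong positive
#' log2FC correlation between agents within a timepoint and negative
#' correlation across timepoints, and a cross-modal signal peaking at one of
#' six serial CSF timepoints.
#'
#' @slot nGenes,nProteins,nMappable universe sizes.
#' @slot agents,timepointsHours condition grid for the bulk tables.
#' @slot signalFraction fraction of genes with true effects.
#' @slot effectSd scale of true log2 fold changes (signal genes).
#' @slot noiseSd measurement noise scale of observed log2 fold changes.
#' @slot withinTimeCorr,acrossTimeCorr target realized Spearman correlation
#'   of observed log2fc between conditions at the same / at different
#'   timepoints.
#' @slot nGeneSig,nProteinSig planted signature sizes for the cross-modal
#'   generator (neuronal gene side, CSF protein side).
#' @slot crossmodalEnrichment multiplier on the expected overlap at the peak
#'   timepoint; 1 means no planted association (null).
#' @slot concordancePeakTimepoint index of the CSF timepoint where the
#'   planted cross-modal signal peaks.
#' @slot csfHours serial CSF draw times (strictly increasing).
#' @slot upProportion background probability that an analyte's log2fc is
#'   positive on either side (drives the directional-concordance null).
#' @slot peakCoupling coupling of |log2fc| magnitudes between gene and
#'   protein over overlapping analytes at the peak timepoint.
#' @slot agreementAtPeak probability that an overlapping analyte's
#'   fold-change direction agrees between modalities at the peak timepoint
#'   (ramps from the background null off-peak).
#' @slot genePCutoff gene-side calling cutoff the planted signature is built
#'   against (uncorrected).
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(nGenes = "integer",
                        nProteins = "integer",
                        nMappable = "integer",
                        agents = "character",
                        timepointsHours = "numeric",
                        signalFraction = "numeric",
                        effectSd = "numeric",
                        noiseSd = "numeric",
                        withinTimeCorr = "numeric",
                        acrossTimeCorr = "numeric",
                        nGeneSig = "integer",
                        nProteinSig = "integer",
                        crossmodalEnrichment = "numeric",
                        concordancePeakTimepoint = "integer",
                        csfHours = "numeric",
                        upProportion = "numeric",
                        peakCoupling = "numeric",
                        agreementAtPeak = "numeric",
                        genePCutoff = "numeric"),
         prototype(nGenes = 20000L, nProteins = 1461L, nMappable = 1235L,
                   agents = c("HNK", "psilocybin", "LSD", "DOI"),
                   timepointsHours = c(6, 24),
                   signalFraction = 0.05, effectSd = 2, noiseSd = 0.5,
                   withinTimeCorr = 0.8, acrossTimeCorr = -0.3,
                   nGeneSig = 72L, nProteinSig = 364L,
                   crossmodalEnrichment = 2,
                   concordancePeakTimepoint = 5L,
                   csfHours = c(1, 2, 4, 8, 12, 24),
                   upProportion = 0.6, peakCoupling = 0.95,
                   agreementAtPeak = 25 / 28,
                   genePCutoff = 0.05))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nMappable > min(object@nGenes, object@nProteins))
    msg <- c(msg, "nMappable must be <= min(nGenes, nProteins)")
  if (object@signalFraction < 0 || object@signalFraction > 1)
    msg <- c(msg, "signalFraction must lie in [0, 1]")
  for (s in c("withinTimeCorr", "acrossTimeCorr", "peakCoupling"))
    if (abs(slot(object, s)) > 1)
      msg <- c(msg, paste(s, "must lie in [-1, 1]"))
  if (is.unsorted(object@csfHours, strictly = TRUE))
    msg <- c(msg, "csfHours must be strictly increasing")
  if (object@concordancePeakTimepoint < 1L ||
      object@concordancePeakTimepoint > length(object@csfHours))
    msg <- c(msg, "concordancePeakTimepoint out of range")
  if (object@upProportion <= 0 || object@upProportion >= 1)
    msg <- c(msg, "upProportion must lie in (0, 1)")
  if (object@agreementAtPeak < 0 || object@agreementAtPeak > 1)
    msg <- c(msg, "agreementAtPeak must lie in [0, 1]")
  if (object@nGeneSig > object@nMappable || object@nProteinSig > object@nMappable)
    msg <- c(msg, "planted signature sizes must not exceed nMappable")
  if (object@genePCutoff <= 0 || object@genePCutoff >= 1)
    msg <- c(msg, "genePCutoff must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
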