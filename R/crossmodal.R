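## Cross-modal module: gene-protein universe construction and temporal
## concordance profiling.

#' Construct a gene-protein identifier mapping
#'
#' @param gene,protein equal-length character vectors; row i is the pair
#'   (gene[i], protein[i]). Duplicate pairs are an error; many-to-many
#'   relations are allowed and collapsed per policy at table translation.
#' @param collapsePolicy \code{"best_p"} (default), \code{"first"} or
#'   \code{"mean_lfc"}.
#' @return a \linkS4class{CrossModalMap}.
#' @export
crossModalMap <- function(gene, protein, collapsePolicy = "best_p") {
  new("CrossModalMap", gene = as.character(gene),
      protein = as.character(protein), collapsePolicy = collapsePolicy)
}

setMethod("show", "CrossModalMap", function(object) {
  cat(sprintf("CrossModalMap: %d pairs (%d genes, %d proteins), collapse = %s\n",
              length(object@gene), length(unique(object@gene)),
              length(unique(object@protein)), object@collapsePolicy))
})

#' Read a two-column gene-protein mapping TSV
#'
#' @param path TSV with columns \code{gene_id} and \code{protein_id} (or two
#'   unnamed columns in that order).
#' @param collapsePolicy see \code{\link{crossModalMap}}.
#' @return a \linkS4class{CrossModalMap}.
#' @export
readCrossModalMap <- function(path, collapsePolicy = "best_p") {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("gene_id", "protein_id") %in% names(tab))) {
    if (ncol(tab) < 2L) stop("mapping file needs two columns")
    names(tab)[1:2] <- c("gene_id", "protein_id")
  }
  crossModalMap(tab$gene_id, tab$protein_id, collapsePolicy)
}

#' Write a mapping as two-column TSV
#' @param x a \linkS4class{CrossModalMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCrossModalMap <- function(x, path) {
  write.table(data.frame(gene_id = x@gene, protein_id = x@protein),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a cross-modal background universe
#'
#' The universe contains every tested gene that maps to at least one protein
#' actually present on the protein panel. Genes mapping to several proteins
#' contribute one universe entry (the collapse happens at table
#' translation). Unmapped counts on both sides are recorded in the result.
#'
#' @param geneIds genes tested for differential expression.
#' @param proteinIds proteins assessable on the panel.
#' @param map a \linkS4class{CrossModalMap}.
#' @return an \linkS4class{AnalyteUniverse} with cross-modal provenance.
#' @examples
#' m <- crossModalMap(c("g1", "g2"), c("p1", "p2"))
#' universeIds(buildUniverse(c("g1", "g2", "g3"), c("p1", "p2"), m))
#' @export
buildUniverse <- function(geneIds, proteinIds, map) {
  stopifnot(is(map, "CrossModalMap"))
  geneIds <- unique(as.character(geneIds))
  proteinIds <- unique(as.character(proteinIds))
  usable <- map@protein %in% proteinIds & map@gene %in% geneIds
  ids <- unique(map@gene[usable])
  if (!length(ids)) stop("empty cross-modal universe")
  mappedGenes <- unique(map@gene[map@protein %in% proteinIds])
  mappedProts <- unique(map@protein[map@gene %in% geneIds])
  new("AnalyteUniverse", ids = ids, provenance = "cross-modal",
      nGenes = length(geneIds), nProteins = length(proteinIds),
      nUnmappedGenes = length(setdiff(geneIds, mappedGenes)),
      nUnmappedProteins = length(setdiff(proteinIds, mappedProts)))
}

#' Construct a single-modality universe
#'
#' @param ids analyte ids.
#' @return an \linkS4class{AnalyteUniverse}.
#' @export
analyteUniverse <- function(ids) {
  new("AnalyteUniverse", ids = unique(as.character(ids)),
      provenance = "single-modality")
}

#' @rdname AnalyteUniverse-class
#' @param x,object an \linkS4class{AnalyteUniverse}.
#' @export
setMethod("universeIds", "AnalyteUniverse", function(x) x@ids)

#' @rdname AnalyteUniverse-class
#' @export
setMethod("length", "AnalyteUniverse", function(x) length(x@ids))

setMethod("show", "AnalyteUniverse", function(object) {
  cat(sprintf("AnalyteUniverse: %d analytes (%s)\n", length(object@ids),
              object@provenance))
  if (object@provenance == "cross-modal")
    cat(sprintf("  sources: %d genes, %d proteins; unmapped: %d genes, %d proteins\n",
                object@nGenes, object@nProteins, object@nUnmappedGenes,
                object@nUnmappedProteins))
})

#' Translate a protein differential table to gene identifier space
#'
#' For each gene with at least one mapped protein present in the table, one
#' record is produced according to the map's collapse policy: the protein
#' with the smallest p-value (\code{"best_p"}), the first listed pair
#' (\code{"first"}), or the mean log2fc with the smallest p
#' (\code{"mean_lfc"}).
#'
#' @param table a protein-modality \linkS4class{DifferentialTable}.
#' @param map a \linkS4class{CrossModalMap}.
#' @return a gene-keyed \linkS4class{DifferentialTable} (modality still
#'   \code{"protein"}; only the identifier space changes).
#' @export
mapProteinTable <- function(table, map) {
  stopifnot(is(table, "DifferentialTable"), is(map, "CrossModalMap"))
  st <- table@stats
  idx <- match(map@protein, st$analyte_id)
  present <- !is.na(idx)
  if (!any(present)) stop("no mapped proteins present in the table")
  pairs <- data.frame(gene = map@gene[present], row = idx[present],
                      order = which(present), stringsAsFactors = FALSE)
  pick <- switch(map@collapsePolicy,
    first = {
      pairs <- pairs[order(pairs$order), ]
      pairs[!duplicated(pairs$gene), ]
    },
    best_p = {
      pv <- st$p_value[pairs$row]
      pairs <- pairs[order(pairs$gene, pv, pairs$order), ]
      pairs[!duplicated(pairs$gene), ]
    },
    mean_lfc = {
      pv <- st$p_value[pairs$row]
      pairs <- pairs[order(pairs$gene, pv, pairs$order), ]
      pairs[!duplicated(pairs$gene), ]
    })
  out <- st[pick$row, , drop = FALSE]
  out$analyte_id <- pick$gene
  if (map@collapsePolicy == "mean_lfc") {
    ml <- tapply(st$log2fc[pairs$row], pairs$gene, mean, na.rm = TRUE)
    out$log2fc <- as.numeric(ml[out$analyte_id])
  }
  rownames(out) <- NULL
  differentialTable(out$analyte_id, out$log2fc, out$p_value, out$adj_p,
                    agent = table@agent, timepointHours = table@timepointHours,
                    modality = table@modality)
}

## restrict a table's records to a universe
.restrictTable <- function(table, uni) {
  st <- table@stats[table@stats$analyte_id %in% uni, , drop = FALSE]
  rownames(st) <- NULL
  differentialTable(st$analyte_id, st$log2fc, st$p_value, st$adj_p,
                    agent = table@agent, timepointHours = table@timepointHours,
                    modality = table@modality)
}

#' Temporal cross-modal concordance profile
#'
#' Compares one fixed transcriptomic signature against serial proteomic
#' differential tables over a shared cross-modal universe. Per timepoint the
#' protein table is translated to gene space, both signatures are called
#' with their (deliberately asymmetric) thresholds -- uncorrected p on the
#' gene side, FDR-adjusted on the protein side -- and overlap counts, a
#' permutation enrichment p, directional concordance against the
#' background-derived null, and the Spearman correlation of log2 fold
#' changes over the overlapping analytes are computed. Correlation p-values
#' are BH-corrected across the series.
#'
#' @param neuronal gene-modality \linkS4class{DifferentialTable}.
#' @param csfSeries list of protein-modality tables with strictly increasing
#'   \code{timepointHours}.
#' @param map a \linkS4class{CrossModalMap}.
#' @param geneThresholds thresholds for the gene side (default uncorrected
#'   p < 0.05, no fold-change cutoff).
#' @param proteinThresholds thresholds for the protein side (default
#'   FDR-adjusted p < 0.05).
#' @param universe optional \linkS4class{AnalyteUniverse}; built from the
#'   inputs when NULL.
#' @param nPerm,seed permutation settings.
#' @param restrictToUniverse if TRUE (default) signatures are re-called
#'   within the universe (including re-computation of the protein-side BH
#'   adjustment on the restricted table); if FALSE they are called globally
#'   and then intersected with the universe.
#' @return a \linkS4class{TemporalProfile} whose \code{profile} data.frame
#'   has columns \code{hours}, \code{nGeneSig}, \code{nProteinSig},
#'   \code{overlap}, \code{expected}, \code{overlapP}, \code{kAgree},
#'   \code{p0}, \code{pBinom}, \code{rho}, \code{p}, \code{q}. Timepoints
#'   with fewer than 3 overlapping analytes get NA correlations and are
#'   skipped by the BH correction.
#' @export
temporalConcordance <- function(neuronal, csfSeries, map,
                                geneThresholds = signatureThresholds(0.05, 0),
                                proteinThresholds = signatureThresholds(0.05, 0, useAdjusted = TRUE),
                                universe = NULL,
                                nPerm = 10000L, seed = NULL,
                                restrictToUniverse = TRUE) {
  stopifnot(is(neuronal, "DifferentialTable"), is(map, "CrossModalMap"))
  hours <- vapply(csfSeries, function(tb) tb@timepointHours, 0)
  if (is.unsorted(hours, strictly = TRUE))
    stop("csfSeries timepoints must be strictly increasing")
  mapped <- lapply(csfSeries, mapProteinTable, map = map)
  if (is.null(universe)) {
    protIds <- unique(unlist(lapply(csfSeries, analyteIds)))
    universe <- buildUniverse(analyteIds(neuronal), protIds, map)
  }
  uni <- universeIds(universe)
  run <- function(code) if (is.null(seed)) code() else .withSeed(seed, code)
  geneTabU <- .restrictTable(neuronal, uni)
  rows <- run(function() {
    lapply(seq_along(mapped), function(t) {
      protTabU <- .restrictTable(mapped[[t]], uni)
      if (restrictToUniverse) {
        gTab <- geneTabU
        pTab <- protTabU
        if (proteinThresholds@useAdjusted)
          pTab@stats$adj_p <- bhFDR(pTab@stats$p_value)
        sigG <- callSignature(gTab, geneThresholds, universe = uni)
        sigP <- callSignature(pTab, proteinThresholds, universe = uni)
      } else {
        sigG <- callSignature(neuronal, geneThresholds)
        sigP <- callSignature(mapped[[t]], proteinThresholds)
        sigG <- signatureSet(intersect(sigG@members, uni),
                             sigG@directions[intersect(sigG@members, uni)],
                             sigG@condition, uni)
        sigP <- signatureSet(intersect(sigP@members, uni),
                             sigP@directions[intersect(sigP@members, uni)],
                             sigP@condition, uni)
      }
      ct <- overlapCounts(sigG, sigP, uni)
      pPerm <- permutationOverlapP(sigG, sigP, uni, nPerm = nPerm)
      p0 <- backgroundAgreementProb(geneTabU, protTabU, uni)
      conc <- directionalConcordance(sigG, sigP, p0)
      common <- intersect(sigG@members, sigP@members)
      rho <- NA_real_; rp <- NA_real_
      if (length(common) >= 3L) {
        glfc <- log2FoldChange(geneTabU)[common]
        plfc <- log2FoldChange(protTabU)[common]
        ok <- !is.na(glfc) & !is.na(plfc)
        if (sum(ok) >= 3L) {
          res <- tryCatch(spearmanRhoP(glfc[ok], plfc[ok]),
                          warning = function(w) NULL)
          if (!is.null(res)) { rho <- res@rho; rp <- res@p }
        }
      }
      data.frame(hours = hours[t],
                 nGeneSig = length(sigG), nProteinSig = length(sigP),
                 overlap = ct@a,
                 expected = (ct@a + ct@b) * (ct@a + ct@c) / universeSize(ct),
                 overlapP = pPerm,
                 kAgree = conc@kAgree, p0 = as.numeric(p0),
                 pBinom = conc@pBinom, rho = rho, p = rp)
    })
  })
  prof <- do.call(rbind, rows)
  prof$q <- NA_real_
  defined <- !is.na(prof$p)
  if (any(defined)) prof$q[defined] <- bhFDR(prof$p[defined])
  new("TemporalProfile", profile = prof,
      universeSize = length(uni), nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname TemporalProfile-class
#' @param x,object a \linkS4class{TemporalProfile}.
#' @export
profileTable <- function(x) x@profile

setMethod("show", "TemporalProfile", function(object) {
  cat(sprintf("TemporalProfile over %d timepoints (universe %d, nPerm %d)\n",
              nrow(object@profile), object@universeSize, object@nPerm))
  print(within(object@profile, {
    overlapP <- signif(overlapP, 3); pBinom <- signif(pBinom, 3)
    rho <- round(rho, 3); p <- signif(p, 3); q <- signif(q, 3)
    expected <- round(expected, 1); p0 <- round(p0, 3)
  }), row.names = FALSE)
})

#' Write a temporal profile (TSV + JSON)
#'
#' @param x a \linkS4class{TemporalProfile}.
#' @param path output TSV path; a JSON twin is written to
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeTemporalProfile <- function(x, path) {
  write.table(x@profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(universe_size = x@universeSize, n_perm = x@nPerm,
                            seed = x@seed, profile = x@profile),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot a temporal concordance profile
#'
#' Overlap counts (bars would overstate precision; points and lines are
#' used) and Spearman rho per CSF timepoint, with an optional
#' pharmacokinetic concentration overlay for annotation. The PK curve is
#' purely decorative: no statistic is computed against it.
#'
#' @param x a \linkS4class{TemporalProfile}.
#' @param pk optional data.frame with columns \code{hours} and
#'   \code{concentration} (scaled), e.g. CSF drug/metabolite levels.
#' @param ... passed to \code{plot}.
#' @return invisibly, the profile data.frame.
#' @export
plotTemporalProfile <- function(x, pk = NULL, ...) {
  prof <- x@profile
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  plot(prof$hours, prof$overlap, type = "b", pch = 19,
       xlab = "CSF timepoint (h)", ylab = "overlapping analytes", ...)
  lines(prof$hours, prof$expected, lty = 2)
  scale <- max(prof$overlap, na.rm = TRUE)
  if (any(!is.na(prof$rho))) {
    points(prof$hours, prof$rho * scale, type = "b", pch = 1, col = "blue")
    axis(4, at = pretty(c(-1, 1)) * scale, labels = pretty(c(-1, 1)),
         col.axis = "blue")
  }
  if (!is.null(pk))
    lines(pk$hours, pk$concentration / max(pk$concentration) * scale,
          col = "red", lty = 3)
  legend("topleft", bty = "n", lty = c(1, 2, 1), pch = c(19, NA, 1),
         col = c("black", "black", "blue"),
         legend = c("overlap", "expected", "rho (right axis)"))
  invisible(prof)
}
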