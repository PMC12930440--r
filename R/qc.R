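## QC module: MAD-based outlier filtering of per-cell metrics.

#' MAD filter rule
#'
#' @param metric column name the rule applies to (e.g. \code{"pct_mito"}).
#' @param nMads threshold in scaled-MAD units (> 0).
#' @param sides \code{"upper"}, \code{"lower"} or \code{"both"}.
#' @param scaleConstant MAD scale factor; 1.4826 (default) makes the MAD a
#'   consistent estimator of the standard deviation under normality, 1 gives
#'   the raw MAD.
#' @return a \linkS4class{MADFilterSpec}.
#' @export
madFilterSpec <- function(metric, nMads = 3, sides = c("both", "upper", "lower"),
                          scaleConstant = 1.4826) {
  sides <- match.arg(sides)
  new("MADFilterSpec", metric = metric, nMads = as.numeric(nMads),
      sides = sides, scaleConstant = as.numeric(scaleConstant))
}

#' Default single-cell QC rules
#'
#' Mitochondrial percentage: upper-only at 3 MADs (high-mito cells are
#' damaged; low values are good). Gene and UMI counts: both sides at 3 MADs.
#'
#' @return list of \linkS4class{MADFilterSpec}s.
#' @export
defaultQCSpecs <- function() {
  list(madFilterSpec("pct_mito", 3, "upper"),
       madFilterSpec("n_genes", 3, "both"),
       madFilterSpec("n_umi", 3, "both"))
}

#' MAD-based outlier filtering of per-cell QC metrics
#'
#' For each rule, the median and MAD of the metric are computed once over
#' all input cells, and a cell fails the rule when its value lies strictly
#' beyond median +/- nMads * (scaleConstant * MAD) on the rule's side(s).
#' All rules are applied simultaneously on the original statistics (no
#' iterative re-computation after removals), so the result is invariant
#' under row permutation and removing an unflagged cell cannot change other
#' cells' fates. A metric with MAD = 0 makes the rule a no-op, flagged as
#' degenerate in the threshold table.
#'
#' @param table data.frame with a \code{cell_id} column plus the metric
#'   columns named by the rules (defaults: \code{n_genes}, \code{n_umi},
#'   \code{pct_mito}).
#' @param specs list of \linkS4class{MADFilterSpec}s
#'   (default \code{\link{defaultQCSpecs}()}).
#' @return a \linkS4class{FilterReport}.
#' @examples
#' tab <- data.frame(cell_id = paste0("c", 1:6),
#'                   pct_mito = c(5, 6, 7, 8, 9, 50))
#' madOutlierFilter(tab, list(madFilterSpec("pct_mito", 3, "upper")))
#' @export
madOutlierFilter <- function(table, specs = defaultQCSpecs()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("table must be a nonempty data.frame")
  if (!"cell_id" %in% names(table)) stop("table needs a 'cell_id' column")
  if (anyDuplicated(table$cell_id)) stop("cell_id must be unique")
  failures <- setNames(vector("list", nrow(table)), table$cell_id)
  thr <- data.frame()
  for (spec in specs) {
    stopifnot(is(spec, "MADFilterSpec"))
    if (!spec@metric %in% names(table))
      stop("metric not in table: ", spec@metric)
    x <- table[[spec@metric]]
    m <- median(x)
    s <- mad(x, constant = spec@scaleConstant)
    degenerate <- s == 0
    lo <- if (spec@sides %in% c("lower", "both")) m - spec@nMads * s else -Inf
    hi <- if (spec@sides %in% c("upper", "both")) m + spec@nMads * s else Inf
    label <- sprintf("%s_%s", spec@metric, spec@sides)
    if (degenerate) {
      message("MAD = 0 for metric '", spec@metric,
              "': rule is a no-op (degenerate)")
    } else {
      bad <- which(x < lo | x > hi)
      for (i in bad) failures[[i]] <- c(failures[[i]], label)
    }
    thr <- rbind(thr, data.frame(rule = label, metric = spec@metric,
                                 median = m, scaled_mad = s,
                                 lower = lo, upper = hi,
                                 degenerate = degenerate))
  }
  failed <- !vapply(failures, is.null, TRUE)
  new("FilterReport", kept = table$cell_id[!failed],
      removed = failures[failed], thresholds = thr)
}

setMethod("show", "FilterReport", function(object) {
  n <- length(object@kept) + length(object@removed)
  cat(sprintf("FilterReport: kept %d / %d cells (%.1f%% removed)\n",
              length(object@kept), n, 100 * length(object@removed) / n))
  print(object@thresholds, row.names = FALSE)
})

#' Read a per-cell QC metrics TSV
#'
#' @param path TSV with header: \code{cell_id}, \code{n_genes},
#'   \code{n_umi}, \code{pct_mito}.
#' @return validated data.frame.
#' @export
readQCMetrics <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("cell_id", "n_genes", "n_umi", "pct_mito")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing QC columns: ", paste(miss, collapse = ", "))
  if (any(tab$pct_mito < 0 | tab$pct_mito > 100))
    stop("pct_mito must lie in [0, 100]")
  tab
}

#' Write a filter report (kept list TSV + JSON)
#'
#' @param x a \linkS4class{FilterReport}.
#' @param path output TSV path for the kept-cell list; thresholds and
#'   removal reasons go to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(x, path) {
  write.table(data.frame(cell_id = x@kept), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(thresholds = x@thresholds,
                            removed = x@removed,
                            n_kept = length(x@kept),
                            n_removed = length(x@removed)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
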