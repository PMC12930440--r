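## Signature module: reading/writing differential tables, expression
## filtering, signature calling.

#' Construct a DifferentialTable
#'
#' @param analyte_id character vector of unique analyte identifiers.
#' @param log2fc signed log2 fold changes (NA allowed).
#' @param p_value p-values in (0, 1] (NA allowed).
#' @param adj_p optional adjusted p-values in (0, 1]; these are taken as
#'   supplied (typically from an external multiple-testing procedure or
#'   \code{\link{bhFDR}}) and are not assumed to dominate \code{p_value}.
#' @param agent,timepointHours,modality condition label components.
#' @return a \linkS4class{DifferentialTable}.
#' @examples
#' differentialTable(c("GRN", "NECTIN2"), c(1.2, -0.4), c(0.001, 0.2),
#'                   agent = "HNK", timepointHours = 24)
#' @export
differentialTable <- function(analyte_id, log2fc, p_value, adj_p = NULL,
                              agent = "unspecified", timepointHours = NA_real_,
                              modality = "gene") {
  if (is.null(adj_p)) adj_p <- rep(NA_real_, length(analyte_id))
  st <- data.frame(analyte_id = as.character(analyte_id),
                   log2fc = as.numeric(log2fc),
                   p_value = as.numeric(p_value),
                   adj_p = as.numeric(adj_p),
                   stringsAsFactors = FALSE)
  new("DifferentialTable", agent = agent,
      timepointHours = as.numeric(timepointHours),
      modality = modality, stats = st)
}

#' @rdname DifferentialTable-class
#' @export
setMethod("analyteIds", "DifferentialTable", function(x) x@stats$analyte_id)

#' @rdname DifferentialTable-class
#' @export
setMethod("log2FoldChange", "DifferentialTable",
          function(x) setNames(x@stats$log2fc, x@stats$analyte_id))

#' @rdname DifferentialTable-class
#' @export
setMethod("pValues", "DifferentialTable",
          function(x) setNames(x@stats$p_value, x@stats$analyte_id))

#' @rdname DifferentialTable-class
#' @export
setMethod("adjPValues", "DifferentialTable",
          function(x) setNames(x@stats$adj_p, x@stats$analyte_id))

#' @rdname DifferentialTable-class
#' @export
setMethod("conditionLabel", "DifferentialTable", function(x) {
  tp <- if (is.na(x@timepointHours)) "NA" else
    format(x@timepointHours, trim = TRUE)
  sprintf("%s_%sh_%s", x@agent, tp, x@modality)
})

#' @rdname DifferentialTable-class
#' @export
setMethod("length", "DifferentialTable", function(x) nrow(x@stats))

#' @rdname DifferentialTable-class
#' @param row.names,optional,... passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "DifferentialTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@stats)

setMethod("show", "DifferentialTable", function(object) {
  cat("DifferentialTable:", conditionLabel(object), "\n")
  cat("  ", nrow(object@stats), "analytes;",
      sum(!is.na(object@stats$adj_p)), "with adjusted p\n")
})

#' Read a differential-statistics table from delimited text
#'
#' Reads a TSV/CSV with a header and maps its columns onto the
#' \linkS4class{DifferentialTable} contract. Rows whose fold-change or
#' p-value fields cannot be parsed as numbers are dropped with a warning
#' reporting their row indices.
#'
#' @param path file path; comma-separated if the extension is \code{.csv},
#'   tab-separated otherwise.
#' @param columns named list mapping the required fields to column names;
#'   defaults \code{list(analyte = "analyte", log2fc = "log2fc",
#'   p = "pvalue", padj = "padj")}. \code{padj} is optional in the file.
#' @param agent,timepointHours,modality condition label components.
#' @param normalizeCase if TRUE analyte ids are uppercased (identifier
#'   matching elsewhere in the package is otherwise exact and
#'   case-sensitive).
#' @return a \linkS4class{DifferentialTable}.
#' @export
readDifferentialTable <- function(path,
                                  columns = list(analyte = "analyte",
                                                 log2fc = "log2fc",
                                                 p = "pvalue",
                                                 padj = "padj"),
                                  agent = "unspecified",
                                  timepointHours = NA_real_,
                                  modality = "gene",
                                  normalizeCase = FALSE) {
  defaults <- list(analyte = "analyte", log2fc = "log2fc",
                   p = "pvalue", padj = "padj")
  columns <- modifyList(defaults, as.list(columns))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  for (field in c("analyte", "log2fc", "p")) {
    if (!columns[[field]] %in% names(raw))
      stop(sprintf("missing required column '%s' in %s",
                   columns[[field]], path))
  }
  ids <- raw[[columns$analyte]]
  if (normalizeCase) ids <- toupper(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate analyte_id in ", path, ": ",
         paste(head(dup, 10), collapse = ", "))
  parseNum <- function(x) suppressWarnings(as.numeric(x))
  lfc <- parseNum(raw[[columns$log2fc]])
  pv <- parseNum(raw[[columns$p]])
  bad <- which((is.na(lfc) & nzchar(trimws(raw[[columns$log2fc]]))) |
                 (is.na(pv) & nzchar(trimws(raw[[columns$p]]))))
  padj <- if (columns$padj %in% names(raw))
    parseNum(raw[[columns$padj]]) else rep(NA_real_, nrow(raw))
  if (length(bad)) {
    warning(sprintf("dropping %d row(s) with unparseable numerics: rows %s",
                    length(bad), paste(head(bad, 20), collapse = ", ")))
    keep <- setdiff(seq_len(nrow(raw)), bad)
    ids <- ids[keep]; lfc <- lfc[keep]; pv <- pv[keep]; padj <- padj[keep]
  }
  differentialTable(ids, lfc, pv, padj, agent = agent,
                    timepointHours = timepointHours, modality = modality)
}

#' Write a differential table as TSV
#'
#' Numbers are written with 17 significant digits so that a write/read
#' round trip reproduces finite values bit-comparably.
#'
#' @param x a \linkS4class{DifferentialTable}.
#' @param path output file path.
#' @param columns column names to use, as in
#'   \code{\link{readDifferentialTable}}.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialTable <- function(x, path,
                                   columns = list(analyte = "analyte",
                                                  log2fc = "log2fc",
                                                  p = "pvalue",
                                                  padj = "padj")) {
  defaults <- list(analyte = "analyte", log2fc = "log2fc",
                   p = "pvalue", padj = "padj")
  columns <- modifyList(defaults, as.list(columns))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(x@stats$analyte_id, fmt(x@stats$log2fc),
                    fmt(x@stats$p_value), fmt(x@stats$adj_p),
                    stringsAsFactors = FALSE)
  names(out) <- unlist(columns[c("analyte", "log2fc", "p", "padj")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Low-expression filter on a CPM matrix
#'
#' Keeps analytes observed strictly above \code{cpmMin} counts-per-million
#' in at least \code{minSamples} samples. The result does not depend on the
#' column order of the matrix.
#'
#' @param cpm numeric matrix of nonnegative CPM values with analyte row
#'   names (a \code{SummarizedExperiment} is accepted; its first assay is
#'   used).
#' @param cpmMin expression threshold (strict).
#' @param minSamples minimum number of samples exceeding it.
#' @return character vector of retained analyte ids.
#' @examples
#' m <- rbind(kept = c(0.2, 0.2, 0.2, 0.2, 0.2, 0),
#'            lost = c(0.2, 0.2, 0.2, 0.2, 0, 0))
#' filterLowExpression(m, cpmMin = 0.1, minSamples = 5)
#' @export
filterLowExpression <- function(cpm, cpmMin = 0.1, minSamples = 5L) {
  if (methods::is(cpm, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input requires the SummarizedExperiment package")
    cpm <- SummarizedExperiment::assay(cpm)
  }
  cpm <- as.matrix(cpm)
  if (length(cpm) == 0L) return(character())
  if (cpmMin < 0) stop("cpmMin must be >= 0")
  if (minSamples < 1L || minSamples > ncol(cpm))
    stop("minSamples must lie in [1, ncol(cpm)]")
  if (any(cpm < 0, na.rm = TRUE)) stop("CPM values must be nonnegative")
  keep <- rowSums(cpm > cpmMin, na.rm = TRUE) >= minSamples
  ids <- rownames(cpm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(cpm)))
  ids[keep]
}

#' Signature-calling thresholds
#'
#' @param pCutoff p-value cutoff in (0,1), strict.
#' @param lfcCutoff |log2 fold change| cutoff, strict. The conventional
#'   "log2 fold change > 1.5" rule is read as a threshold on the magnitude
#'   of the log2 fold change, not on the linear fold change.
#' @param useAdjusted threshold the adjusted p-value column instead of the
#'   raw one.
#' @return a \linkS4class{SignatureThresholds}.
#' @export
signatureThresholds <- function(pCutoff = 0.01, lfcCutoff = 1.5,
                                useAdjusted = FALSE) {
  new("SignatureThresholds", pCutoff = as.numeric(pCutoff),
      lfcCutoff = as.numeric(lfcCutoff), useAdjusted = as.logical(useAdjusted))
}

setMethod("show", "SignatureThresholds", function(object) {
  cat(sprintf("SignatureThresholds: %s p < %g, |log2FC| > %g\n",
              if (object@useAdjusted) "adjusted" else "raw",
              object@pCutoff, object@lfcCutoff))
})

#' Call a differential signature
#'
#' An analyte is a member iff its chosen p-value is strictly below
#' \code{pCutoff} and its |log2fc| strictly above \code{lfcCutoff}; its
#' direction is the sign of the fold change (a zero fold change can never be
#' a member). Records with missing statistics are excluded and counted in
#' the \code{nDropped} slot of the result.
#'
#' @param table a \linkS4class{DifferentialTable}.
#' @param thresholds a \linkS4class{SignatureThresholds}.
#' @param universe optional background (character vector or
#'   \linkS4class{AnalyteUniverse}); when given, calling is restricted to
#'   analytes inside it and the universe is attached to the result.
#' @return a \linkS4class{SignatureSet}.
#' @examples
#' tab <- differentialTable(c("a", "b", "c"), c(2, 1.5, -3),
#'                          c(0.005, 0.005, 0.02))
#' members(callSignature(tab, signatureThresholds(0.01, 1.5)))
#' @export
callSignature <- function(table, thresholds = signatureThresholds(),
                          universe = NULL) {
  stopifnot(is(table, "DifferentialTable"),
            is(thresholds, "SignatureThresholds"))
  st <- table@stats
  if (nrow(st) == 0L) stop("table is empty")
  uni <- character()
  if (!is.null(universe)) {
    uni <- .universeIds(universe)
    st <- st[st$analyte_id %in% uni, , drop = FALSE]
  }
  pv <- if (thresholds@useAdjusted) st$adj_p else st$p_value
  if (thresholds@useAdjusted && anyNA(st$adj_p)) {
    offenders <- st$analyte_id[is.na(st$adj_p)]
    stop("useAdjusted = TRUE but adj_p is missing for: ",
         paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) sprintf(" (and %d more)",
                                             length(offenders) - 10) else "")
  }
  usable <- !is.na(pv) & !is.na(st$log2fc)
  nDropped <- sum(!usable)
  hit <- usable & pv < thresholds@pCutoff &
    abs(st$log2fc) > thresholds@lfcCutoff
  ids <- st$analyte_id[hit]
  dirs <- as.integer(sign(st$log2fc[hit]))
  new("SignatureSet", condition = conditionLabel(table),
      members = ids, directions = setNames(dirs, ids),
      universe = uni, nDropped = as.integer(nDropped))
}

#' @rdname SignatureSet-class
#' @param x,object a \linkS4class{SignatureSet}.
#' @export
setMethod("members", "SignatureSet", function(x) x@members)

#' @rdname SignatureSet-class
#' @export
setMethod("directions", "SignatureSet", function(x) x@directions)

#' @rdname SignatureSet-class
#' @export
setMethod("length", "SignatureSet", function(x) length(x@members))

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", object@condition, "\n")
  cat(sprintf("  %d members (%d up / %d down), %d dropped for missing stats\n",
              length(object@members), sum(object@directions == 1L),
              sum(object@directions == -1L), object@nDropped))
  if (length(object@universe))
    cat("  universe attached:", length(object@universe), "analytes\n")
})

#' Construct a SignatureSet directly
#'
#' @param members analyte ids.
#' @param directions +1/-1 per member (recycled if length 1).
#' @param condition condition label.
#' @param universe optional background ids.
#' @return a \linkS4class{SignatureSet}.
#' @export
signatureSet <- function(members, directions = 1L, condition = "unspecified",
                         universe = character()) {
  members <- as.character(members)
  directions <- as.integer(rep_len(directions, length(members)))
  new("SignatureSet", condition = condition, members = members,
      directions = setNames(directions, members),
      universe = .universeIds(universe))
}

#' Write a signature set (TSV + JSON sidecar)
#'
#' Writes a two-column TSV (\code{analyte_id}, \code{direction}) and a JSON
#' sidecar (\code{<path>.json}) with the condition label and counts.
#'
#' @param x a \linkS4class{SignatureSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureSet <- function(x, path) {
  out <- data.frame(analyte_id = x@members,
                    direction = unname(x@directions))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(condition = x@condition,
               n_members = length(x@members),
               n_up = sum(x@directions == 1L),
               n_down = sum(x@directions == -1L),
               n_dropped = x@nDropped,
               universe_size = length(x@universe))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a signature set written by [writeSignatureSet()]
#'
#' @param path TSV path.
#' @param condition condition label to attach.
#' @return a \linkS4class{SignatureSet}.
#' @export
readSignatureSet <- function(path, condition = "unspecified") {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  signatureSet(tab$analyte_id, as.integer(tab$direction), condition)
}

## internal coercions used throughout
.memberIds <- function(x) {
  if (is(x, "SignatureSet")) x@members else as.character(x)
}

.universeIds <- function(x) {
  if (is.null(x)) return(character())
  if (is(x, "AnalyteUniverse")) x@ids else as.character(x)
}
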