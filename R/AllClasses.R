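#' @include AllGenerics.R
NULL

#' QuantMatrix: reporter abundances with sample metadata
#'
#' A features-by-samples matrix of non-negative reporter abundances (TMT or
#' comparable isobaric quantification) together with the sample annotation
#' needed to form condition groups. Extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay named
#' `"abundance"`; `colData` carries `cell_line`, `drug` and `replicate`.
#' Vehicle-control columns use the drug label `"DMSO"`.
#'
#' Validity requires non-negative (or missing) abundances, unique feature
#' identifiers, at least two replicate columns per (cell line, drug) group,
#' and a matched DMSO group in the same cell line for every treated group.
#'
#' @seealso [QuantMatrix()] for construction, [buildFoldChangeTable()].
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
  msg <- character(0)
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  a <- assay(object, "abundance")
  if (!is.numeric(a))
    msg <- c(msg, "abundances must be numeric")
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be non-negative")
  if ((nrow(object) > 0L && is.null(rownames(object))) ||
      anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers must be present and unique")
  cd <- colData(object)
  need <- c("cell_line", "drug", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", ")))
  } else {
    key <- paste(cd$cell_line, cd$drug)
    cnt <- table(key)
    if (any(cnt < 2L))
      msg <- c(msg, paste0("group(s) with fewer than 2 replicate columns: ",
                           paste(names(cnt)[cnt < 2L], collapse = ", ")))
    treated <- unique(cd[cd$drug != VEHICLE, c("cell_line", "drug"),
                         drop = FALSE])
    veh_lines <- unique(cd$cell_line[cd$drug == VEHICLE])
    orphan <- setdiff(unique(treated$cell_line), veh_lines)
    if (length(orphan))
      msg <- c(msg, paste0("cell line(s) without a matched DMSO group: ",
                           paste(orphan, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param abundances numeric matrix (or coercible), features x samples, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param sampleInfo `data.frame` with one row per sample column and columns
#'   `cell_line`, `drug` (`"DMSO"` for vehicle) and `replicate`. Rows are
#'   matched to columns by a `sample` column if present, otherwise by
#'   rownames, otherwise by position.
#' @return a validated [QuantMatrix-class] object.
#' @examples
#' a <- matrix(rexp(12, 1e-5), nrow = 3,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' si <- data.frame(cell_line = "A549",
#'                  drug = rep(c("belinostat", "DMSO"), each = 2),
#'                  replicate = rep(1:2, 2))
#' qm <- QuantMatrix(a, si)
#' @export
QuantMatrix <- function(abundances, sampleInfo) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  sampleInfo <- as.data.frame(sampleInfo)
  if (is.null(colnames(abundances)))
    stop("abundance matrix must have sample column names")
  if ("sample" %in% colnames(sampleInfo)) {
    idx <- match(colnames(abundances), sampleInfo$sample)
    if (anyNA(idx)) {
      stop("sample metadata missing for column(s): ",
           paste(colnames(abundances)[is.na(idx)], collapse = ", "))
    }
    sampleInfo <- sampleInfo[idx, setdiff(colnames(sampleInfo), "sample"),
                             drop = FALSE]
  } else if (!is.null(rownames(sampleInfo)) &&
             all(colnames(abundances) %in% rownames(sampleInfo))) {
    sampleInfo <- sampleInfo[colnames(abundances), , drop = FALSE]
  } else if (nrow(sampleInfo) != ncol(abundances)) {
    stop("sample metadata does not cover all sample columns")
  }
  se <- SummarizedExperiment(
    assays = list(abundance = abundances),
    colData = DataFrame(sampleInfo, row.names = colnames(abundances)))
  new("QuantMatrix", se)
}

#' @rdname abundances
#' @export
setMethod("abundances", "QuantMatrix", function(object, ...)
  assay(object, "abundance"))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "QuantMatrix", function(object, ...)
  as.data.frame(colData(object)))

#' @rdname conditionGroups
#' @export
setMethod("conditionGroups", "QuantMatrix", function(object, ...) {
  cd <- as.data.frame(colData(object))
  g <- unique(cd[cd$drug != VEHICLE, c("cell_line", "drug"), drop = FALSE])
  g <- g[order(g$cell_line, g$drug), , drop = FALSE]
  data.frame(group = .groupId(g$cell_line, g$drug),
             cell_line = g$cell_line, drug = g$drug,
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "QuantMatrix", function(object) {
  cd <- colData(object)
  ngrp <- nrow(conditionGroups(object))
  cat("QuantMatrix with", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  cell lines:", paste(unique(cd$cell_line), collapse = ", "), "\n")
  cat("  condition groups:", ngrp, " (vehicle label:", VEHICLE, ")\n")
})

#' FoldChangeTable: vehicle-relative log2 fold changes per condition group
#'
#' One row per feature x condition group holding the log2 fold change of the
#' treated replicate mean over the matched DMSO replicate mean, the
#' linear-scale replicate CVs of both arms, replicate counts, and a
#' `quantified` flag. Entries fail quantification when either arm's CV meets
#' or exceeds `cvMax` or when replicate values are missing; their `log2fc`
#' is `NA`.
#'
#' @slot table long-format `data.frame` (see [fcTable()]).
#' @slot groups `data.frame` of condition groups (`group`, `cell_line`,
#'   `drug`).
#' @slot cvMax the replicate CV ceiling applied.
#' @seealso [buildFoldChangeTable()], [fcMatrix()]
#' @export
setClass("FoldChangeTable",
         representation(table = "data.frame", groups = "data.frame",
                        cvMax = "numeric"))

setValidity("FoldChangeTable", function(object) {
  msg <- character(0)
  need <- c("feature", "group", "cell_line", "drug", "log2fc", "cv_treated",
            "cv_vehicle", "n_treated", "n_vehicle", "quantified")
  miss <- setdiff(need, colnames(object@table))
  if (length(miss))
    msg <- c(msg, paste0("table lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    q <- object@table$quantified
    if (any(q & !is.finite(object@table$log2fc)))
      msg <- c(msg, "log2fc must be finite wherever quantified")
    cvs <- c(object@table$cv_treated, object@table$cv_vehicle)
    if (any(cvs < 0, na.rm = TRUE))
      msg <- c(msg, "replicate CVs must be non-negative")
  }
  if (length(object@cvMax) != 1L || object@cvMax <= 0)
    msg <- c(msg, "cvMax must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname fcTable
#' @export
setMethod("fcTable", "FoldChangeTable", function(object, ...) object@table)

#' @rdname conditionGroups
#' @export
setMethod("conditionGroups", "FoldChangeTable", function(object, ...)
  object@groups)

#' @rdname cvMax
#' @export
setMethod("cvMax", "FoldChangeTable", function(object) object@cvMax)

#' @rdname fcMatrix
#' @export
setMethod("fcMatrix", "FoldChangeTable", function(object, groups = NULL, ...) {
  tab <- object@table
  gs <- object@groups$group
  if (!is.null(groups)) {
    bad <- setdiff(groups, gs)
    if (length(bad))
      stop("unknown condition group(s): ", paste(bad, collapse = ", "))
    gs <- groups
  }
  feats <- unique(tab$feature)
  m <- matrix(NA_real_, length(feats), length(gs),
              dimnames = list(feats, gs))
  keep <- tab$quantified & tab$group %in% gs
  m[cbind(match(tab$feature[keep], feats), match(tab$group[keep], gs))] <-
    tab$log2fc[keep]
  m
})

setMethod("show", "FoldChangeTable", function(object) {
  tab <- object@table
  cat("FoldChangeTable:", length(unique(tab$feature)), "features x",
      nrow(object@groups), "condition groups\n")
  cat(sprintf("  quantified entries: %d of %d (CV < %.2f in both arms)\n",
              sum(tab$quantified), nrow(tab), object@cvMax))
})
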