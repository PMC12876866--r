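#' @include hdacPerturb-package.R
NULL

#' Extract the reporter-abundance matrix
#'
#' @param object a [QuantMatrix-class] object.
#' @param ... further arguments, unused.
#' @return numeric matrix of abundances, features in rows, samples in columns.
#' @export
setGeneric("abundances", function(object, ...) standardGeneric("abundances"))

#' Extract per-sample metadata
#'
#' @param object a [QuantMatrix-class] object.
#' @param ... further arguments, unused.
#' @return `data.frame` with one row per sample column (`cell_line`, `drug`,
#'   `replicate`).
#' @export
setGeneric("sampleInfo", function(object, ...) standardGeneric("sampleInfo"))

#' Enumerate condition groups
#'
#' A condition group ("cell-line-by-drug group") is one treated
#' (cell line, drug) combination with its replicates; DMSO columns are the
#' matched vehicle and do not form groups of their own.
#'
#' @param object a [QuantMatrix-class] or [FoldChangeTable-class] object.
#' @param ... further arguments, unused.
#' @return `data.frame` with columns `group`, `cell_line`, `drug`.
#' @export
setGeneric("conditionGroups", function(object, ...)
  standardGeneric("conditionGroups"))

#' Long-format fold-change table
#'
#' @param object a [FoldChangeTable-class] object.
#' @param ... further arguments, unused.
#' @return `data.frame` with one row per feature x condition group.
#' @export
setGeneric("fcTable", function(object, ...) standardGeneric("fcTable"))

#' Wide matrix of log2 fold changes
#'
#' @param object a [FoldChangeTable-class] object.
#' @param groups optional character vector restricting the columns.
#' @param ... further arguments, unused.
#' @return numeric matrix, features x condition groups; entries that failed
#'   the replicate-quality filter are `NA`.
#' @export
setGeneric("fcMatrix", function(object, groups = NULL, ...)
  standardGeneric("fcMatrix"))

#' Replicate CV ceiling used when the table was built
#'
#' @param object a [FoldChangeTable-class] object.
#' @return the `cv_max` threshold (linear-scale coefficient of variation).
#' @export
setGeneric("cvMax", function(object) standardGeneric("cvMax"))
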