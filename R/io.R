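#' @include AllClasses.R
NULL

.writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reporter-abundance table with its sample metadata
#'
#' The abundance file is TSV with a `feature_id` header column followed by
#' one column per sample; the metadata file is TSV with columns `sample`,
#' `cell_line`, `drug`, `replicate`. Duplicate feature ids and sample
#' columns without metadata are rejected.
#'
#' @param path abundance TSV.
#' @param meta_path sample-metadata TSV.
#' @return a [QuantMatrix-class].
#' @export
readQuantTable <- function(path, meta_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "feature_id")
    stop("first column of ", path, " must be 'feature_id'")
  ids <- tab$feature_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature id(s): ", paste(head(dup, 10L), collapse = ", "))
  a <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(a) <- ids
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "drug", "replicate")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  QuantMatrix(a, meta)
}

#' Write a QuantMatrix as TSV abundance + metadata files
#'
#' Inverse of [readQuantTable()]; round-trips losslessly up to numeric
#' printing precision (15 significant digits).
#'
#' @param m a [QuantMatrix-class].
#' @param path abundance TSV to write.
#' @param meta_path metadata TSV to write.
#' @return invisibly, the two paths.
#' @export
writeQuantTable <- function(m, path, meta_path) {
  stopifnot(is(m, "QuantMatrix"))
  a <- abundances(m)
  tab <- data.frame(feature_id = rownames(a),
                    format(a, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  .writeTSV(tab, path)
  si <- sampleInfo(m)
  meta <- data.frame(sample = rownames(si), si, row.names = NULL,
                     stringsAsFactors = FALSE)
  .writeTSV(meta, meta_path)
  invisible(c(path, meta_path))
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then member ids.
#' Duplicate members within a set are deduplicated with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors; set descriptions are kept in
#'   the `"description"` attribute.
#' @export
readGMT <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(ln)) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, " of ", path,
           ": GMT lines need name, description and at least one member")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate member id(s) in set '", f[1L], "' deduplicated")
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    desc[f[1L]] <- f[2L]
  }
  if (anyDuplicated(names(sets)))
    stop("duplicate set name(s) in ", path)
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors; descriptions are taken from
#'   the `"description"` attribute when present.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "description")
  ln <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(ln, path)
  invisible(path)
}

#' Read a transcript effect table
#'
#' TSV with columns `gene`, `normalized_effect` (the upstream
#' differential-expression dose coefficient) and `fdr`.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
readTranscriptTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "normalized_effect", "fdr")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("transcript table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  tab
}

#' Read a kinase-substrate map
#'
#' Two-column TSV `kinase<TAB>site`; site ids follow the
#' `PROTEIN_<residue><position>` convention (e.g. `BAD_S118`).
#'
#' @param path TSV file (a header row `kinase	site` is optional).
#' @return named list, kinase to character vector of site ids.
#' @export
readKinaseSubstrateMap <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("kinase-substrate map needs two tab-separated columns")
  hdr <- tolower(unname(vapply(tab[1L, 1:2], as.character, character(1))))
  if (identical(hdr, c("kinase", "site")))
    tab <- tab[-1L, , drop = FALSE]
  split(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read a kinase motif-score table
#'
#' Two-column TSV `kinase<TAB>score` from an external motif predictor.
#'
#' @param path TSV file (header optional).
#' @return named numeric vector.
#' @export
readMotifScores <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("motif-score table needs two tab-separated columns")
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]
  setNames(as.numeric(tab[[2L]]), tab[[1L]])
}
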