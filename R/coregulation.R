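#' @include quant.R
NULL

#' Pearson correlation of two fold-change profiles
#'
#' Thin, validated wrapper around the product-moment correlation used by the
#' co-regulation screens; refuses short or constant inputs rather than
#' returning an undefined value silently.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_points minimum number of paired finite observations.
#' @return Pearson r.
#' @export
pearsonCorrelation <- function(x, y, min_points = 3L) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_points)
    stop("fewer than ", min_points, " shared finite observations")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop("constant input; correlation undefined")
  cor(x[ok], y[ok])
}

#' Screen all features for co-regulation with anchor features
#'
#' Correlates every feature's log2 fold-change profile across condition
#' groups with each anchor's profile (pairwise-complete observations) and
#' returns the anchor-partner pairs passing a strict correlation threshold.
#' Only partners quantified in at least `coverage_min` of the condition
#' groups are tested, mirroring the coverage rule of the phosphosite screen.
#' The protein-level screen conventionally uses signed r (e.g. r > 0.9);
#' setting `signed = FALSE` compares |r| instead (e.g. |r| > 0.8 for
#' phosphosites, where anticorrelated partners are of equal interest).
#'
#' @param fc a [FoldChangeTable-class].
#' @param anchors character vector of anchor feature ids; each must be
#'   present in `fc`.
#' @param r_threshold correlation threshold (strict `>`).
#' @param coverage_min minimum fraction of condition groups in which a
#'   partner must be quantified to be tested.
#' @param signed compare signed r (`TRUE`, default) or |r|.
#' @param min_points edges supported by fewer than this many shared groups
#'   are flagged (`low_n = TRUE`) rather than dropped.
#' @param groups optional subset of condition groups over which profiles are
#'   taken (default: all groups in `fc`).
#' @return `data.frame` of edges: `anchor`, `partner`, `r`, `n_points`,
#'   `low_n`.
#' @export
anchorScreen <- function(fc, anchors, r_threshold = 0.9, coverage_min = 0.8,
                         signed = TRUE, min_points = 5L, groups = NULL) {
  stopifnot(is(fc, "FoldChangeTable"))
  m <- fcMatrix(fc, groups = groups)
  missing_anchors <- setdiff(anchors, rownames(m))
  if (length(missing_anchors))
    stop("anchor(s) absent from the fold-change table: ",
         paste(missing_anchors, collapse = ", "))
  ngrp <- ncol(m)
  coverage <- rowSums(!is.na(m)) / ngrp
  testable <- rownames(m)[coverage >= coverage_min]
  edges <- lapply(anchors, function(anc) {
    av <- m[anc, ]
    partners <- setdiff(testable, anc)
    if (!length(partners)) return(NULL)
    pm <- t(m[partners, , drop = FALSE])
    n_pts <- colSums(!is.na(pm) & !is.na(av))
    r <- suppressWarnings(cor(pm, av, use = "pairwise.complete.obs"))[, 1L]
    pass <- !is.na(r) & n_pts >= 2L &
      (if (signed) r > r_threshold else abs(r) > r_threshold)
    if (!any(pass)) return(NULL)
    data.frame(anchor = anc, partner = partners[pass], r = unname(r[pass]),
               n_points = unname(n_pts[pass]),
               low_n = unname(n_pts[pass]) < min_points,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  if (is.null(out))
    out <- data.frame(anchor = character(0), partner = character(0),
                      r = numeric(0), n_points = integer(0),
                      low_n = logical(0))
  out
}

#' Fraction of co-regulated partners attributable to one anchor
#'
#' Percentage of the distinct partners in an edge set that have an edge to
#' the given anchor, e.g. "68 of 81 HDAC-correlated proteins were correlated
#' with HDAC7" is an attribution of 83.9%.
#'
#' @param edges edge `data.frame` from [anchorScreen()].
#' @param anchor anchor feature id.
#' @return percentage, truncated to one decimal for display (68 of 81
#'   reports as 83.9).
#' @examples
#' edges <- data.frame(anchor = c("HDAC7", "HDAC7", "HDAC1"),
#'                     partner = c("SRC", "MICALL1", "FUCA1"))
#' attributeFraction(edges, "HDAC7")  # 2 of 3 partners -> 66.6
#' @export
attributeFraction <- function(edges, anchor) {
  if (is.null(edges) || nrow(edges) == 0L)
    stop("empty edge set; attribution undefined")
  all_partners <- unique(edges$partner)
  anc_partners <- unique(edges$partner[edges$anchor == anchor])
  trunc(1000 * length(anc_partners) / length(all_partners)) / 10
}
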