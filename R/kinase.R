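#' @include quant.R
NULL

#' Kinase-substrate enrichment analysis (KSEA) for one condition group
#'
#' Scores each kinase by comparing the mean log2 fold change of its
#' quantified substrate phosphosites against the background of all
#' quantified sites in the group:
#' \deqn{z = (\bar{m}_s - \bar{m}_p) \sqrt{m} / \delta}
#' where \eqn{\bar{m}_s} is the substrate-set mean, \eqn{\bar{m}_p} the mean
#' over all sites, \eqn{m} the number of quantified substrates and
#' \eqn{\delta} the sample standard deviation over all sites. Two-sided
#' normal p-values are Benjamini-Hochberg adjusted across the kinases
#' scored within the group.
#'
#' @param site_fc named numeric vector of phosphosite log2 fold changes for
#'   one condition group (names are site ids such as `"BAD_S118"`);
#'   non-finite entries are dropped.
#' @param map named list, kinase id to character vector of substrate site
#'   ids.
#' @return `data.frame` with `kinase`, `z`, `m`, `p`, `p_adj`, restricted to
#'   kinases with at least one quantified substrate; `NULL` (with a warning)
#'   when the background SD is zero.
#' @examples
#' fc <- c(a = 0, b = 0, c = 0, d = 0, e = 1, f = 1)
#' ksea(fc, list(K1 = c("e", "f")))  # z = (1 - 1/3) * sqrt(2) / sd(fc)
#' @export
ksea <- function(site_fc, map) {
  site_fc <- site_fc[is.finite(site_fc)]
  if (length(site_fc) < 2L)
    stop("need at least 2 quantified sites")
  if (is.null(names(site_fc)) || !length(map) || is.null(names(map)))
    stop("site_fc and map must be named")
  bg_mean <- mean(site_fc)
  bg_sd <- sd(site_fc)
  if (bg_sd == 0) {
    warning("zero background SD; group skipped")
    return(NULL)
  }
  rows <- lapply(names(map), function(k) {
    subs <- intersect(map[[k]], names(site_fc))
    m <- length(subs)
    if (m < 1L) return(NULL)
    z <- (mean(site_fc[subs]) - bg_mean) * sqrt(m) / bg_sd
    data.frame(kinase = k, z = z, m = m, p = 2 * pnorm(-abs(z)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adj <- bhAdjust(out$p)
  out[order(-abs(out$z)), , drop = FALSE]
}

#' KSEA across all condition groups of a phosphosite fold-change table
#'
#' @param fc a [FoldChangeTable-class] of phosphosite log2 fold changes.
#' @param map kinase-substrate map (named list of site-id vectors).
#' @param groups optional subset of condition groups (default all).
#' @return long `data.frame`: `group`, `kinase`, `z`, `m`, `p`, `p_adj`
#'   (BH within each group).
#' @export
kseaAll <- function(fc, map, groups = NULL) {
  stopifnot(is(fc, "FoldChangeTable"))
  m <- fcMatrix(fc, groups = groups)
  out <- lapply(colnames(m), function(g) {
    v <- m[, g]
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NULL)
    res <- ksea(v, map)
    if (is.null(res)) return(NULL)
    cbind(group = g, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank candidate kinases for one phosphosite
#'
#' Implements the two-criterion candidate rule for assigning an upstream
#' kinase to a regulated phosphosite: the kinase must carry a
#' sequence-motif predictor score strictly above `score_min` for the site's
#' motif, and its protein-abundance fold-change profile must correlate with
#' the site's fold-change profile at |r| strictly above `r_min` across the
#' shared condition groups. Kinases quantified in fewer than `min_coverage`
#' groups are excluded before testing. Motif scores are an external
#' predictor's output supplied as input, not computed here.
#'
#' @param site_profile named numeric vector: the phosphosite's log2 fold
#'   change per condition group (`NA` where unquantified).
#' @param kinase_fc a [FoldChangeTable-class] restricted to kinase proteins,
#'   or a numeric matrix kinases x groups.
#' @param motif_scores named numeric vector, kinase to predictor score;
#'   kinases without a score are dropped.
#' @param r_min correlation threshold (strict, on |r|).
#' @param score_min motif-score threshold (strict).
#' @param min_coverage minimum number of groups in which a kinase must be
#'   quantified (the screen convention is 28 of 30 HDACi groups).
#' @param min_points minimum shared quantified groups for a correlation.
#' @return `data.frame` sorted by decreasing |r|: `kinase`, `motif_score`,
#'   `r`, `n_points`, `passes`. Empty (with a warning) when no kinase meets
#'   the coverage floor.
#' @export
rankKinaseCandidates <- function(site_profile, kinase_fc, motif_scores,
                                 r_min = 0.8, score_min = 1.0,
                                 min_coverage = 28L, min_points = 5L) {
  km <- if (is(kinase_fc, "FoldChangeTable")) fcMatrix(kinase_fc) else
    as.matrix(kinase_fc)
  km <- km[, names(site_profile), drop = FALSE]
  km <- km[rownames(km) %in% names(motif_scores), , drop = FALSE]
  covered <- rowSums(!is.na(km)) >= min_coverage
  empty <- data.frame(kinase = character(0), motif_score = numeric(0),
                      r = numeric(0), n_points = integer(0),
                      passes = logical(0))
  if (!any(covered)) {
    warning("no kinase passes the coverage floor")
    return(empty)
  }
  km <- km[covered, , drop = FALSE]
  rows <- lapply(rownames(km), function(k) {
    ok <- is.finite(km[k, ]) & is.finite(site_profile)
    n <- sum(ok)
    if (n < min_points) return(NULL)
    if (sd(km[k, ok]) == 0 || sd(site_profile[ok]) == 0) return(NULL)
    r <- cor(km[k, ok], site_profile[ok])
    sc <- unname(motif_scores[k])
    data.frame(kinase = k, motif_score = sc, r = r, n_points = n,
               passes = sc > score_min && abs(r) > r_min,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out[order(-abs(out$r)), , drop = FALSE]
}
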