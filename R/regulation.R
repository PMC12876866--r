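#' @include quant.R
NULL

#' Call regulated events from a fold-change table
#'
#' A feature is regulated in a condition group when its absolute log2 fold
#' change strictly exceeds the threshold (default 1, i.e. a two-fold
#' change). Unquantified entries receive no call.
#'
#' @param fc a [FoldChangeTable-class].
#' @param threshold fold-change threshold on the log2 scale; the comparison
#'   is strict, so `log2fc == threshold` is not a call.
#' @return `data.frame` with one row per quantified feature x group:
#'   `feature`, `group`, `cell_line`, `drug`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `log2fc`.
#' @export
callRegulated <- function(fc, threshold = 1.0) {
  stopifnot(is(fc, "FoldChangeTable"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number")
  tab <- fcTable(fc)
  tab <- tab[tab$quantified, , drop = FALSE]
  dir <- rep("none", nrow(tab))
  dir[tab$log2fc > threshold] <- "up"
  dir[tab$log2fc < -threshold] <- "down"
  data.frame(feature = tab$feature, group = tab$group,
             cell_line = tab$cell_line, drug = tab$drug,
             direction = dir, log2fc = tab$log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group regulated-event counts (waterfall)
#'
#' Counts up- and down-regulated features per condition group, ordered by
#' decreasing total (ties broken lexicographically by group name), the
#' ordering used in waterfall displays of proteome remodeling strength.
#'
#' @param calls output of [callRegulated()].
#' @return `data.frame` with `group`, `n_up`, `n_down`, `n_total`.
#' @export
waterfallCounts <- function(calls) {
  stopifnot(all(c("group", "direction") %in% colnames(calls)))
  gs <- sort(unique(calls$group))
  up <- vapply(gs, function(g)
    sum(calls$group == g & calls$direction == "up"), integer(1))
  down <- vapply(gs, function(g)
    sum(calls$group == g & calls$direction == "down"), integer(1))
  out <- data.frame(group = gs, n_up = up, n_down = down,
                    n_total = up + down, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$n_total, out$group), , drop = FALSE]
}

#' Classify cross-group consistency of regulation
#'
#' Separates universal effectors (regulated in every HDACi condition group)
#' from cell-type-specific responders. With `specific_cutoff = 14` a
#' feature regulated in 1-13 groups is `"specific"`, one regulated in 14 or
#' more but not all is `"shared"`, and one never regulated is
#' `"unresponsive"`. Counting is restricted to `hdaci_groups`; outgroup
#' treatments (e.g. a non-HDACi kinase inhibitor) must be excluded by the
#' caller because universality is defined over HDACi-treated cells only.
#'
#' @param calls output of [callRegulated()]; one row per quantified
#'   feature x group.
#' @param hdaci_groups character vector of HDACi condition-group names over
#'   which consistency is assessed.
#' @param specific_cutoff upper bound (exclusive) on the number of regulated
#'   groups for the `"specific"` class.
#' @param require_full_coverage when `TRUE` (default, the stricter reading)
#'   a feature must be quantified in every HDACi group to be `"universal"`;
#'   when `FALSE` universality is judged over the groups where the feature
#'   is quantified.
#' @return `data.frame` with `feature`, `n_regulated`, `n_quantified`,
#'   `n_total_groups`, `class`.
#' @export
classifyConsistency <- function(calls, hdaci_groups, specific_cutoff = 14,
                                require_full_coverage = TRUE) {
  if (length(hdaci_groups) == 0L)
    stop("hdaci_groups must be non-empty")
  bad <- setdiff(hdaci_groups, unique(calls$group))
  if (length(bad))
    stop("group(s) not present in the calls: ", paste(bad, collapse = ", "))
  keep <- calls$group %in% hdaci_groups
  calls <- calls[keep, , drop = FALSE]
  n_total <- length(hdaci_groups)
  feats <- sort(unique(calls$feature))
  reg <- calls$direction != "none"
  n_reg <- vapply(split(reg, factor(calls$feature, levels = feats)), sum,
                  integer(1))
  n_qty <- vapply(split(reg, factor(calls$feature, levels = feats)), length,
                  integer(1))
  cls <- rep("shared", length(feats))
  all_reg <- if (require_full_coverage) {
    n_qty == n_total & n_reg == n_total
  } else {
    n_reg == n_qty & n_reg >= 1L
  }
  cls[all_reg] <- "universal"
  cls[!all_reg & n_reg >= 1L & n_reg < specific_cutoff] <- "specific"
  cls[n_reg == 0L] <- "unresponsive"
  data.frame(feature = feats, n_regulated = unname(n_reg),
             n_quantified = unname(n_qty), n_total_groups = n_total,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of a cell-line subset's composite viability with the global
#' mean
#'
#' Given a conditions-by-models viability matrix (e.g. per-drug viability
#' fold changes over a large cell-line collection), computes the Pearson
#' correlation between the per-condition mean over a chosen subset of
#' models and the per-condition mean over all models. Used to ask how well
#' a small panel recapitulates population-level drug response.
#'
#' @param viability numeric matrix, conditions x models.
#' @param subset column names (or indices) of the model subset.
#' @return Pearson r between the subset composite mean and the global mean.
#' @export
compositeViabilityCorrelation <- function(viability, subset) {
  viability <- as.matrix(viability)
  if (nrow(viability) < 3L)
    stop("need at least 3 conditions")
  if (length(subset) == 0L)
    stop("subset must be non-empty")
  if (is.character(subset)) {
    bad <- setdiff(subset, colnames(viability))
    if (length(bad))
      stop("unknown model(s): ", paste(bad, collapse = ", "))
  }
  gm <- rowMeans(viability)
  sm <- rowMeans(viability[, subset, drop = FALSE])
  if (sd(gm) == 0 || sd(sm) == 0)
    stop("constant viability vector; correlation undefined")
  cor(sm, gm)
}
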