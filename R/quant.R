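#' @include AllClasses.R
NULL

#' Column-sum normalization of a reporter-abundance matrix
#'
#' Rescales every sample column so that all column sums equal the mean of
#' the original column sums, correcting for unequal total reporter signal
#' per channel while leaving within-column feature proportions unchanged.
#'
#' @param m a [QuantMatrix-class] object.
#' @return a [QuantMatrix-class] with rescaled abundances.
#' @examples
#' a <- matrix(c(2, 8, 6, 24), nrow = 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' # column sums 10 and 30 are both brought to 20
#' @export
normalizeColumns <- function(m) {
  stopifnot(is(m, "QuantMatrix"))
  a <- abundances(m)
  cs <- colSums(a, na.rm = TRUE)
  if (any(cs == 0))
    stop("zero-sum sample column(s): ",
         paste(colnames(a)[cs == 0], collapse = ", "))
  target <- mean(cs)
  a <- sweep(a, 2L, target / cs, `*`)
  QuantMatrix(a, sampleInfo(m))
}

#' Replicate coefficient of variation
#'
#' Linear-scale CV (sample standard deviation divided by the mean) over
#' replicate abundances of one feature in one condition group. Features
#' whose replicate CV meets or exceeds the ceiling (default 0.3) are
#' excluded from fold-change quantification.
#'
#' @param values numeric vector of replicate abundances.
#' @return the CV, or `NA` when fewer than two finite values are present or
#'   the mean is not positive (the feature is then unquantified).
#' @examples
#' replicateCV(c(5, 5))   # 0
#' replicateCV(c(1, 3))   # sqrt(2)/2
#' @export
replicateCV <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  sd(values) / m
}

#' Vehicle-relative log2 fold change for one feature
#'
#' log2 of the ratio of replicate means, treated over vehicle, computed only
#' when both arms pass the replicate CV filter. The ratio-of-means form is
#' robust to per-replicate scaling differences.
#'
#' @param treated,vehicle numeric vectors of replicate abundances.
#' @param cv_max replicate CV ceiling applied to each arm independently;
#'   either arm failing voids the pair.
#' @return the log2 fold change, or `NA` when either arm fails the filter.
#' @examples
#' log2FoldChange(c(4, 4), c(1, 1))   # 2
#' log2FoldChange(c(2, 4), c(1, 1))   # log2(3)
#' @export
log2FoldChange <- function(treated, vehicle, cv_max = 0.3) {
  cvt <- replicateCV(treated)
  cvv <- replicateCV(vehicle)
  if (is.na(cvt) || is.na(cvv) || cvt >= cv_max || cvv >= cv_max)
    return(NA_real_)
  log2(mean(treated[is.finite(treated)]) / mean(vehicle[is.finite(vehicle)]))
}

#' Between-replicate Pearson correlation per condition group
#'
#' Correlates log2 abundances of replicate columns within each (cell line,
#' drug) group, including vehicle groups, over features quantified in all
#' replicates of that group; groups with more than two replicates use the
#' mean of all pairwise correlations. Used as a global reproducibility
#' summary of a quantification run.
#'
#' @param m a [QuantMatrix-class] object.
#' @param log compute correlations on log2 abundances (default) rather than
#'   the linear scale.
#' @return list with `per_group` (named numeric vector of r) and `median`.
#'   Groups where a replicate vector is constant are skipped with a warning.
#' @export
replicateCorrelation <- function(m, log = TRUE) {
  stopifnot(is(m, "QuantMatrix"))
  a <- abundances(m)
  if (log) a <- log2(a)
  cd <- sampleInfo(m)
  key <- .groupId(cd$cell_line, cd$drug)
  out <- vapply(unique(key), function(k) {
    x <- a[, key == k, drop = FALSE]
    x <- x[complete.cases(x) & apply(is.finite(x), 1L, all), , drop = FALSE]
    if (nrow(x) < 2L) return(NA_real_)
    if (any(apply(x, 2L, sd) == 0)) {
      warning("constant replicate vector in group ", k, "; skipped")
      return(NA_real_)
    }
    cc <- cor(x)
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  list(per_group = out, median = median(out, na.rm = TRUE))
}

#' Build the fold-change table for all condition groups
#'
#' The workhorse of the quantification stage: for every feature and every
#' treated (cell line, drug) group, computes the replicate CV of the treated
#' and the matched DMSO arm, applies the CV filter (`cv_max`, strict `<` to
#' pass) to both arms independently, and records the log2 fold change of
#' treated over vehicle replicate means where both pass. Features with a
#' missing value in any replicate of an arm are unquantified for that group
#' (no imputation).
#'
#' @param m a [QuantMatrix-class] object.
#' @param cv_max replicate CV ceiling (default 0.3).
#' @return a [FoldChangeTable-class].
#' @examples
#' a <- matrix(c(4, 1, 4, 1, 1, 1, 1, 1), nrow = 2,
#'             dimnames = list(c("P1", "P2"), paste0("s", 1:4)))
#' si <- data.frame(cell_line = "A549",
#'                  drug = rep(c("belinostat", "DMSO"), each = 2),
#'                  replicate = rep(1:2, 2))
#' fct <- buildFoldChangeTable(QuantMatrix(a, si))
#' fcMatrix(fct)   # P1: log2fc 2, P2: 0
#' @export
buildFoldChangeTable <- function(m, cv_max = 0.3) {
  stopifnot(is(m, "QuantMatrix"))
  if (length(cv_max) != 1L || !is.finite(cv_max) || cv_max <= 0)
    stop("cv_max must be a single positive number")
  a <- abundances(m)
  cd <- sampleInfo(m)
  grp <- conditionGroups(m)
  feats <- rownames(a)

  veh_lines <- unique(cd$cell_line[cd$drug == VEHICLE])
  orphan <- setdiff(unique(grp$cell_line), veh_lines)
  if (length(orphan))
    stop("condition group(s) without matched vehicle: ",
         paste(grp$group[grp$cell_line %in% orphan], collapse = ", "))

  if (length(feats) == 0L || nrow(grp) == 0L) {
    tab <- data.frame(feature = character(0), group = character(0),
                      cell_line = character(0), drug = character(0),
                      log2fc = numeric(0), cv_treated = numeric(0),
                      cv_vehicle = numeric(0), n_treated = integer(0),
                      n_vehicle = integer(0), quantified = logical(0))
    return(new("FoldChangeTable", table = tab, groups = grp, cvMax = cv_max))
  }

  # vehicle statistics are shared by all groups of the same cell line
  vstats <- lapply(setNames(veh_lines, veh_lines), function(cl) {
    vx <- a[, cd$cell_line == cl & cd$drug == VEHICLE, drop = FALSE]
    vm <- rowMeans(vx)
    vcv <- .rowSD(vx) / vm
    list(mean = vm, cv = vcv, n = ncol(vx))
  })

  rows <- lapply(seq_len(nrow(grp)), function(i) {
    tx <- a[, cd$cell_line == grp$cell_line[i] & cd$drug == grp$drug[i],
            drop = FALSE]
    tm <- rowMeans(tx)
    tcv <- .rowSD(tx) / tm
    vs <- vstats[[grp$cell_line[i]]]
    ok <- is.finite(tcv) & is.finite(vs$cv) & tcv < cv_max & vs$cv < cv_max &
      tm > 0 & vs$mean > 0
    ok[is.na(ok)] <- FALSE
    l2 <- ifelse(ok, log2(tm / vs$mean), NA_real_)
    data.frame(feature = feats, group = grp$group[i],
               cell_line = grp$cell_line[i], drug = grp$drug[i],
               log2fc = l2, cv_treated = tcv, cv_vehicle = vs$cv,
               n_treated = ncol(tx), n_vehicle = vs$n, quantified = ok,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  new("FoldChangeTable", table = do.call(rbind, rows), groups = grp,
      cvMax = cv_max)
}
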