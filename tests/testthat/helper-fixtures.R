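# small in-code fixtures shared across the suite

# minimal QuantMatrix: one cell line, one drug + DMSO, duplicate columns
toyQuantMatrix <- function(abund, drugs = c("drugA", "drugA", "DMSO", "DMSO"),
                           cell_line = "CL01") {
  abund <- as.matrix(abund)
  colnames(abund) <- sprintf("%s_%s_rep%d", cell_line, drugs,
                             ave(seq_along(drugs), drugs, FUN = seq_along))
  if (is.null(rownames(abund)))
    rownames(abund) <- sprintf("P%03d", seq_len(nrow(abund)))
  si <- data.frame(cell_line = cell_line, drug = drugs,
                   replicate = ave(seq_along(drugs), drugs, FUN = seq_along))
  QuantMatrix(abund, si)
}

# independent naive fold-change oracle: per-feature loops, n-1 SD by hand
naiveFoldChanges <- function(m, cv_max = 0.3) {
  a <- abundances(m)
  cd <- sampleInfo(m)
  grp <- conditionGroups(m)
  res <- list()
  for (i in seq_len(nrow(grp))) {
    tcols <- which(cd$cell_line == grp$cell_line[i] & cd$drug == grp$drug[i])
    vcols <- which(cd$cell_line == grp$cell_line[i] & cd$drug == "DMSO")
    for (f in rownames(a)) {
      tv <- a[f, tcols]; vv <- a[f, vcols]
      cv <- function(x) {
        if (any(!is.finite(x))) return(NA_real_)
        mu <- sum(x) / length(x)
        sqrt(sum((x - mu)^2) / (length(x) - 1)) / mu
      }
      ct <- cv(tv); cvh <- cv(vv)
      q <- !is.na(ct) && !is.na(cvh) && ct < cv_max && cvh < cv_max
      res[[length(res) + 1L]] <- data.frame(
        feature = f, group = grp$group[i],
        log2fc = if (q) log2(mean(tv) / mean(vv)) else NA_real_,
        quantified = q, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

smallSimConfig <- function(seed = 1L, ...) {
  simConfig(n_proteins = 300L, n_phosphosites = 100L,
            n_pisa_proteins = 60L, n_concordance_genes = 90L,
            n_divergent = 40L, seed = seed, ...)
}

makeFct <- function(l2fc_matrix) {
  # wrap a features x groups log2fc matrix into a FoldChangeTable
  feats <- rownames(l2fc_matrix)
  gs <- colnames(l2fc_matrix)
  parts <- strsplit(gs, "_", fixed = TRUE)
  tab <- expand.grid(feature = feats, group = gs,
                     stringsAsFactors = FALSE)
  idx <- cbind(match(tab$feature, feats), match(tab$group, gs))
  tab$cell_line <- vapply(parts, `[`, "", 1L)[idx[, 2L]]
  tab$drug <- vapply(parts, `[`, "", 2L)[idx[, 2L]]
  tab$log2fc <- l2fc_matrix[idx]
  tab$cv_treated <- 0.01
  tab$cv_vehicle <- 0.01
  tab$n_treated <- 2L
  tab$n_vehicle <- 2L
  tab$quantified <- is.finite(tab$log2fc)
  tab$log2fc[!tab$quantified] <- NA_real_
  grp <- data.frame(group = gs, cell_line = vapply(parts, `[`, "", 1L),
                    drug = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  new("FoldChangeTable", table = tab, groups = grp, cvMax = 0.3)
}
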