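#' @include quant.R
NULL

# row-major 3x3 grid: transcript state in rows (up, none, down), protein
# state in columns (down, none, up); fixed by the anchored descriptions
# Group 1 = transcript-up/protein-down, Group 3 = transcript-up/protein-up,
# and the concordance of Groups 3 and 7.
.NINE_GROUP_GRID <- matrix(1:9, nrow = 3, byrow = TRUE,
                           dimnames = list(c("up", "none", "down"),
                                           c("down", "none", "up")))

#' Nine-group transcript-protein concordance classification
#'
#' Classifies each (protein log2 fold change, transcript normalized effect)
#' pair into a 3x3 grid by thresholding both axes with strict inequalities:
#' transcript state up/none/down at `+/- t_thresh`, protein state at
#' `+/- p_thresh`. Group 1 is transcript-up/protein-down, Group 3
#' transcript-up/protein-up, Group 5 the double-null center, Group 7
#' transcript-down/protein-down, Group 9 transcript-down/protein-up;
#' Groups 3 and 7 are the concordant responders.
#'
#' @param protein_log2fc,transcript_effect numeric vectors (recycled to a
#'   common length).
#' @param p_thresh protein threshold on the log2 scale (default 1).
#' @param t_thresh transcript normalized-effect threshold (default 0.05).
#' @return integer vector of groups 1-9; pairs with a non-finite member are
#'   `NA` with a warning.
#' @examples
#' classifyNineGroups(2.0, 0.10)    # 3: concordant up
#' classifyNineGroups(-1.5, 0.06)   # 1: transcript up, protein down
#' classifyNineGroups(1.0, 0.0)     # 5: thresholds are strict
#' @export
classifyNineGroups <- function(protein_log2fc, transcript_effect,
                               p_thresh = 1.0, t_thresh = 0.05) {
  n <- max(length(protein_log2fc), length(transcript_effect))
  p <- rep_len(protein_log2fc, n)
  t <- rep_len(transcript_effect, n)
  bad <- !is.finite(p) | !is.finite(t)
  if (any(bad))
    warning(sum(bad), " record(s) with non-finite values skipped")
  trow <- ifelse(t > t_thresh, 1L, ifelse(t < -t_thresh, 3L, 2L))
  pcol <- ifelse(p < -p_thresh, 1L, ifelse(p > p_thresh, 3L, 2L))
  g <- .NINE_GROUP_GRID[cbind(trow, pcol)]
  g[bad] <- NA_integer_
  g
}

#' Merge proteome and transcriptome layers and classify concordance
#'
#' Inner-joins per-gene protein log2 fold changes with transcript
#' normalized effects (case-insensitive symbol match), computes the Pearson
#' correlation between the paired vectors, and assigns every joined gene a
#' nine-group concordance class via [classifyNineGroups()].
#'
#' @param protein_fc named numeric vector of protein log2 fold changes for
#'   one condition group, or a [FoldChangeTable-class] together with
#'   `group`.
#' @param transcripts `data.frame` with columns `gene`, `normalized_effect`
#'   and `fdr` (the upstream differential-expression fit's dose coefficient
#'   and adjusted p).
#' @param group condition-group name, required when `protein_fc` is a
#'   [FoldChangeTable-class].
#' @param p_thresh,t_thresh thresholds passed to [classifyNineGroups()].
#' @param require_fdr when `TRUE`, genes with `fdr >= fdr_max` are forced to
#'   the transcript-null state regardless of effect size. Off by default:
#'   the axis thresholds alone decide states.
#' @param fdr_max FDR ceiling used when `require_fdr = TRUE`.
#' @return list with `records` (`gene`, `protein_log2fc`,
#'   `transcript_effect`, `group`) and `r`, the proteome-transcriptome
#'   Pearson correlation over the joined genes.
#' @export
mergeOmics <- function(protein_fc, transcripts, group = NULL,
                       p_thresh = 1.0, t_thresh = 0.05,
                       require_fdr = FALSE, fdr_max = 0.05) {
  if (is(protein_fc, "FoldChangeTable")) {
    if (is.null(group))
      stop("supply 'group' when protein_fc is a FoldChangeTable")
    m <- fcMatrix(protein_fc, groups = group)
    protein_fc <- m[, 1L]
  }
  if (is.null(names(protein_fc)))
    stop("protein_fc must be named by gene")
  need <- c("gene", "normalized_effect", "fdr")
  if (!all(need %in% colnames(transcripts)))
    stop("transcripts must have columns: ", paste(need, collapse = ", "))
  protein_fc <- protein_fc[is.finite(protein_fc)]
  idx <- match(toupper(names(protein_fc)), toupper(transcripts$gene))
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no genes shared between the protein and transcript layers")
  genes <- names(protein_fc)[keep]
  p <- unname(protein_fc[keep])
  tt <- transcripts[idx[keep], , drop = FALSE]
  te <- tt$normalized_effect
  if (require_fdr)
    te[tt$fdr >= fdr_max] <- 0
  grp <- classifyNineGroups(p, te, p_thresh = p_thresh, t_thresh = t_thresh)
  r <- if (length(p) >= 3L && sd(p) > 0 && sd(te) > 0) cor(p, te)
       else NA_real_
  list(records = data.frame(gene = genes, protein_log2fc = p,
                            transcript_effect = te, group = grp,
                            row.names = NULL, stringsAsFactors = FALSE),
       r = r)
}
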