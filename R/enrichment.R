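#' @include hdacPerturb-package.R
NULL

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust]) with
#' input validation; values are returned in the input order, capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (`NA` passed
#'   through).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a foreground set
#' (e.g. the regulated proteins of one condition group) within a background
#' universe (the proteins quantified in that group), using the upper-tail
#' hypergeometric probability \eqn{P(X \ge k)} for drawing `k` term members
#' in a foreground of size `n` from a background of `N` features containing
#' `K` term members. Term membership is intersected with the background
#' before testing; p-values are Benjamini-Hochberg adjusted across all
#' tested terms and a term is called enriched at adjusted p < `alpha`.
#'
#' @param foreground character vector of feature ids; must be a subset of
#'   `background`.
#' @param background character vector of at least 2 feature ids (the
#'   quantified universe).
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param alpha adjusted-p threshold for the `enriched` flag.
#' @return `data.frame`: `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `enriched`.
#' @examples
#' bg <- paste0("P", 1:10)
#' hypergeomEnrich(paste0("P", 1:5), bg, list(T1 = paste0("P", 1:4)))
#' @export
hypergeomEnrich <- function(foreground, background, sets, alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(background) < 2L)
    stop("background must contain at least 2 features")
  stray <- setdiff(foreground, background)
  if (length(stray))
    stop("foreground feature(s) outside the background: ",
         paste(head(stray, 10L), collapse = ", "),
         if (length(stray) > 10L) ", ...")
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a non-empty named list")
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), background)
    K <- length(members)
    k <- length(intersect(foreground, members))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$enriched <- out$p_adj < alpha
  out[order(out$p_adj, out$p, out$term), , drop = FALSE]
}
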