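#' @include quant.R
NULL

#' PISA stability shift for one protein
#'
#' The PISA (proteome integral solubility alteration) readout is the pooled
#' soluble-fraction abundance over a temperature gradient; ligand
#' engagement shifts the pooled abundance between treated and vehicle
#' arms. The shift is the log2 ratio of replicate means; significance comes
#' from a two-sided Welch t-test on the log2 abundances.
#'
#' @param treated,vehicle numeric vectors of replicate pooled soluble
#'   abundances (at least 2 per arm, positive means).
#' @return named numeric vector `c(log2fc, p)`. When both arms have zero
#'   variance, `p` is 1 for equal means and 0 otherwise, by convention.
#' @examples
#' pisaShift(c(4, 4, 4), c(1, 1, 1))  # log2fc = 2
#' @export
pisaShift <- function(treated, vehicle) {
  treated <- treated[is.finite(treated)]
  vehicle <- vehicle[is.finite(vehicle)]
  if (length(treated) < 2L || length(vehicle) < 2L)
    stop("need at least 2 replicates per arm")
  mt <- mean(treated); mv <- mean(vehicle)
  if (mt <= 0 || mv <= 0)
    stop("replicate means must be positive")
  l2 <- log2(mt / mv)
  lt <- log2(treated); lv <- log2(vehicle)
  if (sd(lt) == 0 && sd(lv) == 0) {
    p <- if (isTRUE(all.equal(mt, mv))) 1 else 0
    if (p == 1) l2 <- 0
    return(c(log2fc = l2, p = p))
  }
  p <- t.test(lt, lv, var.equal = FALSE)$p.value
  c(log2fc = l2, p = p)
}

#' Classify cell/lysate thermal engagement
#'
#' Combines matched cell-based and lysate-based PISA results into an
#' engagement class. A shift is significant in an arm when `p < alpha` and
#' `|log2fc| > min_abs_log2fc`. `direct` engagement requires significance
#' in both arms with concordant sign (the hallmark of physical ligand
#' binding); `cell-context` is significant in the live-cell arm only
#' (cellular-context-dependent, e.g. downstream of signaling);
#' `lysate-only` the converse; everything else (including the rare
#' both-arm significant discordant case, whose direction is reported as
#' `"mixed"`) is `none`.
#'
#' @param log2fc_cell,p_cell,log2fc_lysate,p_lysate numeric vectors
#'   (recycled to a common length).
#' @param alpha significance level per arm (default 0.05).
#' @param min_abs_log2fc absolute shift floor (default 0.2).
#' @return `data.frame` with `engagement` in
#'   `{direct, cell-context, lysate-only, none}` and `direction` in
#'   `{stabilized, destabilized, mixed, none}` (positive shift =
#'   stabilized).
#' @export
classifyEngagement <- function(log2fc_cell, p_cell, log2fc_lysate, p_lysate,
                               alpha = 0.05, min_abs_log2fc = 0.2) {
  n <- max(length(log2fc_cell), length(p_cell), length(log2fc_lysate),
           length(p_lysate))
  fc_c <- rep_len(log2fc_cell, n); p_c <- rep_len(p_cell, n)
  fc_l <- rep_len(log2fc_lysate, n); p_l <- rep_len(p_lysate, n)
  sig_c <- !is.na(p_c) & !is.na(fc_c) & p_c < alpha &
    abs(fc_c) > min_abs_log2fc
  sig_l <- !is.na(p_l) & !is.na(fc_l) & p_l < alpha &
    abs(fc_l) > min_abs_log2fc
  concordant <- sign(fc_c) == sign(fc_l)
  engagement <- rep("none", n)
  engagement[sig_c & !sig_l] <- "cell-context"
  engagement[!sig_c & sig_l] <- "lysate-only"
  engagement[sig_c & sig_l & concordant] <- "direct"
  direction <- rep("none", n)
  direction[engagement == "direct" & fc_c > 0] <- "stabilized"
  direction[engagement == "direct" & fc_c < 0] <- "destabilized"
  direction[engagement == "cell-context"] <-
    ifelse(fc_c[engagement == "cell-context"] > 0, "stabilized",
           "destabilized")
  direction[engagement == "lysate-only"] <-
    ifelse(fc_l[engagement == "lysate-only"] > 0, "stabilized",
           "destabilized")
  direction[sig_c & sig_l & !concordant] <- "mixed"
  data.frame(engagement = engagement, direction = direction,
             stringsAsFactors = FALSE)
}

#' Analyze a matched cell/lysate PISA experiment
#'
#' Computes per-protein stability shifts and Welch p-values in each arm
#' (see [pisaShift()]) and classifies engagement
#' (see [classifyEngagement()]). Proteins missing from either arm are
#' reported with `engagement = "unclassified"`.
#'
#' @param cell,lysate long `data.frame`s with columns `protein`, `condition`
#'   (`"treated"` or `"vehicle"`), `replicate`, `abundance` for the
#'   live-cell and lysate arms.
#' @param alpha,min_abs_log2fc significance rule, see [classifyEngagement()].
#' @param adjust apply Benjamini-Hochberg adjustment to the per-arm
#'   p-values before classification (off by default: PISA calls are
#'   conventionally reported per protein).
#' @return `data.frame`: `protein`, `log2fc_cell`, `p_cell`,
#'   `log2fc_lysate`, `p_lysate`, `engagement`, `direction`.
#' @export
pisaAnalyze <- function(cell, lysate, alpha = 0.05, min_abs_log2fc = 0.2,
                        adjust = FALSE) {
  shift_arm <- function(tab) {
    need <- c("protein", "condition", "replicate", "abundance")
    if (!all(need %in% colnames(tab)))
      stop("PISA table must have columns: ", paste(need, collapse = ", "))
    prots <- unique(tab$protein)
    res <- vapply(prots, function(p) {
      tr <- tab$abundance[tab$protein == p & tab$condition == "treated"]
      ve <- tab$abundance[tab$protein == p & tab$condition == "vehicle"]
      if (length(tr) < 2L || length(ve) < 2L)
        return(c(NA_real_, NA_real_))
      pisaShift(tr, ve)
    }, numeric(2))
    data.frame(protein = prots, log2fc = res[1L, ], p = res[2L, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  sc <- shift_arm(cell)
  sl <- shift_arm(lysate)
  prots <- union(sc$protein, sl$protein)
  ic <- match(prots, sc$protein); il <- match(prots, sl$protein)
  out <- data.frame(protein = prots,
                    log2fc_cell = sc$log2fc[ic], p_cell = sc$p[ic],
                    log2fc_lysate = sl$log2fc[il], p_lysate = sl$p[il],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust) {
    out$p_cell <- bhAdjust(out$p_cell)
    out$p_lysate <- bhAdjust(out$p_lysate)
  }
  both <- !is.na(out$p_cell) & !is.na(out$p_lysate)
  out$engagement <- "unclassified"
  out$direction <- NA_character_
  if (any(both)) {
    cls <- classifyEngagement(out$log2fc_cell[both], out$p_cell[both],
                              out$log2fc_lysate[both], out$p_lysate[both],
                              alpha = alpha,
                              min_abs_log2fc = min_abs_log2fc)
    out$engagement[both] <- cls$engagement
    out$direction[both] <- cls$direction
  }
  out
}

#' Simulate pooled PISA abundances from a two-state melting model
#'
#' Models each protein's soluble fraction as a two-state sigmoid of
#' temperature, \eqn{f(T) = 1 / (1 + \exp((T - T_m)/k)))}, pools the
#' soluble fraction over the temperature gradient by averaging (the PISA
#' integral readout), and applies log-normal replicate noise. Treatment
#' shifts the melting midpoint by `shift` degrees for the treated arm, so a
#' positive shift (stabilization) increases the pooled soluble abundance.
#'
#' @param tm melting midpoint in degrees C (should lie within or near the
#'   gradient window for the readout to be sensitive).
#' @param shift treatment-induced midpoint shift in degrees C.
#' @param slope sigmoid slope parameter k in degrees C (> 0).
#' @param temps temperature gradient (default 10 points, 48-58 degrees C).
#' @param baseline expected soluble abundance at full solubility.
#' @param cv replicate coefficient of variation of the pooled abundance.
#' @param n_replicates replicates per arm (default 3).
#' @return list with numeric vectors `treated` and `vehicle` of length
#'   `n_replicates`, plus `expected_treated` and `expected_vehicle` pooled
#'   fractions (noise-free).
#' @export
simulateMelting <- function(tm, shift = 0, slope = 1,
                            temps = seq(48, 58, length.out = 10),
                            baseline = 1e5, cv = 0.05, n_replicates = 3L) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be positive")
  pooled <- function(midpoint)
    mean(1 / (1 + exp((temps - midpoint) / slope)))
  fv <- pooled(tm)
  ft <- pooled(tm + shift)
  sigma <- sqrt(log(1 + cv^2))
  list(treated = baseline * ft * exp(rnorm(n_replicates, 0, sigma)),
       vehicle = baseline * fv * exp(rnorm(n_replicates, 0, sigma)),
       expected_treated = ft, expected_vehicle = fv)
}
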