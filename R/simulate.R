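#' @include pisa.R
NULL

#' Configuration for a synthetic HDACi perturbation experiment
#'
#' Captures the study design being emulated: a panel of cell lines treated
#' with a set of drugs (the last `n_outgroup` drugs are a non-HDACi
#' outgroup carrying no planted HDACi effect) plus matched DMSO vehicle, in
#' duplicate for proteome and phosphoproteome layers; triplicate PISA in
#' matched cell and lysate arms over a 48-58 degree gradient. Planted
#' ground truth comprises universal effectors (shifted in every HDACi
#' condition group), divergent effectors (shifted in a small subset of cell
#' lines, the heterogeneity axis of the design), an anchor-correlated
#' protein module driven by a shared latent factor, one kinase whose
#' substrates shift with a per-group activity, a nine-group concordance
#' panel, and PISA engagement targets.
#'
#' Replicate noise is log-normal: per-replicate log2 abundance = baseline +
#' condition effect + N(0, sigma) with sigma = sqrt(ln(1 + cv^2)) / ln 2 so
#' that the linear-scale CV approximates `replicate_cv`.
#'
#' @param n_cell_lines,n_drugs,n_outgroup,n_replicates design counts; the
#'   defaults are 5 cell lines, 6 HDACi plus 1 outgroup drug, duplicates.
#' @param n_proteins,n_phosphosites feature counts.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale location/scale of
#'   feature baselines (reporter-intensity-like).
#' @param replicate_cv target linear-scale replicate CV (default 0.05).
#' @param effect_size_log2 planted effector magnitude (default 2).
#' @param n_universal,n_divergent,n_null planted effector counts; `n_null`
#'   defaults to the remaining proteins.
#' @param divergent_max_lines divergent effectors shift 1 to this many cell
#'   lines (default 2, keeping them within the cell-type-specific class).
#' @param anchor_module_size,anchor_latent_sd size of the anchor-correlated
#'   module (partners of the anchor protein) and the SD (log2) of the shared
#'   per-group latent term.
#' @param kinase_effect_log2,kinase_activity_sd mean and SD of the planted
#'   kinase's per-group activity, added to its substrates' log2 fold change.
#' @param n_kinase_substrates,n_decoy_kinases substrates of the planted
#'   kinase; decoy kinases receive random unshifted substrate sets.
#' @param n_concordance_genes size of the nine-group concordance panel
#'   (split evenly across the 9 groups).
#' @param n_pisa_proteins PISA panel size (the last proteins of the
#'   proteome).
#' @param pisa_n_temps,pisa_temp_min,pisa_temp_max,pisa_n_replicates PISA
#'   gradient design: 10 points from 48 to 58 degrees C, triplicate.
#' @param pisa_tm_mean,pisa_tm_sd,pisa_slope,pisa_shift_degC melting-curve
#'   parameters: midpoints near the gradient center, and the planted
#'   midpoint shift (degrees C) for engaged targets.
#' @param dropout_rate probability that an individual measurement is
#'   missing (simple random dropout; default 0).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @return validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_cell_lines = 5L, n_drugs = 7L, n_outgroup = 1L,
                      n_replicates = 2L, n_proteins = 2000L,
                      n_phosphosites = 500L, baseline_log2_mean = 16,
                      baseline_log2_sd = 2, replicate_cv = 0.05,
                      effect_size_log2 = 2, n_universal = 15L,
                      n_divergent = 100L, n_null = NULL,
                      divergent_max_lines = 2L, anchor_module_size = 20L,
                      anchor_latent_sd = 1.0, kinase_effect_log2 = 1.5,
                      kinase_activity_sd = 0.5, n_kinase_substrates = 20L,
                      n_decoy_kinases = 10L, n_concordance_genes = 900L,
                      n_pisa_proteins = 300L, pisa_n_temps = 10L,
                      pisa_temp_min = 48, pisa_temp_max = 58,
                      pisa_n_replicates = 3L, pisa_tm_mean = 53,
                      pisa_tm_sd = 1, pisa_slope = 1, pisa_shift_degC = 2,
                      dropout_rate = 0, seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_drugs = as.integer(n_drugs),
              n_outgroup = as.integer(n_outgroup),
              n_replicates = as.integer(n_replicates),
              n_proteins = as.integer(n_proteins),
              n_phosphosites = as.integer(n_phosphosites),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              replicate_cv = replicate_cv,
              effect_size_log2 = effect_size_log2,
              n_universal = as.integer(n_universal),
              n_divergent = as.integer(n_divergent),
              divergent_max_lines = as.integer(divergent_max_lines),
              anchor_module_size = as.integer(anchor_module_size),
              anchor_latent_sd = anchor_latent_sd,
              kinase_effect_log2 = kinase_effect_log2,
              kinase_activity_sd = kinase_activity_sd,
              n_kinase_substrates = as.integer(n_kinase_substrates),
              n_decoy_kinases = as.integer(n_decoy_kinases),
              n_concordance_genes = as.integer(n_concordance_genes),
              n_pisa_proteins = as.integer(n_pisa_proteins),
              pisa_n_temps = as.integer(pisa_n_temps),
              pisa_temp_min = pisa_temp_min, pisa_temp_max = pisa_temp_max,
              pisa_n_replicates = as.integer(pisa_n_replicates),
              pisa_tm_mean = pisa_tm_mean, pisa_tm_sd = pisa_tm_sd,
              pisa_slope = pisa_slope, pisa_shift_degC = pisa_shift_degC,
              dropout_rate = dropout_rate, seed = as.integer(seed))

  chk <- function(cond, field, what) {
    if (!cond) stop("invalid SimConfig field '", field, "': ", what,
                    call. = FALSE)
  }
  for (f in c("n_cell_lines", "n_drugs", "n_replicates", "n_proteins",
              "n_phosphosites", "pisa_n_temps", "pisa_n_replicates",
              "divergent_max_lines"))
    chk(cfg[[f]] >= 1L, f, "must be at least 1")
  for (f in c("n_universal", "n_divergent", "anchor_module_size",
              "n_outgroup", "n_decoy_kinases", "n_kinase_substrates",
              "n_concordance_genes", "n_pisa_proteins"))
    chk(cfg[[f]] >= 0L, f, "must be non-negative")
  chk(cfg$replicate_cv > 0, "replicate_cv", "must be positive")
  chk(cfg$dropout_rate >= 0 && cfg$dropout_rate < 1, "dropout_rate",
      "must lie in [0, 1)")
  chk(cfg$n_outgroup < cfg$n_drugs, "n_outgroup",
      "must leave at least one HDACi drug")
  chk(cfg$divergent_max_lines <= cfg$n_cell_lines, "divergent_max_lines",
      "cannot exceed n_cell_lines")
  chk(cfg$pisa_temp_max > cfg$pisa_temp_min, "pisa_temp_max",
      "must exceed pisa_temp_min")
  chk(cfg$pisa_slope > 0, "pisa_slope", "must be positive")
  n_anchor <- if (cfg$anchor_module_size > 0L)
    cfg$anchor_module_size + 1L else 0L
  planted <- cfg$n_universal + cfg$n_divergent + n_anchor
  chk(planted <= cfg$n_proteins, "n_proteins",
      "fewer proteins than planted effectors + anchor module")
  if (is.null(n_null)) {
    cfg$n_null <- cfg$n_proteins - planted
  } else {
    cfg$n_null <- as.integer(n_null)
    chk(cfg$n_universal + cfg$n_divergent + cfg$n_null <= cfg$n_proteins,
        "n_null", "effector counts exceed n_proteins")
  }
  chk(cfg$n_pisa_proteins <= cfg$n_proteins, "n_pisa_proteins",
      "cannot exceed n_proteins")
  chk(cfg$n_kinase_substrates <= cfg$n_phosphosites, "n_kinase_substrates",
      "cannot exceed n_phosphosites")
  class(cfg) <- "SimConfig"
  cfg
}

# log2-scale replicate noise SD for a target linear CV
.log2SigmaFromCV <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Generate a seeded synthetic multi-omic perturbation experiment
#'
#' Draws a full experiment under a [simConfig()]: proteome and
#' phosphoproteome [QuantMatrix-class] objects (sample columns named
#' `<cellline>_<drug>_rep<k>`, with DMSO vehicle columns carrying no
#' planted effect), a transcript effect table and matched per-gene protein
#' fold changes for the concordance panel, triplicate cell and lysate PISA
#' tables, and the `SyntheticTruth` listing every planted assignment.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `protein`, `phospho` ([QuantMatrix-class]),
#'   `transcripts` (`data.frame`: `gene`, `normalized_effect`, `fdr`),
#'   `concordance_protein_fc` (named numeric), `pisa_cell`, `pisa_lysate`
#'   (long `data.frame`s for [pisaAnalyze()]), `kinase_map`,
#'   `motif_scores`, `hdaci_groups` (character), `truth` (class
#'   `"SyntheticTruth"`), `config`.
#' @export
simulateExperiment <- function(config) {
  if (!inherits(config, "SimConfig"))
    stop("config must be created by simConfig()")
  cfg <- config
  set.seed(cfg$seed)
  sigma <- .log2SigmaFromCV(cfg$replicate_cv)

  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  hdaci_drugs <- drugs[seq_len(cfg$n_drugs - cfg$n_outgroup)]

  # treated condition groups, line-major
  grp <- expand.grid(drug = drugs, cell_line = lines,
                     stringsAsFactors = FALSE)[, c(2L, 1L)]
  grp$group <- .groupId(grp$cell_line, grp$drug)
  grp$hdaci <- grp$drug %in% hdaci_drugs
  n_grp <- nrow(grp)

  # sample columns: all drugs then DMSO within each line, reps innermost
  col_meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          drug = c(drugs, VEHICLE), cell_line = lines,
                          stringsAsFactors = FALSE)[, c(3L, 2L, 1L)]
  col_meta$sample <- sprintf("%s_%s_rep%d", col_meta$cell_line,
                             col_meta$drug, col_meta$replicate)
  grp_of_col <- match(.groupId(col_meta$cell_line, col_meta$drug),
                      grp$group)  # NA for vehicle columns

  ## ---- protein layer -------------------------------------------------
  wid <- max(4L, nchar(as.character(cfg$n_proteins)))
  prot_ids <- sprintf(paste0("P%0", wid, "d"), seq_len(cfg$n_proteins))
  idx <- 0L
  take <- function(n) {
    out <- if (n > 0L) prot_ids[idx + seq_len(n)] else character(0)
    idx <<- idx + n
    out
  }
  universal_ids <- take(cfg$n_universal)
  divergent_ids <- take(cfg$n_divergent)
  anchor_id <- if (cfg$anchor_module_size > 0L) take(1L) else NA_character_
  partner_ids <- take(cfg$anchor_module_size)

  effect <- matrix(0, cfg$n_proteins, n_grp,
                   dimnames = list(prot_ids, grp$group))
  hd <- grp$hdaci
  universal_sign <- setNames(sample(c(-1, 1), cfg$n_universal,
                                    replace = TRUE), universal_ids)
  effect[universal_ids, hd] <- universal_sign * cfg$effect_size_log2

  divergent_lines <- list()
  divergent_sign <- setNames(sample(c(-1, 1), cfg$n_divergent,
                                    replace = TRUE), divergent_ids)
  for (id in divergent_ids) {
    nl <- sample.int(cfg$divergent_max_lines, 1L)
    dl <- sample(lines, nl)
    divergent_lines[[id]] <- dl
    effect[id, hd & grp$cell_line %in% dl] <-
      divergent_sign[[id]] * cfg$effect_size_log2
  }

  anchor_latent <- setNames(rep(0, n_grp), grp$group)
  if (!is.na(anchor_id)) {
    anchor_latent[hd] <- rnorm(sum(hd), 0, cfg$anchor_latent_sd)
    effect[c(anchor_id, partner_ids), ] <-
      matrix(anchor_latent, cfg$anchor_module_size + 1L, n_grp,
             byrow = TRUE)
  }

  # planted kinase: per-group activity added to its substrates (phospho
  # layer) and, attenuated, to the kinase's own protein abundance
  kin_ids <- sprintf("KIN%02d", seq_len(1L + cfg$n_decoy_kinases))
  kin_activity <- setNames(rep(0, n_grp), grp$group)
  kin_activity[hd] <- rnorm(sum(hd), cfg$kinase_effect_log2,
                            cfg$kinase_activity_sd)
  kin_effect <- matrix(0, length(kin_ids), n_grp,
                       dimnames = list(kin_ids, grp$group))
  kin_effect[1L, ] <- 0.5 * kin_activity

  feat_ids <- c(prot_ids, kin_ids)
  all_effect <- rbind(effect, kin_effect)
  baseline <- rnorm(length(feat_ids), cfg$baseline_log2_mean,
                    cfg$baseline_log2_sd)
  draw_matrix <- function(eff, base) {
    nf <- nrow(eff)
    e_col <- ifelse(is.na(grp_of_col), 0L, grp_of_col)
    cond_eff <- cbind(eff, 0)[, ifelse(e_col == 0L, ncol(eff) + 1L, e_col),
                              drop = FALSE]
    l2 <- base + cond_eff +
      matrix(rnorm(nf * nrow(col_meta), 0, sigma), nf, nrow(col_meta))
    m <- 2^l2
    dimnames(m) <- list(rownames(eff), col_meta$sample)
    if (cfg$dropout_rate > 0)
      m[matrix(runif(length(m)) < cfg$dropout_rate, nrow(m))] <- NA_real_
    m
  }
  prot_mat <- draw_matrix(all_effect, baseline)
  protein <- QuantMatrix(prot_mat, col_meta)

  ## ---- phospho layer -------------------------------------------------
  swid <- max(3L, nchar(as.character(cfg$n_phosphosites)))
  site_prot <- sample(prot_ids, cfg$n_phosphosites, replace = TRUE)
  site_ids <- sprintf(paste0("%s_S%0", swid, "d"), site_prot,
                      seq_len(cfg$n_phosphosites))
  substrate_ids <- site_ids[seq_len(cfg$n_kinase_substrates)]
  ph_effect <- matrix(0, cfg$n_phosphosites, n_grp,
                      dimnames = list(site_ids, grp$group))
  if (cfg$n_kinase_substrates > 0L)
    ph_effect[substrate_ids, ] <-
      matrix(kin_activity, cfg$n_kinase_substrates, n_grp, byrow = TRUE)
  ph_baseline <- rnorm(cfg$n_phosphosites, cfg$baseline_log2_mean,
                       cfg$baseline_log2_sd)
  phospho <- QuantMatrix(draw_matrix(ph_effect, ph_baseline), col_meta)

  # kinase-substrate map: planted kinase plus decoys on unshifted sites
  kinase_map <- list()
  kinase_map[[kin_ids[1L]]] <- substrate_ids
  pool <- setdiff(site_ids, substrate_ids)
  for (k in kin_ids[-1L]) {
    kinase_map[[k]] <- sample(pool, min(15L, length(pool)))
  }
  motif_scores <- setNames(c(1.8, runif(cfg$n_decoy_kinases, -0.5, 0.95)),
                           kin_ids)

  ## ---- concordance panel --------------------------------------------
  ng <- cfg$n_concordance_genes
  gwid <- max(4L, nchar(as.character(ng)))
  genes <- sprintf(paste0("G%0", gwid, "d"), seq_len(ng))
  conc_group <- setNames(sample(rep_len(1:9, ng)), genes)
  tstate <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)[conc_group]  # 1 up, 2 none, 3 down
  pstate <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)[conc_group]  # 1 down, 2 none, 3 up
  prot_fc <- numeric(ng)
  prot_fc[pstate == 1] <- -runif(sum(pstate == 1), 1.2, 3)
  prot_fc[pstate == 2] <- runif(sum(pstate == 2), -0.8, 0.8)
  prot_fc[pstate == 3] <- runif(sum(pstate == 3), 1.2, 3)
  tr_eff <- numeric(ng)
  tr_eff[tstate == 1] <- runif(sum(tstate == 1), 0.06, 0.2)
  tr_eff[tstate == 2] <- runif(sum(tstate == 2), -0.045, 0.045)
  tr_eff[tstate == 3] <- -runif(sum(tstate == 3), 0.06, 0.2)
  fdr <- ifelse(tstate == 2, runif(ng), runif(ng, 0, 0.049))
  transcripts <- data.frame(gene = genes, normalized_effect = tr_eff,
                            fdr = fdr, row.names = NULL,
                            stringsAsFactors = FALSE)
  concordance_protein_fc <- setNames(prot_fc, genes)

  ## ---- PISA ----------------------------------------------------------
  np <- cfg$n_pisa_proteins
  pisa_ids <- if (np > 0L) prot_ids[(cfg$n_proteins - np + 1L):
                                      cfg$n_proteins] else character(0)
  # planted engagement classes; remaining proteins unengaged
  n_ds <- min(15L, np); n_dd <- min(10L, max(0L, np - n_ds))
  n_co <- min(10L, max(0L, np - n_ds - n_dd))
  n_lo <- min(10L, max(0L, np - n_ds - n_dd - n_co))
  cls <- rep("none", np)
  cls[seq_len(n_ds)] <- "direct_stabilized"
  cls[n_ds + seq_len(n_dd)] <- "direct_destabilized"
  cls[n_ds + n_dd + seq_len(n_co)] <- "cell_only"
  cls[n_ds + n_dd + n_co + seq_len(n_lo)] <- "lysate_only"
  shift_of <- function(cls, arm) {
    s <- cfg$pisa_shift_degC
    vapply(cls, function(cl) switch(
      cl,
      direct_stabilized = s,
      direct_destabilized = -s,
      cell_only = if (arm == "cell") s else 0,
      lysate_only = if (arm == "lysate") s else 0,
      0), numeric(1))
  }
  temps <- seq(cfg$pisa_temp_min, cfg$pisa_temp_max,
               length.out = cfg$pisa_n_temps)
  tm <- rnorm(np, cfg$pisa_tm_mean, cfg$pisa_tm_sd)
  pisa_base <- 2^rnorm(np, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  draw_arm <- function(arm) {
    sh <- shift_of(cls, arm)
    rows <- lapply(seq_len(np), function(i) {
      sm <- simulateMelting(tm[i], shift = sh[i], slope = cfg$pisa_slope,
                            temps = temps, baseline = pisa_base[i],
                            cv = cfg$replicate_cv,
                            n_replicates = cfg$pisa_n_replicates)
      data.frame(protein = pisa_ids[i], arm = arm,
                 condition = rep(c("treated", "vehicle"),
                                 each = cfg$pisa_n_replicates),
                 replicate = rep(seq_len(cfg$pisa_n_replicates), 2L),
                 abundance = c(sm$treated, sm$vehicle),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pisa_cell <- draw_arm("cell")
  pisa_lysate <- draw_arm("lysate")
  arm_class <- function(arm) {
    sh <- shift_of(cls, arm)
    ifelse(sh > 0, "stabilized", ifelse(sh < 0, "destabilized", "none"))
  }
  pisa_truth <- data.frame(protein = pisa_ids, cell = arm_class("cell"),
                           lysate = arm_class("lysate"),
                           direct = grepl("^direct", cls),
                           row.names = NULL, stringsAsFactors = FALSE)

  ## ---- truth ---------------------------------------------------------
  # truth labels cover every simulated proteome feature; anchor-module and
  # kinase proteins are their own classes (not effector assignments)
  effector_class <- setNames(rep("null", length(feat_ids)), feat_ids)
  effector_class[universal_ids] <- "universal"
  effector_class[divergent_ids] <- "divergent"
  effector_class[kin_ids] <- "kinase"
  if (!is.na(anchor_id))
    effector_class[c(anchor_id, partner_ids)] <- "anchor"
  truth <- structure(list(
    effector_class = effector_class,
    universal_sign = universal_sign,
    divergent_lines = divergent_lines,
    divergent_sign = divergent_sign,
    anchor_id = anchor_id,
    anchor_members = partner_ids,
    anchor_latent = anchor_latent,
    kinase_truth = kinase_map[1L],
    kinase_activity = kin_activity,
    concordance_group = conc_group,
    pisa_truth = pisa_truth,
    effect_matrix = all_effect),
    class = "SyntheticTruth")

  list(protein = protein, phospho = phospho, transcripts = transcripts,
       concordance_protein_fc = concordance_protein_fc,
       pisa_cell = pisa_cell, pisa_lysate = pisa_lysate,
       kinase_map = kinase_map, motif_scores = motif_scores,
       hdaci_groups = grp$group[grp$hdaci], groups = grp,
       truth = truth, config = cfg)
}

#' Score pipeline predictions against planted ground truth
#'
#' Computes precision and recall per planted category. Predictions are a
#' named list of feature-id character vectors with any of the elements
#' `universal`, `divergent` (features called cell-type-specific), `anchor`
#' (anchor-screen partners), `kinase`, and `pisa_direct`. For the effector
#' categories (`universal`, `divergent`) the scoring universe is the
#' proteins planted as universal, divergent or null; anchor-module members
#' are excluded because their planted regulation follows the latent
#' co-regulation factor rather than an effector assignment.
#'
#' By stated convention an empty prediction set has precision 1.0 with
#' `precision_undefined = TRUE`, keeping recovery reports total.
#'
#' @param predictions named list of character vectors (see above).
#' @param truth the `SyntheticTruth` from [simulateExperiment()].
#' @return `data.frame`: `category`, `n_truth`, `n_predicted`,
#'   `true_positives`, `precision`, `recall`, `precision_undefined`.
#' @export
truthRecoveryReport <- function(predictions, truth) {
  if (!inherits(truth, "SyntheticTruth"))
    stop("truth must be a SyntheticTruth")
  ec <- truth$effector_class
  task_universe <- names(ec)[ec %in% c("universal", "divergent", "null")]
  spec <- list(
    universal = list(truth = names(ec)[ec == "universal"],
                     known = names(ec), universe = task_universe),
    divergent = list(truth = names(ec)[ec == "divergent"],
                     known = names(ec), universe = task_universe),
    anchor = list(truth = truth$anchor_members,
                  known = names(ec), universe = names(ec)),
    kinase = list(truth = names(truth$kinase_truth), known = NULL,
                  universe = NULL),
    pisa_direct = list(
      truth = truth$pisa_truth$protein[truth$pisa_truth$direct],
      known = truth$pisa_truth$protein,
      universe = truth$pisa_truth$protein))
  cats <- intersect(names(spec), names(predictions))
  if (!length(cats))
    stop("no recognized prediction categories supplied")
  rows <- lapply(cats, function(cat) {
    pred <- unique(predictions[[cat]])
    tru <- spec[[cat]]$truth
    known <- spec[[cat]]$known
    if (!is.null(known)) {
      missing_ids <- setdiff(pred, known)
      if (length(missing_ids))
        stop("prediction(s) for category '", cat,
             "' absent from the truth: ",
             paste(head(missing_ids, 10L), collapse = ", "))
    }
    uni <- spec[[cat]]$universe
    if (!is.null(uni))
      pred <- intersect(pred, uni)
    tp <- length(intersect(pred, tru))
    undef <- length(pred) == 0L
    precision <- if (undef) 1.0 else tp / length(pred)
    recall <- if (length(tru) == 0L) 1.0 else tp / length(tru)
    data.frame(category = cat, n_truth = length(tru),
               n_predicted = length(pred), true_positives = tp,
               precision = precision, recall = recall,
               precision_undefined = undef,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
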