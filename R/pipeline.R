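#' @include simulate.R io.R regulation.R coregulation.R kinase.R
#' @include concordance.R enrichment.R
NULL

#' Analysis configuration with the conventional thresholds
#'
#' Collects every tunable threshold of the pipeline at its conventional
#' value: replicate CV ceiling 0.3; regulation at |log2FC| > 1; protein
#' co-regulation at signed r > 0.9 and phosphosite co-regulation at
#' |r| > 0.8 with at least 80% condition-group coverage; transcript
#' normalized-effect threshold 0.05; enrichment and PISA significance at
#' 0.05; consistency `specific` cutoff at fewer than 14 regulated groups;
#' kinase candidates at motif score > 1 and |r| > 0.8 with coverage in at
#' least 28 samples.
#'
#' @param cv_max replicate CV ceiling.
#' @param fc_threshold regulation threshold (log2).
#' @param coreg_r protein anchor-screen correlation threshold (signed).
#' @param phospho_r phosphosite screen threshold (absolute).
#' @param coverage_min screen coverage fraction.
#' @param transcript_effect transcript normalized-effect threshold.
#' @param alpha significance level (enrichment, PISA).
#' @param specific_cutoff consistency cutoff (exclusive).
#' @param motif_score_min kinase-candidate motif-score threshold.
#' @param kinase_coverage_min minimum groups a kinase must be quantified in.
#' @param pisa_min_abs_log2fc PISA absolute shift floor.
#' @param require_full_coverage stricter universality rule, see
#'   [classifyConsistency()].
#' @param seed RNG seed recorded with every run.
#' @return validated list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(cv_max = 0.3, fc_threshold = 1.0, coreg_r = 0.9,
                           phospho_r = 0.8, coverage_min = 0.8,
                           transcript_effect = 0.05, alpha = 0.05,
                           specific_cutoff = 14L, motif_score_min = 1.0,
                           kinase_coverage_min = 28L,
                           pisa_min_abs_log2fc = 0.2,
                           require_full_coverage = TRUE, seed = 1L) {
  cfg <- list(cv_max = cv_max, fc_threshold = fc_threshold,
              coreg_r = coreg_r, phospho_r = phospho_r,
              coverage_min = coverage_min,
              transcript_effect = transcript_effect, alpha = alpha,
              specific_cutoff = as.integer(specific_cutoff),
              motif_score_min = motif_score_min,
              kinase_coverage_min = as.integer(kinase_coverage_min),
              pisa_min_abs_log2fc = pisa_min_abs_log2fc,
              require_full_coverage = isTRUE(require_full_coverage),
              seed = as.integer(seed))
  pos <- c("cv_max", "fc_threshold", "coreg_r", "phospho_r",
           "transcript_effect", "alpha", "specific_cutoff",
           "pisa_min_abs_log2fc")
  for (f in pos)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("invalid AnalysisConfig field '", f, "': must be positive",
           call. = FALSE)
  for (f in c("coverage_min", "alpha"))
    if (cfg[[f]] > 1)
      stop("invalid AnalysisConfig field '", f, "': must lie in (0, 1]",
           call. = FALSE)
  if (cfg$coverage_min <= 0)
    stop("invalid AnalysisConfig field 'coverage_min': must lie in (0, 1]",
         call. = FALSE)
  class(cfg) <- "AnalysisConfig"
  cfg
}

.stage <- function(name, expr, verbose) {
  res <- tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  res
}

.log_stage <- function(verbose, ...) if (verbose) message("[pipeline] ", ...)

#' Run the full perturbation-analysis pipeline
#'
#' Ties the stages together: quantification (column normalization,
#' fold-change table with CV filtering), regulation calls and waterfall
#' counts, cross-group consistency classification over the HDACi groups,
#' anchor co-regulation screening, per-group KSEA, transcript-protein
#' concordance, PISA engagement calls, and over-representation analysis of
#' the regulated set. Inputs are either a [simConfig()] (synthetic mode,
#' with a truth-recovery report appended) or externally supplied objects.
#'
#' @param config an [analysisConfig()].
#' @param sim a [simConfig()]; when given, all inputs are simulated and
#'   scored against the planted truth.
#' @param protein,phospho [QuantMatrix-class] inputs (external mode).
#' @param transcripts transcript effect table (`gene`, `normalized_effect`,
#'   `fdr`), optional.
#' @param protein_fc_for_transcripts named numeric vector of per-gene
#'   protein log2 fold changes paired with `transcripts` (external mode).
#' @param pisa_cell,pisa_lysate long PISA tables (see [pisaAnalyze()]),
#'   optional.
#' @param kinase_map,motif_scores kinase-substrate map and motif scores,
#'   optional.
#' @param gene_sets named list of annotation sets for enrichment, optional.
#' @param anchors anchor feature ids for the co-regulation screen; in
#'   synthetic mode defaults to the planted anchor.
#' @param hdaci_groups condition groups over which consistency is assessed;
#'   in synthetic mode defaults to the simulated HDACi groups, otherwise to
#'   all groups.
#' @param out_dir when non-`NULL`, every stage output is written there as
#'   TSV together with a JSON echo of both configs and the seed.
#' @param verbose log one line per stage with feature counts.
#' @return list of stage outputs (`foldchange`, `calls`, `waterfall`,
#'   `consistency`, `anchor_edges`, `ksea`, `concordance`, `pisa`,
#'   `enrichment`, `replicate_correlation`, and in synthetic mode
#'   `recovery` plus the simulation `truth`).
#' @export
runPipeline <- function(config = analysisConfig(), sim = NULL,
                        protein = NULL, phospho = NULL, transcripts = NULL,
                        protein_fc_for_transcripts = NULL,
                        pisa_cell = NULL, pisa_lysate = NULL,
                        kinase_map = NULL, motif_scores = NULL,
                        gene_sets = NULL, anchors = NULL,
                        hdaci_groups = NULL, out_dir = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(config, "AnalysisConfig"))
  truth <- NULL
  if (!is.null(sim)) {
    simdata <- .stage("simulate", simulateExperiment(sim), verbose)
    .log_stage(verbose, "simulate: ", nrow(simdata$protein), " proteins, ",
               nrow(simdata$phospho), " phosphosites")
    protein <- simdata$protein
    phospho <- simdata$phospho
    transcripts <- simdata$transcripts
    protein_fc_for_transcripts <- simdata$concordance_protein_fc
    pisa_cell <- simdata$pisa_cell
    pisa_lysate <- simdata$pisa_lysate
    kinase_map <- simdata$kinase_map
    motif_scores <- simdata$motif_scores
    truth <- simdata$truth
    if (is.null(anchors) && !is.na(simdata$truth$anchor_id))
      anchors <- simdata$truth$anchor_id
    if (is.null(hdaci_groups))
      hdaci_groups <- simdata$hdaci_groups
  }
  if (is.null(protein))
    stop("either 'sim' or a protein QuantMatrix is required")

  out <- list(config = config)

  protein <- .stage("normalize", normalizeColumns(protein), verbose)
  fct <- .stage("quantify",
                buildFoldChangeTable(protein, cv_max = config$cv_max),
                verbose)
  out$foldchange <- fct
  .log_stage(verbose, "quantify: ", sum(fcTable(fct)$quantified), " of ",
             nrow(fcTable(fct)), " feature-group pairs quantified")
  out$replicate_correlation <- .stage(
    "replicate-correlation", replicateCorrelation(protein), verbose)

  calls <- .stage("regulate",
                  callRegulated(fct, threshold = config$fc_threshold),
                  verbose)
  out$calls <- calls
  out$waterfall <- waterfallCounts(calls)
  .log_stage(verbose, "regulate: ", sum(calls$direction != "none"),
             " regulated events")

  if (is.null(hdaci_groups))
    hdaci_groups <- conditionGroups(fct)$group
  out$consistency <- .stage(
    "consistency",
    classifyConsistency(calls, hdaci_groups,
                        specific_cutoff = config$specific_cutoff,
                        require_full_coverage =
                          config$require_full_coverage),
    verbose)
  .log_stage(verbose, "consistency: ",
             sum(out$consistency$class == "universal"), " universal, ",
             sum(out$consistency$class == "specific"), " specific")

  if (!is.null(anchors)) {
    out$anchor_edges <- .stage(
      "coregulate",
      anchorScreen(fct, anchors, r_threshold = config$coreg_r,
                   coverage_min = config$coverage_min, signed = TRUE),
      verbose)
    .log_stage(verbose, "coregulate: ", nrow(out$anchor_edges), " edges")
  }

  if (!is.null(phospho) && !is.null(kinase_map)) {
    ph_fct <- .stage("quantify-phospho",
                     buildFoldChangeTable(normalizeColumns(phospho),
                                          cv_max = config$cv_max),
                     verbose)
    out$phospho_foldchange <- ph_fct
    out$ksea <- .stage("ksea",
                       kseaAll(ph_fct, kinase_map, groups = hdaci_groups),
                       verbose)
    .log_stage(verbose, "ksea: ",
               length(unique(out$ksea$kinase)), " kinases scored in ",
               length(unique(out$ksea$group)), " groups")
  }

  if (!is.null(transcripts) && !is.null(protein_fc_for_transcripts)) {
    out$concordance <- .stage(
      "concordance",
      mergeOmics(protein_fc_for_transcripts, transcripts,
                 p_thresh = config$fc_threshold,
                 t_thresh = config$transcript_effect),
      verbose)
    .log_stage(verbose, "concordance: ",
               nrow(out$concordance$records), " genes joined, r = ",
               round(out$concordance$r, 3))
  }

  if (!is.null(pisa_cell) && !is.null(pisa_lysate)) {
    out$pisa <- .stage(
      "pisa",
      pisaAnalyze(pisa_cell, pisa_lysate, alpha = config$alpha,
                  min_abs_log2fc = config$pisa_min_abs_log2fc),
      verbose)
    .log_stage(verbose, "pisa: ",
               sum(out$pisa$engagement == "direct"), " direct targets")
  }

  if (!is.null(gene_sets)) {
    m <- fcMatrix(fct)
    background <- rownames(m)[rowSums(!is.na(m)) > 0]
    foreground <- intersect(
      unique(calls$feature[calls$direction != "none"]), background)
    out$enrichment <- .stage(
      "enrich",
      hypergeomEnrich(foreground, background, gene_sets,
                      alpha = config$alpha),
      verbose)
    .log_stage(verbose, "enrich: ", sum(out$enrichment$enriched),
               " enriched terms")
  }

  if (!is.null(truth)) {
    preds <- extractPredictions(out, anchor = anchors[1L],
                                alpha = config$alpha)
    out$recovery <- .stage("recovery",
                           truthRecoveryReport(preds, truth), verbose)
    out$truth <- truth
  }

  if (!is.null(out_dir))
    .writePipelineOutputs(out, out_dir, sim)
  out
}

#' Extract prediction sets from pipeline outputs
#'
#' Collapses stage outputs into the named character-vector lists consumed
#' by [truthRecoveryReport()]: universal and specific consistency classes,
#' anchor-screen partners, kinases with BH-significant enrichment in more
#' than half of the scored condition groups, and PISA direct targets.
#'
#' @param out pipeline output list from [runPipeline()].
#' @param anchor anchor id whose partners are taken as the anchor
#'   predictions.
#' @param alpha significance level for the kinase calls.
#' @return named list of character vectors.
#' @export
extractPredictions <- function(out, anchor = NULL, alpha = 0.05) {
  preds <- list()
  if (!is.null(out$consistency)) {
    preds$universal <-
      out$consistency$feature[out$consistency$class == "universal"]
    preds$divergent <-
      out$consistency$feature[out$consistency$class == "specific"]
  }
  if (!is.null(out$anchor_edges) && !is.null(anchor))
    preds$anchor <-
      unique(out$anchor_edges$partner[out$anchor_edges$anchor == anchor])
  if (!is.null(out$ksea)) {
    ks <- out$ksea
    n_groups <- length(unique(ks$group))
    sig <- ks[ks$p_adj < alpha, , drop = FALSE]
    cnt <- table(sig$kinase)
    preds$kinase <- names(cnt)[cnt > n_groups / 2]
  }
  if (!is.null(out$pisa))
    preds$pisa_direct <- out$pisa$protein[out$pisa$engagement == "direct"]
  preds
}

.writePipelineOutputs <- function(out, out_dir, sim) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) .writeTSV(x, file.path(out_dir, name))
  w(fcTable(out$foldchange), "foldchange.tsv")
  w(out$calls, "regulation_calls.tsv")
  w(out$waterfall, "waterfall.tsv")
  w(out$consistency, "consistency.tsv")
  if (!is.null(out$anchor_edges)) w(out$anchor_edges, "anchor_edges.tsv")
  if (!is.null(out$ksea)) w(out$ksea, "ksea.tsv")
  if (!is.null(out$concordance))
    w(out$concordance$records, "concordance.tsv")
  if (!is.null(out$pisa)) w(out$pisa, "pisa.tsv")
  if (!is.null(out$enrichment)) w(out$enrichment, "enrichment.tsv")
  if (!is.null(out$recovery)) w(out$recovery, "recovery.tsv")
  meta <- list(analysis_config = unclass(out$config),
               sim_config = if (!is.null(sim)) unclass(sim),
               seed = out$config$seed,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}
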