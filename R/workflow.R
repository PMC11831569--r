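# End-to-end orchestration: simulate -> QC -> per-cell senescence
# scoring -> signature construction -> bulk scoring and stratification ->
# response classifier -> MTLR survival model -> CRISPR ranking -> hub
# intersection, with per-stage derived seeds and a serializable report.

PIPELINE_STAGES <- c("simulate", "qc", "score_cells", "build_fss",
                     "score_bulk", "ici", "mtlr", "crispr", "hub")

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic inputs; its
#'   `seed` is the pipeline master seed.
#' @param stages Enabled stages, a subset of
#'   `c("simulate", "qc", "score_cells", "build_fss", "score_bulk",
#'   "ici", "mtlr", "crispr", "hub")`.
#' @param min_genes,max_pct_mito QC thresholds (defaults 500 / 5).
#' @param min_logfc,min_pct Marker thresholds (defaults 0.25 / 0.1).
#' @param fdr FDR cutoff for senescence-correlated genes (default 0.05).
#' @param gmean_cutoff,min_support_frac Signature aggregation (defaults
#'   0.25 / 0.25).
#' @param top_fraction Screen top-ranked fraction (default 0.10).
#' @param train_frac Train split fraction (default 0.8).
#' @param cv_k,cv_repeats Classifier CV scheme (defaults 10 / 5).
#' @param n_features Prognostic features selected for the survival model
#'   (default 10).
#' @param signature Optional externally supplied signature gene vector
#'   (replaces the `build_fss` stage output for downstream stages).
#' @param out_dir Optional directory for tabular/JSON artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = PIPELINE_STAGES,
                            min_genes = 500, max_pct_mito = 5,
                            min_logfc = 0.25, min_pct = 0.1,
                            fdr = 0.05,
                            gmean_cutoff = 0.25, min_support_frac = 0.25,
                            top_fraction = 0.10,
                            train_frac = 0.8, cv_k = 10, cv_repeats = 5,
                            n_features = 10,
                            signature = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  stopifnot(min_genes >= 0, max_pct_mito >= 0, max_pct_mito <= 100,
            fdr > 0, fdr < 1, gmean_cutoff >= 0,
            min_support_frac >= 0, min_support_frac <= 1,
            top_fraction > 0, top_fraction <= 1,
            train_frac > 0, train_frac < 1, n_features >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Deterministic per-stage seed derived from the master seed.
stage_seed <- function(master, stage) {
  (as.integer(master) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic data with planted
#' ground truth and returns a run report. Identical configuration (and
#' master seed) yields an identical report.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`: per-stage outputs (`fss`,
#'   `bulk_scores`, `subgroups`, `ici`, `mtlr`, `ranking`, `enrichment`,
#'   `hub_genes`, ...), `counts`, `metrics`, `seeds`, and `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  on_ <- function(s) s %in% st
  need <- function(s, producer) {
    if (!on_(producer)) {
      stop(sprintf("stage '%s' requires output of disabled stage '%s'",
                   s, producer))
    }
  }
  master <- config$sim$seed
  seeds <- vapply(PIPELINE_STAGES, stage_seed, integer(1), master = master)
  rep <- list(seeds = seeds, counts = list(), metrics = list())

  sc <- bulk <- screens <- NULL
  if (on_("qc") || on_("score_cells") || on_("build_fss") ||
      on_("score_bulk") || on_("ici") || on_("mtlr") || on_("crispr")) {
    need("qc", "simulate")
  }
  if (on_("simulate")) {
    sc <- generate_sc_datasets(config$sim)
    bulk <- generate_bulk_cohorts(config$sim)
    screens <- generate_crispr_screens(config$sim)
    rep$truth <- list(sc = lapply(sc, `[[`, "truth"),
                      bulk = bulk$truth, screens = screens$truth)
    rep$counts$n_sc_datasets <- length(sc)
    rep$counts$n_bulk_samples <- nrow(bulk$cohort$expr)
    rep$counts$n_screens <- length(screens$screens)
  }

  if (on_("qc")) {
    sc <- lapply(sc, function(x) {
      x$dataset <- qc_filter_cells(x$dataset, config$min_genes,
                                   config$max_pct_mito)
      x
    })
    rep$counts$cells_kept <- sum(vapply(sc, function(x)
      ncol(x$dataset$counts), numeric(1)))
  }

  signature <- config$signature
  if (on_("build_fss")) {
    need("build_fss", "qc")
    sen_genes <- sc[[1]]$truth$senescence_set_genes
    sigs <- lapply(sc, function(x) {
      per_dataset_signature(x$dataset, sen_genes,
                            min_detect = config$min_pct, fdr = config$fdr,
                            min_logfc = config$min_logfc,
                            min_pct = config$min_pct)
    })
    fss <- aggregate_fss(lapply(sigs, `[[`, "fsn"),
                         cutoff = config$gmean_cutoff,
                         min_support_frac = config$min_support_frac)
    rep$per_dataset <- sigs
    rep$fss <- fss
    signature <- fss$members
    rep$counts$fss_size <- length(signature)
  }
  if (is.null(signature) &&
      (on_("score_bulk") || on_("ici") || on_("mtlr") || on_("crispr"))) {
    stop("no signature available: enable stage 'build_fss' or supply one in the config")
  }

  if (on_("score_bulk")) {
    need("score_bulk", "simulate")
    fss_scores <- score_cohort_fss(bulk$cohort, signature)
    cyto <- list(cytotoxic = bulk$truth$cytotoxic_genes)
    imm <- immune_scores(bulk$cohort, cyto)
    strat <- stratify_fss_tmb(fss_scores, bulk$cohort$clinical$tmb)
    rep$bulk_scores <- fss_scores
    rep$immune <- imm
    rep$subgroups <- strat
    rep$subgroup_tests <- compare_subgroups(imm, strat$combined)
    rep$metrics$fss_vs_burden_spearman <-
      cor(fss_scores, bulk$truth$S, method = "spearman")
  }

  expr_std <- NULL
  if (on_("ici") || on_("mtlr")) {
    need(if (on_("ici")) "ici" else "mtlr", "simulate")
    expr_std <- batch_standardize(bulk$cohort$expr,
                                  bulk$cohort$clinical$cohort)
  }

  if (on_("ici")) {
    feats <- intersect(signature, colnames(expr_std))
    clin <- bulk$cohort$clinical
    part <- partition_cohort(clin$sample_id, clin$response,
                             train_frac = config$train_frac,
                             seed = seeds[["ici"]])
    tr <- match(part$train, clin$sample_id)
    va <- match(part$validation, clin$sample_id)
    mod <- train_response_classifier(expr_std[tr, feats, drop = FALSE],
                                     clin$response[tr],
                                     model = "gbm",
                                     k = config$cv_k,
                                     repeats = config$cv_repeats,
                                     seed = seeds[["ici"]])
    val_scores <- predict(mod, expr_std[va, feats, drop = FALSE])
    auc <- roc_auc(val_scores, clin$response[va] == "R")
    risk_grp <- ifelse(val_scores > median(val_scores), "low_risk",
                       "high_risk")
    surv <- tryCatch(
      kaplan_meier_logrank(clin$os_time[va], clin$os_event[va], risk_grp),
      error = function(e) NULL)
    rep$ici <- list(model = mod, partition = part,
                    validation_scores = val_scores, survival = surv)
    rep$metrics$ici_validation_auc <- auc
    if (!is.null(surv)) rep$metrics$ici_logrank_p <- surv$p
  }

  if (on_("mtlr")) {
    feats <- intersect(signature, colnames(expr_std))
    clin <- bulk$cohort$clinical
    de <- select_de_features(expr_std[, feats, drop = FALSE],
                             clin$os_time, clin$os_event,
                             n_features = min(config$n_features,
                                              length(feats)))
    Xs <- scale(expr_std[, de, drop = FALSE])
    fit <- fit_mtlr(Xs, clin$os_time, clin$os_event,
                    C1 = 1, C2 = 1, tol = 1e-4)
    pred <- predict(fit, Xs)
    cidx <- concordance_index(clin$os_time, clin$os_event, pred$risk)
    rep$mtlr <- list(features = de, fit = fit, risk = pred$risk)
    rep$metrics$mtlr_cindex <- cidx
    rep$counts$n_prognostic_features <- length(de)
  }

  if (on_("crispr")) {
    need("crispr", "simulate")
    zs <- zscore_screens(screens$screens)
    rk <- aggregate_rank(zs, fraction = config$top_fraction)
    enr <- enrichment_test(rk, signature)
    rep$ranking <- rk
    rep$enrichment <- enr
    rep$counts$flagged_genes <- sum(rk$flagged)
    rep$metrics$enrichment_p <- enr$p
  }

  if (on_("hub")) {
    need("hub", "crispr")
    need("hub", "mtlr")
    rep$hub_genes <- intersect_hub(rep$enrichment$overlap_genes,
                                   rep$mtlr$features)
    rep$counts$n_hub_genes <- length(rep$hub_genes)
  }

  if (!is.null(config$out_dir)) write_report_artifacts(rep, config)
  class(rep) <- "run_report"
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$counts[[nm]], collapse = " ")))
  }
  for (nm in names(x$metrics)) {
    cat(sprintf("  %s: %.4g\n", nm, x$metrics[[nm]]))
  }
  if (!is.null(x$hub_genes)) {
    cat(sprintf("  hub genes: %s\n", paste(x$hub_genes, collapse = ", ")))
  }
  invisible(x)
}

write_report_artifacts <- function(rep, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  if (!is.null(rep$fss)) {
    write_gmt(rep$fss$members, file.path(od, "fss.gmt"), name = "FSS")
    write.table(rep$fss$table, file.path(od, "fss_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$bulk_scores)) {
    write.table(data.frame(sample_id = names(rep$bulk_scores),
                           fss_score = as.numeric(rep$bulk_scores)),
                file.path(od, "fss_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$subgroups)) {
    write.table(cbind(sample_id = rownames(rep$subgroups), rep$subgroups),
                file.path(od, "subgroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$ranking)) {
    write.table(rep$ranking, file.path(od, "ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$enrichment)) {
    jsonlite::write_json(rep$enrichment[c("overlap", "n_flagged",
                                          "n_signature", "n_universe",
                                          "expected", "p")],
                         file.path(od, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(rep$hub_genes)) {
    writeLines(rep$hub_genes, file.path(od, "hub_genes.txt"))
  }
  if (length(rep$metrics) > 0L) {
    jsonlite::write_json(rep$metrics, file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(od)
}
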