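# Seeded synthetic data with planted ground truth: cell-type-structured
# single-cell counts driven by a latent fibroblast senescence score, bulk
# cohorts whose survival and immunotherapy response depend on the latent
# senescence burden, and CRISPR-screen logFC tables with planted
# immune-resistance hits. Used to validate every downstream stage against
# known truth.

#' Simulation configuration
#'
#' Bundles and validates every knob of the three generators. Defaults
#' define the reference simulation used throughout the package's tests:
#' 8 single-cell datasets of 1500 cells over a 1000-gene universe,
#' a 400-sample 4-cohort bulk collection, and 17 CRISPR screens.
#'
#' @param n_datasets Number of single-cell datasets (default 8).
#' @param n_cells_per_dataset Cells per dataset (default 1500).
#' @param n_genes Size of the gene universe (default 1000).
#' @param cell_type_props Named probability vector over the six modeled
#'   cell types; must sum to 1.
#' @param n_senescence_genes Size of the senescence-induced gene set
#'   (default 50), upregulated with latent senescence in every cell type.
#' @param n_planted_fss_genes Number of planted fibroblast-senescence
#'   genes (default 40): upregulated with senescence in fibroblasts only
#'   and fibroblast-enriched.
#' @param n_marker_genes Marker genes per cell type (default 25).
#' @param senescence_effect Log-scale slope (gamma) of the senescence set
#'   on the latent score, all cell types (default 1).
#' @param fss_effect Log-scale slope (beta) of planted genes on the latent
#'   score within fibroblasts (default 1).
#' @param marker_effect Log-scale shift of marker genes in their cell type
#'   (default 2, i.e. roughly seven-fold marker enrichment).
#' @param nb_dispersion Negative-binomial size parameter shared by all
#'   genes (default 30).
#' @param mito_gene_count Number of `MT-` genes (default 10).
#' @param lowdepth_cell_frac Fraction of cells whose depth is scaled by
#'   0.05 to exercise QC (default 0.1).
#' @param bulk_n_samples,bulk_n_cohorts Bulk collection size (default
#'   400 samples over 4 cohorts).
#' @param batch_sd SD of per-cohort per-gene additive batch offsets
#'   (default 0.5, log-scale).
#' @param hazard_coef Log-hazard slope on latent burden (default 1.5).
#' @param baseline_hazard Baseline exponential hazard per day (default
#'   1/1000).
#' @param censor_frac Target censored fraction (default 0.3); must be in
#'   \[0, 1).
#' @param response_coef Slope of non-response on latent burden (default 3).
#' @param response_intercept Logit intercept of response (default 1).
#' @param cytotoxic_effect Log-scale decrease of cytotoxic markers per
#'   unit burden (default 1).
#' @param tmb_effect Log-scale increase of cytotoxic markers per unit
#'   log-TMB (default 0.15).
#' @param bulk_noise_sd Residual log-scale noise in bulk expression
#'   (default 0.3).
#' @param screen_n_datasets Number of CRISPR screens (default 17).
#' @param screen_effect Depletion (delta) of planted resistant genes'
#'   logFC (default 2; must be >= 0).
#' @param screen_n_resistant Planted immune-resistance genes (default 25).
#' @param screen_fss_overlap How many resistant genes are drawn from the
#'   planted fibroblast-senescence genes (default 15).
#' @param screen_measured_frac Fraction of the universe measured by each
#'   screen (default 0.9).
#' @param seed Master seed (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 8,
                       n_cells_per_dataset = 1500,
                       n_genes = 1000,
                       cell_type_props = c(fibroblast = 0.25, malignant = 0.30,
                                           tcell = 0.20, bcell = 0.10,
                                           myeloid = 0.10, endothelial = 0.05),
                       n_senescence_genes = 50,
                       n_planted_fss_genes = 40,
                       n_marker_genes = 25,
                       senescence_effect = 1.0,
                       fss_effect = 1.0,
                       marker_effect = 2.0,
                       nb_dispersion = 30,
                       mito_gene_count = 10,
                       lowdepth_cell_frac = 0.1,
                       bulk_n_samples = 400,
                       bulk_n_cohorts = 4,
                       batch_sd = 0.5,
                       hazard_coef = 1.5,
                       baseline_hazard = 1 / 1000,
                       censor_frac = 0.3,
                       response_coef = 3,
                       response_intercept = 1,
                       cytotoxic_effect = 1.0,
                       tmb_effect = 0.15,
                       bulk_noise_sd = 0.3,
                       screen_n_datasets = 17,
                       screen_effect = 2,
                       screen_n_resistant = 25,
                       screen_fss_overlap = 15,
                       screen_measured_frac = 0.9,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_datasets", "n_cells_per_dataset", "n_genes",
              "n_senescence_genes", "n_planted_fss_genes", "n_marker_genes",
              "mito_gene_count", "bulk_n_samples", "bulk_n_cohorts",
              "screen_n_datasets", "screen_n_resistant")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(sprintf("%s must be a positive count", nm))
  }
  probs <- c("lowdepth_cell_frac", "screen_measured_frac")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(sprintf("%s must be in [0,1]", nm))
  }
  if (cfg$censor_frac < 0 || cfg$censor_frac >= 1) {
    stop("censor_frac must be in [0, 1)")
  }
  if (abs(sum(cfg$cell_type_props) - 1) > 1e-8) {
    stop("cell_type_props must sum to 1")
  }
  if (any(cfg$cell_type_props < 0)) stop("cell_type_props must be >= 0")
  if (cfg$nb_dispersion <= 0 || cfg$batch_sd < 0) {
    stop("nb_dispersion must be > 0 and batch_sd >= 0")
  }
  if (cfg$screen_effect < 0) stop("screen_effect (delta) must be >= 0")
  if (cfg$screen_fss_overlap > min(cfg$screen_n_resistant,
                                   cfg$n_planted_fss_genes)) {
    stop("screen_fss_overlap exceeds resistant or planted gene count")
  }
  n_types <- length(cfg$cell_type_props)
  need <- cfg$mito_gene_count + cfg$n_senescence_genes +
    cfg$n_planted_fss_genes + n_types * cfg$n_marker_genes
  if (need > cfg$n_genes) {
    stop(sprintf(paste0("n_genes = %d cannot host the disjoint mito/",
                        "senescence/planted/marker sets (need %d; ",
                        "deficit %d)"), cfg$n_genes, need, need - cfg$n_genes))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Gene universe with disjoint special-role index blocks.
gene_universe <- function(cfg) {
  types <- names(cfg$cell_type_props)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  mito <- seq_len(cfg$mito_gene_count)
  genes[mito] <- paste0("MT-", seq_along(mito))
  at <- cfg$mito_gene_count
  sen <- at + seq_len(cfg$n_senescence_genes); at <- at + cfg$n_senescence_genes
  fss <- at + seq_len(cfg$n_planted_fss_genes)
  at <- at + cfg$n_planted_fss_genes
  markers <- list()
  for (t in types) {
    markers[[t]] <- at + seq_len(cfg$n_marker_genes)
    at <- at + cfg$n_marker_genes
  }
  list(genes = genes, mito = mito, senescence = sen, fss = fss,
       markers = markers)
}

#' Generate single-cell datasets with planted fibroblast senescence
#'
#' Cell types are drawn from `cell_type_props`; each cell carries a latent
#' senescence score `s` in \[0, 1\] (Beta(5, 2) in fibroblasts, Beta(2, 5)
#' elsewhere). Gene baseline log-means are Normal(1, 1) per dataset;
#' counts are negative binomial around `depth * exp(log-mean)`. The
#' senescence set gains `gamma * s` in all cells; planted
#' fibroblast-senescence genes gain `beta * s` plus the marker shift in
#' fibroblasts only; each cell type has disjoint markers shifted by
#' `marker_effect`; a `lowdepth_cell_frac` fraction of cells has depth
#' scaled by 0.05 to exercise QC.
#'
#' @param cfg A [sim_config()].
#' @return List of length `n_datasets`; each element is
#'   `list(dataset = cell_dataset, truth = list)` where truth records the
#'   latent scores, planted/senescence/marker gene sets, and low-depth
#'   cells.
#' @export
generate_sc_datasets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  uni <- gene_universe(cfg)
  types <- names(cfg$cell_type_props)
  out <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    id <- sprintf("scds%02d", d)
    n <- cfg$n_cells_per_dataset
    p <- cfg$n_genes
    ct <- sample(types, n, replace = TRUE, prob = cfg$cell_type_props)
    fib <- ct == "fibroblast"
    s <- ifelse(fib, rbeta(n, 5, 2), rbeta(n, 2, 5))
    mu0 <- rnorm(p, 1, 1)
    logE <- matrix(mu0, nrow = p, ncol = n)
    logE[uni$senescence, ] <- logE[uni$senescence, , drop = FALSE] +
      rep(cfg$senescence_effect * s, each = length(uni$senescence))
    if (any(fib)) {
      logE[uni$fss, fib] <- logE[uni$fss, fib, drop = FALSE] +
        rep(cfg$fss_effect * s[fib] + cfg$marker_effect,
            each = length(uni$fss))
    }
    for (t in types) {
      sel <- ct == t
      if (any(sel)) {
        logE[uni$markers[[t]], sel] <-
          logE[uni$markers[[t]], sel, drop = FALSE] + cfg$marker_effect
      }
    }
    depth <- exp(rnorm(n, 0.5, 0.3))
    low <- runif(n) < cfg$lowdepth_cell_frac
    depth[low] <- depth[low] * 0.05
    mu <- sweep(exp(logE), 2L, depth, "*")
    counts <- matrix(rnbinom(p * n, size = cfg$nb_dispersion, mu = mu),
                     nrow = p,
                     dimnames = list(uni$genes,
                                     sprintf("%s_cell%04d", id, seq_len(n))))
    meta <- data.frame(dataset_id = id, cell_type = ct,
                       row.names = colnames(counts),
                       stringsAsFactors = FALSE)
    ds <- cell_dataset(counts, meta, dataset_id = id)
    truth <- list(
      dataset_id = id,
      s = setNames(s, colnames(counts)),
      planted_fss_genes = uni$genes[uni$fss],
      senescence_set_genes = uni$genes[uni$senescence],
      marker_genes = lapply(uni$markers, function(ix) uni$genes[ix]),
      lowdepth_cells = colnames(counts)[low])
    out[[d]] <- list(dataset = ds, truth = truth)
  }
  out
}

# Bisection on the exponential censoring rate c so that the expected
# censored fraction E_i[c / (c + lambda_i)] hits the target.
calibrate_censor_rate <- function(lambda, target, tol = 1e-10) {
  if (target <= 0) return(0)
  f <- function(cc) mean(cc / (cc + lambda)) - target
  lo <- 1e-12
  hi <- max(lambda)
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * hi) break
  }
  (lo + hi) / 2
}

#' Generate bulk cohorts with senescence-dependent survival and response
#'
#' Each sample carries a latent senescence burden `S` (Beta(2, 2)) and a
#' fibroblast fraction `f` (Beta(6, 18)). Log-expression is the per-gene
#' baseline plus: `gamma * S` on the senescence set, `beta * S * f / 0.25`
#' on planted fibroblast-senescence genes (burden signal carried by the
#' fibroblast compartment), `marker_effect * f / 0.25` on fibroblast
#' markers, and `-cytotoxic_effect * S + tmb_effect * log(TMB)` on the
#' cytotoxic (T-cell marker) panel, plus per-cohort Normal(0, batch_sd^2)
#' gene offsets and residual noise. Survival time is exponential with
#' rate `h0 * exp(hazard_coef * S)`, independently censored at a rate
#' calibrated by bisection to the target censored fraction; response is
#' Bernoulli(`plogis(intercept - response_coef * S)`); TMB is log-normal
#' and independent of `S`.
#'
#' @param cfg A [sim_config()].
#' @return `list(cohort, truth)`: `cohort` is a list with `expr`
#'   (samples x genes log-expression) and `clinical` (sample_id, cohort,
#'   os_time, os_event, tmb, response, stage); `truth` records `S`, `f`,
#'   true hazard, response probability, and batch offsets.
#' @export
generate_bulk_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  uni <- gene_universe(cfg)
  n <- cfg$bulk_n_samples
  p <- cfg$n_genes
  ids <- sprintf("sample%04d", seq_len(n))
  cohort <- sprintf("cohort%02d", rep_len(seq_len(cfg$bulk_n_cohorts), n))
  S <- rbeta(n, 2, 2)
  f <- rbeta(n, 6, 18)
  tmb <- rlnorm(n, log(5), 1)
  mu0 <- rnorm(p, 0, 1)
  X <- matrix(rnorm(n * p, 0, cfg$bulk_noise_sd), nrow = n,
              dimnames = list(ids, uni$genes))
  X <- sweep(X, 2L, mu0, "+")
  X[, uni$senescence] <- X[, uni$senescence, drop = FALSE] +
    cfg$senescence_effect * S
  X[, uni$fss] <- X[, uni$fss, drop = FALSE] +
    cfg$fss_effect * S * (f / 0.25)
  X[, uni$markers$fibroblast] <- X[, uni$markers$fibroblast, drop = FALSE] +
    cfg$marker_effect * (f / 0.25)
  cyto <- uni$markers$tcell
  X[, cyto] <- X[, cyto, drop = FALSE] -
    cfg$cytotoxic_effect * S + cfg$tmb_effect * log(tmb)
  batch <- matrix(rnorm(cfg$bulk_n_cohorts * p, 0, cfg$batch_sd),
                  nrow = cfg$bulk_n_cohorts,
                  dimnames = list(sprintf("cohort%02d",
                                          seq_len(cfg$bulk_n_cohorts)),
                                  uni$genes))
  X <- X + batch[cohort, , drop = FALSE]
  lambda <- cfg$baseline_hazard * exp(cfg$hazard_coef * S)
  death <- rexp(n, lambda)
  crate <- calibrate_censor_rate(lambda, cfg$censor_frac)
  cens <- if (crate > 0) rexp(n, crate) else rep(Inf, n)
  os_time <- pmin(death, cens)
  os_event <- as.integer(death <= cens)
  pR <- plogis(cfg$response_intercept - cfg$response_coef * S)
  response <- ifelse(rbinom(n, 1, pR) == 1, "R", "NR")
  clinical <- data.frame(
    sample_id = ids, cohort = cohort,
    os_time = os_time, os_event = os_event, tmb = tmb,
    response = response,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2)),
    stringsAsFactors = FALSE)
  truth <- list(S = setNames(S, ids), f = setNames(f, ids),
                hazard = setNames(lambda, ids),
                response_prob = setNames(pR, ids),
                censor_rate = crate,
                batch_offsets = batch,
                cytotoxic_genes = uni$genes[cyto],
                planted_fss_genes = uni$genes[uni$fss],
                senescence_set_genes = uni$genes[uni$senescence])
  list(cohort = list(expr = X, clinical = clinical), truth = truth)
}

#' Generate CRISPR-screen logFC tables with planted resistant genes
#'
#' Screen `d` measures a random `screen_measured_frac` subset of the gene
#' universe with `logFC ~ Normal(mu_d, sigma_d^2)`, `mu_d ~ Normal(0,
#' 0.5^2)`, `sigma_d ~ Uniform(0.5, 2)`. Planted immune-resistance genes
#' (a configurable number of which overlap the planted
#' fibroblast-senescence genes) are shifted by `-delta`, emulating
#' depletion under immune pressure.
#'
#' @param cfg A [sim_config()].
#' @return `list(screens, truth)`: `screens` is a named list of
#'   data.frames (`gene`, `logfc`); `truth` records the resistant genes,
#'   the overlap genes, and per-dataset `mu`/`sigma`.
#' @export
generate_crispr_screens <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  uni <- gene_universe(cfg)
  genes <- uni$genes
  overlap <- genes[uni$fss][seq_len(cfg$screen_fss_overlap)]
  pool <- setdiff(genes[-c(uni$mito, uni$senescence, uni$fss,
                           unlist(uni$markers))], overlap)
  extra <- sample(pool, cfg$screen_n_resistant - cfg$screen_fss_overlap)
  resistant <- c(overlap, extra)
  mu_d <- rnorm(cfg$screen_n_datasets, 0, 0.5)
  sigma_d <- runif(cfg$screen_n_datasets, 0.5, 2)
  screens <- list()
  for (d in seq_len(cfg$screen_n_datasets)) {
    id <- sprintf("screen%02d", d)
    measured <- sort(sample(seq_along(genes),
                            max(2L, round(cfg$screen_measured_frac *
                                            length(genes)))))
    g <- genes[measured]
    lfc <- rnorm(length(g), mu_d[d], sigma_d[d])
    lfc[g %in% resistant] <- lfc[g %in% resistant] - cfg$screen_effect
    screens[[id]] <- data.frame(gene = g, logfc = lfc,
                                stringsAsFactors = FALSE)
  }
  truth <- list(planted_resistant_genes = resistant,
                fss_overlap_genes = overlap,
                mu = setNames(mu_d, names(screens)),
                sigma = setNames(sigma_d, names(screens)))
  list(screens = screens, truth = truth)
}

#' Write a single-cell dataset as MTX + TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cells.tsv`
#' (metadata) into `dir`.
#'
#' @param ds A `cell_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(as.matrix(ds$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "barcodes.tsv"))
  write.table(cbind(cell_id = rownames(ds$cell_meta), ds$cell_meta),
              file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell dataset written by [write_sc_dataset()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `cells.tsv`.
#' @return A `cell_dataset`.
#' @export
read_sc_dataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"), row.names = 1)
  cell_dataset(m, meta, dataset_id = meta$dataset_id[1])
}

#' Write/read generator truth records as JSON
#'
#' @param truth Truth list from any generator.
#' @param path JSON path.
#' @return For the writer, `path` invisibly; for the reader, the truth
#'   list.
#' @export
write_truth <- function(truth, path) {
  # named numeric vectors become JSON objects so names survive the trip
  enc <- lapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(x), c("s", "S", "f", "hazard", "response_prob",
                                   "mu", "sigma"))) {
    x[[nm]] <- unlist(x[[nm]])
  }
  x
}
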