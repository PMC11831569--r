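# Single-sample gene-set enrichment scoring: rank-based gene-level
# statistics followed by a weighted Kolmogorov-Smirnov random walk, plus
# the min-max normalization and median high/low split used for per-cell
# senescence scores.

#' Gene-level rank statistic across samples
#'
#' Converts an expression matrix into per-gene relative-rank statistics
#' used by the enrichment random walk. In `ecdf` mode the statistic is the
#' empirical CDF of each gene evaluated at each sample,
#' `z_ij = (1/n) * #\{k : x_ik <= x_ij\}`. In `gauss` mode it is a
#' Gaussian-kernel smoothed CDF with per-gene bandwidth `sd_i / 4`
#' (suited to continuous bulk profiles).
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids).
#' @param mode `"ecdf"` (default; deterministic, suited to sparse
#'   log-normalized single-cell data) or `"gauss"`.
#' @return Numeric matrix of the same dimension with values in (0, 1].
#' @export
gene_level_stat <- function(expr, mode = c("ecdf", "gauss")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (ncol(expr) < 1L) stop("need at least one sample")
  if (nrow(expr) < 2L) stop("need at least two genes")
  if (mode == "ecdf") {
    n <- ncol(expr)
    z <- t(apply(expr, 1L, rank, ties.method = "max")) / n
    dimnames(z) <- dimnames(expr)
    z
  } else {
    z <- cpp_gauss_cdf_stat(expr)
    dimnames(z) <- dimnames(expr)
    z
  }
}

#' Enrichment score from a weighted KS random walk
#'
#' For each sample, genes are ordered by decreasing gene-level statistic
#' (ties broken by ascending gene index). Walking down that list, in-set
#' genes add their symmetric rank weight `|p/2 - rho|^tau` (normalized by
#' the total in-set weight; `rho` is the rank with the top gene at
#' `rho = p`) and out-of-set genes subtract `1/(p - |set|)`. The score is
#' the maximum positive deviation plus the minimum negative deviation of
#' the walk, so ES lies in [-1, 1].
#'
#' @param z Gene-level statistic matrix from [gene_level_stat()],
#'   genes x samples.
#' @param set Character vector of member gene ids (matched against
#'   rownames of `z`) or integer row indices.
#' @param tau Rank-weight exponent (default 1).
#' @param combine How the walk's excursions are combined: `"diff"`
#'   (default) adds the maximum positive and minimum negative deviation;
#'   `"absmax"` takes the signed maximum absolute deviation (magnitude
#'   ties resolve to the positive excursion).
#' @return Named numeric vector of enrichment scores, one per sample.
#' @export
gsva_es <- function(z, set, tau = 1, combine = c("diff", "absmax")) {
  combine <- match.arg(combine)
  z <- as.matrix(z)
  p <- nrow(z)
  if (is.character(set)) {
    idx <- which(rownames(z) %in% set)
  } else {
    idx <- as.integer(set)
  }
  if (length(idx) == 0L) {
    stop("gene set has no overlap with the expression universe")
  }
  if (length(idx) >= p) {
    stop("gene set covers the whole universe; the out-of-set step is undefined")
  }
  es <- cpp_es_walk(z, as.integer(idx), tau,
                    if (combine == "absmax") 1L else 0L)
  names(es) <- colnames(z)
  es
}

#' Score a gene set per sample
#'
#' Convenience wrapper chaining [gene_level_stat()] and [gsva_es()].
#'
#' @inheritParams gene_level_stat
#' @inheritParams gsva_es
#' @return Named numeric vector of enrichment scores.
#' @export
score_geneset <- function(expr, set, mode = c("ecdf", "gauss"), tau = 1,
                          combine = "diff") {
  gsva_es(gene_level_stat(expr, mode), set, tau, combine)
}

#' Min-max normalize a score vector
#'
#' Maps scores onto [0, 1] via `(x - min) / (max - min)`. A constant
#' vector maps to 0.5 everywhere, with a warning.
#'
#' @param x Numeric vector.
#' @return Numeric vector in [0, 1].
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 1L) stop("empty score vector")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant scores: min-max normalization undefined, returning 0.5")
    return(setNames(rep(0.5, length(x)), names(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Split samples into high/low groups at the median score
#'
#' Scores strictly above the population median are labeled `HS`
#' (high-senescent); scores at or below the median are `LS`. Ties at the
#' median deterministically go to `LS`.
#'
#' @param scores Numeric vector.
#' @param ids Optional ids; defaults to `names(scores)`.
#' @return Factor with levels `c("LS", "HS")`, named by `ids`.
#' @export
split_by_median <- function(scores, ids = names(scores)) {
  if (length(scores) < 2L) stop("need at least 2 samples for a median split")
  if (max(scores) == min(scores)) {
    stop("median split undefined: scores are constant")
  }
  grp <- factor(ifelse(scores > median(scores), "HS", "LS"),
                levels = c("LS", "HS"))
  names(grp) <- ids
  grp
}

#' Per-cell senescence scores for a single-cell dataset
#'
#' Log-normalizes counts, computes the ecdf-mode enrichment score of the
#' senescence gene set for every cell, min-max normalizes within the
#' dataset, and attaches the high/low-senescent median split.
#'
#' @param ds A `cell_dataset`.
#' @param geneset Character vector of senescence-induced gene symbols.
#' @param mode Gene-level statistic mode, see [gene_level_stat()].
#' @param split Logical: attach the HS/LS median-split label (default TRUE).
#' @return data.frame with columns `cell_id`, `es` (raw enrichment score),
#'   `score` (min-max normalized), and `group` if `split` is TRUE.
#' @export
senescence_score_cells <- function(ds, geneset, mode = "ecdf", split = TRUE) {
  norm <- lognormalize(ds)
  es <- score_geneset(norm, geneset, mode = mode)
  score <- minmax_normalize(es)
  out <- data.frame(cell_id = colnames(norm), es = as.numeric(es),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  if (split) out$group <- split_by_median(out$score, out$cell_id)
  out
}
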