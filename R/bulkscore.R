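# Bulk-cohort scoring with the FSS, marker-set immune scores, pathway
# correlation, and the FSS x TMB eight-subgroup stratification.

#' Per-sample FSS score of a bulk cohort
#'
#' Gaussian-kernel single-sample enrichment of the signature over the
#' cohort (suited to continuous bulk expression).
#'
#' @param cohort Bulk cohort list with `expr` (samples x genes) and
#'   `clinical`, or a bare samples x genes matrix.
#' @param fss Character vector of signature genes (or an `fss_signature`).
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
score_cohort_fss <- function(cohort, fss) {
  expr <- if (is.list(cohort) && !is.null(cohort$expr)) cohort$expr else cohort
  if (inherits(fss, "fss_signature")) fss <- fss$members
  if (nrow(expr) < 2L) stop("need at least 2 samples")
  cov <- mean(fss %in% colnames(expr))
  if (cov == 0) stop("no signature gene present in the cohort")
  if (cov < 0.5) {
    warning(sprintf("only %.0f%% of signature genes present in the cohort",
                    100 * cov))
  }
  score_geneset(t(expr), fss, mode = "gauss")
}

#' Marker-mean immune-population scores
#'
#' Per-sample abundance proxy for each population: the arithmetic mean of
#' the marker set's log-expression values.
#'
#' @param cohort Bulk cohort (list with `expr`) or samples x genes matrix.
#' @param marker_sets Named list of marker gene sets (e.g. from
#'   [read_gmt()]).
#' @return samples x populations numeric matrix; sets with no overlap are
#'   skipped with a warning.
#' @export
immune_scores <- function(cohort, marker_sets) {
  expr <- if (is.list(cohort) && !is.null(cohort$expr)) cohort$expr else cohort
  out <- list()
  for (nm in names(marker_sets)) {
    genes <- intersect(marker_sets[[nm]], colnames(expr))
    if (length(genes) == 0L) {
      warning(sprintf("marker set '%s' has no overlap with cohort genes; skipped",
                      nm))
      next
    }
    out[[nm]] <- rowMeans(expr[, genes, drop = FALSE])
  }
  if (length(out) == 0L) stop("no marker set overlaps the cohort genes")
  do.call(cbind, out)
}

#' Spearman correlation of FSS scores with pathway scores
#'
#' @param fss_scores Per-sample FSS score vector.
#' @param pathway_scores samples x pathways matrix (aligned rows).
#' @return data.frame (`pathway`, `r`, `p`, `fdr`); constant pathways are
#'   reported as NA.
#' @export
pathway_correlation <- function(fss_scores, pathway_scores) {
  pathway_scores <- as.matrix(pathway_scores)
  if (length(fss_scores) != nrow(pathway_scores)) {
    stop("fss_scores must align to pathway_scores rows")
  }
  if (length(fss_scores) < 5L) stop("need at least 5 samples")
  const <- apply(pathway_scores, 2L, function(x) max(x) == min(x))
  r <- p <- rep(NA_real_, ncol(pathway_scores))
  if (any(!const)) {
    sp <- rowwise_spearman(t(pathway_scores[, !const, drop = FALSE]),
                           fss_scores)
    r[!const] <- sp$r
    p[!const] <- sp$p
  }
  data.frame(pathway = colnames(pathway_scores), r = r, p = p,
             fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

#' Stratify samples by FSS score and TMB medians
#'
#' High-FSS (`HF`) means score strictly above the median (ties go low,
#' `LF`); `HT`/`LT` likewise for TMB. Medians are pooled across cohorts
#' by default. The combined label is the concatenation of the two
#' marginals, giving the four groups `HFHT`, `HFLT`, `LFHT`, `LFLT`.
#'
#' @param fss_scores Per-sample FSS scores.
#' @param tmb Per-sample tumor mutation burden, aligned.
#' @param pooled Use pooled medians (default TRUE); otherwise medians are
#'   taken within `cohort`.
#' @param cohort Cohort labels, required when `pooled = FALSE`.
#' @return data.frame (`fss_label`, `tmb_label`, `combined`), rownames
#'   from `names(fss_scores)`.
#' @export
stratify_fss_tmb <- function(fss_scores, tmb, pooled = TRUE, cohort = NULL) {
  if (length(fss_scores) != length(tmb)) stop("fss_scores and tmb must align")
  if (length(fss_scores) < 4L) stop("need at least 4 samples to stratify")
  med_of <- function(x) {
    if (pooled || is.null(cohort)) rep(median(x), length(x))
    else stats::ave(x, cohort, FUN = median)
  }
  hf <- fss_scores > med_of(fss_scores)
  ht <- tmb > med_of(tmb)
  out <- data.frame(
    fss_label = ifelse(hf, "HF", "LF"),
    tmb_label = ifelse(ht, "HT", "LT"),
    stringsAsFactors = FALSE)
  out$combined <- paste0(out$fss_label, out$tmb_label)
  rownames(out) <- names(fss_scores)
  out
}

#' Pairwise Mann-Whitney comparisons of population scores across subgroups
#'
#' Two-sided Wilcoxon rank-sum test for every population score and every
#' pair of subgroups, with Benjamini-Hochberg adjustment over the whole
#' table.
#'
#' @param scores samples x populations matrix (or a vector for a single
#'   population).
#' @param assignment Group label per sample (e.g. the `combined` column of
#'   [stratify_fss_tmb()]).
#' @param min_n Minimum group size for a pair to be tested (default 3);
#'   smaller pairs are skipped with a warning.
#' @return data.frame (`population`, `group1`, `group2`, `u`, `p`,
#'   `fdr`).
#' @export
compare_subgroups <- function(scores, assignment, min_n = 3) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1,
                     dimnames = list(names(scores), "score"))
  }
  assignment <- as.character(assignment)
  groups <- sort(unique(assignment))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (pop in colnames(scores)) {
    for (pr in pairs) {
      a <- scores[assignment == pr[1], pop]
      b <- scores[assignment == pr[2], pop]
      if (length(a) < min_n || length(b) < min_n) {
        warning(sprintf("pair %s vs %s skipped (group below %d samples)",
                        pr[1], pr[2], min_n))
        next
      }
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, group1 = pr[1], group2 = pr[2],
        u = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no comparable pair of subgroups")
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out
}
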