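# Construction of the fibroblast senescence-associated signature (FSS):
# per-dataset senescence-correlated genes (FS_x), fibroblast-upregulated
# markers (FS_y), their intersection (FS_n), then cross-dataset
# aggregation by geometric-mean Spearman correlation with a cutoff.

# Vectorized Spearman correlation of each row of `mat` against `y`, with
# tie-corrected (average) ranks and a two-sided t-approximation p-value.
rowwise_spearman <- function(mat, y) {
  n <- length(y)
  ry <- rank(y)
  rmat <- t(apply(mat, 1L, rank))
  r <- as.numeric(cor(t(rmat), ry))
  r[is.na(r)] <- 0
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Senescence-correlated genes within fibroblasts (FS_x)
#'
#' Tests every sufficiently detected gene for Spearman correlation with
#' the per-cell senescence score, using tie-corrected ranks and a
#' two-sided t-approximation. Benjamini-Hochberg adjustment is applied
#' over tested genes; genes with `R > 0` and `FDR < fdr` are kept.
#'
#' @param expr Genes x cells normalized expression of fibroblast cells.
#' @param scores Per-cell senescence score aligned to the columns.
#' @param min_detect Minimum detection fraction for a gene to be tested
#'   (default 0.1).
#' @param fdr FDR cutoff (default 0.05).
#' @return data.frame (`gene`, `r`, `p`, `fdr`) of retained genes, sorted
#'   by decreasing `r`.
#' @export
compute_fsx <- function(expr, scores, min_detect = 0.1, fdr = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 10L) stop("need at least 10 fibroblast cells")
  if (length(scores) != ncol(expr)) stop("scores must align to cells")
  if (max(scores) == min(scores)) stop("constant senescence score vector")
  tested <- rowMeans(expr > 0) >= min_detect
  if (!any(tested)) stop("no gene passes the detection filter")
  sp <- rowwise_spearman(expr[tested, , drop = FALSE], scores)
  q <- p.adjust(sp$p, "BH")
  keep <- sp$r > 0 & q < fdr
  out <- data.frame(gene = rownames(expr)[tested][keep],
                    r = sp$r[keep], p = sp$p[keep], fdr = q[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$gene), , drop = FALSE]
}

#' Intersect senescence-correlated and fibroblast-marker genes (FS_n)
#'
#' @param fsx FS_x table from [compute_fsx()].
#' @param fsy Fibroblast marker table from [find_cluster_markers()] (or
#'   any data.frame with a `gene` column).
#' @return data.frame (`gene`, `r`) carrying the FS_x Spearman R for
#'   genes present in both tables (possibly empty).
#' @export
compute_fsn <- function(fsx, fsy) {
  common <- intersect(fsx$gene, fsy$gene)
  out <- fsx[match(common, fsx$gene), c("gene", "r"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-dataset signatures into the FSS
#'
#' For each gene, the geometric mean of its Spearman R is taken over the
#' datasets whose FS_n contains it (all R > 0 by construction); members
#' are the genes with geometric mean above `cutoff` and support in at
#' least `ceil(min_support_frac * n_datasets)` datasets.
#'
#' @param fsn_list List of FS_n tables (one per dataset).
#' @param cutoff Geometric-mean Spearman R cutoff (default 0.25).
#' @param min_support_frac Minimum supporting-dataset fraction
#'   (default 0.25).
#' @return Object of class `fss_signature`: list with `table` (gene,
#'   gmean_r, support, member) and `members` (the signature gene list).
#' @export
aggregate_fss <- function(fsn_list, cutoff = 0.25, min_support_frac = 0.25) {
  if (length(fsn_list) == 0L) stop("empty list of per-dataset signatures")
  all_genes <- sort(unique(unlist(lapply(fsn_list, `[[`, "gene"))))
  n_ds <- length(fsn_list)
  support <- integer(length(all_genes))
  logsum <- numeric(length(all_genes))
  for (fsn in fsn_list) {
    ix <- match(fsn$gene, all_genes)
    support[ix] <- support[ix] + 1L
    logsum[ix] <- logsum[ix] + log(fsn$r)
  }
  gmean <- exp(logsum / pmax(support, 1L))
  gmean[support == 0L] <- NA_real_
  min_support <- ceiling(min_support_frac * n_ds)
  member <- !is.na(gmean) & gmean > cutoff & support >= min_support
  tab <- data.frame(gene = all_genes, gmean_r = gmean, support = support,
                    member = member, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$gmean_r, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, members = tab$gene[tab$member],
                 cutoff = cutoff, min_support = min_support,
                 n_datasets = n_ds),
            class = "fss_signature")
}

#' @export
print.fss_signature <- function(x, ...) {
  cat(sprintf(paste0("fss_signature: %d member genes (of %d candidates; ",
                     "gmean R > %.2f, support >= %d of %d datasets)\n"),
              length(x$members), nrow(x$table), x$cutoff, x$min_support,
              x$n_datasets))
  invisible(x)
}

#' Build per-dataset FS_x / FS_y / FS_n from a QC'd single-cell dataset
#'
#' Convenience wrapper running log-normalization, per-cell senescence
#' scoring, FS_x on fibroblast cells, fibroblast markers (FS_y), and the
#' intersection FS_n.
#'
#' @param ds A QC-filtered `cell_dataset` with a `cell_type` metadata
#'   column.
#' @param senescence_genes Senescence-induced gene set.
#' @param fibro_label Label of the fibroblast population (default
#'   `"fibroblast"`).
#' @param min_detect,fdr Passed to [compute_fsx()].
#' @param min_logfc,min_pct Passed to [find_cluster_markers()].
#' @return List with `fsx`, `fsy`, `fsn`, `scores` (per-cell score table)
#'   and `dataset_id`.
#' @export
per_dataset_signature <- function(ds, senescence_genes,
                                  fibro_label = "fibroblast",
                                  min_detect = 0.1, fdr = 0.05,
                                  min_logfc = 0.25, min_pct = 0.1) {
  norm <- lognormalize(ds)
  sc <- senescence_score_cells(ds, senescence_genes)
  fib <- ds$cell_meta$cell_type == fibro_label
  if (sum(fib) < 10) stop("need at least 10 fibroblast cells")
  fsx <- compute_fsx(norm[, fib, drop = FALSE], sc$score[fib],
                     min_detect = min_detect, fdr = fdr)
  fsy <- find_cluster_markers(norm, ds$cell_meta$cell_type, fibro_label,
                              min_logfc = min_logfc, min_pct = min_pct)
  list(dataset_id = ds$cell_meta$dataset_id[1],
       fsx = fsx, fsy = fsy, fsn = compute_fsn(fsx, fsy), scores = sc)
}
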