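# Single-cell containers, QC filtering, normalization, and cluster-marker
# detection following the defaults of the standard single-cell toolchain
# (500-gene / 5%-mitochondrial QC; Wilcoxon markers at logFC > 0.25 and
# min.pct > 0.1).

#' Construct a single-cell dataset
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (dense or `Matrix` sparse); rownames are gene symbols, colnames cell
#'   barcodes.
#' @param cell_meta Optional data.frame of per-cell metadata (one row per
#'   cell). `n_genes_detected` and `pct_mito` are computed from the counts
#'   when absent; mitochondrial genes are identified by the `MT-` symbol
#'   prefix.
#' @param dataset_id Identifier stored in the metadata.
#' @return Object of class `cell_dataset`: list with `counts`, `gene_ids`
#'   and `cell_meta`.
#' @export
cell_dataset <- function(counts, cell_meta = NULL, dataset_id = "ds1") {
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(dataset_id, "_cell", seq_len(ncol(counts)))
  }
  if (min(counts) < 0) stop("counts must be non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(counts))
  }
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta rows must match count-matrix columns")
  }
  if (is.null(cell_meta$dataset_id)) cell_meta$dataset_id <- dataset_id
  if (is.null(cell_meta$n_genes_detected)) {
    cell_meta$n_genes_detected <- as.integer(Matrix::colSums(counts > 0))
  }
  if (is.null(cell_meta$pct_mito)) {
    mt <- grepl("^MT-", rownames(counts))
    tot <- Matrix::colSums(counts)
    mito <- if (any(mt)) Matrix::colSums(counts[mt, , drop = FALSE]) else 0
    cell_meta$pct_mito <- ifelse(tot > 0, 100 * mito / tot, 0)
  }
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_meta = cell_meta),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d genes x %d cells (dataset %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_meta$dataset_id), collapse = ",")))
  invisible(x)
}

#' QC-filter cells by detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with `n_genes_detected >= min_genes` and
#' `pct_mito <= max_pct_mito`; cell order is preserved. The kept/dropped
#' counts are attached as the `"qc_log"` attribute.
#'
#' @param ds A `cell_dataset`.
#' @param min_genes Minimum number of detected genes (default 500; cells
#'   with fewer are removed).
#' @param max_pct_mito Maximum mitochondrial percentage (default 5).
#' @return Filtered `cell_dataset`.
#' @export
qc_filter_cells <- function(ds, min_genes = 500, max_pct_mito = 5) {
  stopifnot(inherits(ds, "cell_dataset"))
  keep <- ds$cell_meta$n_genes_detected >= min_genes &
    ds$cell_meta$pct_mito <= max_pct_mito
  if (!any(keep)) stop("all cells filtered: no cell passes QC thresholds")
  out <- structure(list(counts = ds$counts[, keep, drop = FALSE],
                        gene_ids = ds$gene_ids,
                        cell_meta = ds$cell_meta[keep, , drop = FALSE]),
                   class = "cell_dataset")
  attr(out, "qc_log") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Library-size log-normalization
#'
#' Per cell: `x -> log(1 + scale * count / cell_total)` (natural log).
#' Zero counts stay zero; doubling all counts of a cell leaves its
#' normalized profile unchanged.
#'
#' @param ds A `cell_dataset` or a genes x cells count matrix.
#' @param scale Size-factor target (default 1e4).
#' @return Dense genes x cells matrix of normalized expression.
#' @export
lognormalize <- function(ds, scale = 1e4) {
  counts <- if (inherits(ds, "cell_dataset")) ds$counts else ds
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop(sprintf("cell(s) with zero total counts: %s",
                 paste(head(colnames(counts)[tot == 0], 5), collapse = ", ")))
  }
  log1p(sweep(counts, 2L, tot / scale, "/"))
}

# Vectorized two-sided Wilcoxon rank-sum test of each row of `mat`
# between columns in `grp` (logical) and the rest, using the normal
# approximation with tie correction. Returns U (for the in-group) and p.
rowwise_ranksum <- function(mat, grp) {
  n1 <- sum(grp)
  n2 <- sum(!grp)
  stopifnot(n1 > 0, n2 > 0)
  N <- n1 + n2
  stats <- apply(mat, 1L, function(x) {
    r <- rank(x)
    u <- sum(r[grp]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) return(c(u, 1))
    z <- (u - n1 * n2 / 2) / sqrt(sig2)
    c(u, 2 * pnorm(-abs(z)))
  })
  list(u = stats[1L, ], p = stats[2L, ])
}

#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' Tests every gene between cells of a cluster and all other cells on
#' log-normalized expression (two-sided Wilcoxon with normal approximation
#' and tie correction). The fold change is
#' `log2((mean_in + 1)/(mean_out + 1))` of `expm1`-backtransformed
#' normalized means. Genes are retained when upregulated
#' (`log2fc > min_logfc`) and detected in at least `min_pct` of cells in
#' either group; Benjamini-Hochberg adjustment is applied over retained
#' tests.
#'
#' @param norm Genes x cells normalized matrix from [lognormalize()].
#' @param labels Cell-type/cluster label per cell.
#' @param cluster Cluster whose markers are sought.
#' @param min_logfc Minimum log2 fold change (default 0.25).
#' @param min_pct Minimum detection fraction in the more-detected group
#'   (default 0.1).
#' @return data.frame (`gene`, `log2fc`, `pct_in`, `pct_out`, `p_value`,
#'   `p_adj`) ordered by p-value.
#' @export
find_cluster_markers <- function(norm, labels, cluster,
                                 min_logfc = 0.25, min_pct = 0.1) {
  labels <- as.character(labels)
  if (!cluster %in% labels) stop(sprintf("unknown cluster label '%s'", cluster))
  grp <- labels == cluster
  if (sum(grp) < 3 || sum(!grp) < 3) {
    stop("need at least 3 cells inside and outside the cluster")
  }
  norm <- as.matrix(norm)
  mean_in <- rowMeans(expm1(norm[, grp, drop = FALSE]))
  mean_out <- rowMeans(expm1(norm[, !grp, drop = FALSE]))
  pct_in <- rowMeans(norm[, grp, drop = FALSE] > 0)
  pct_out <- rowMeans(norm[, !grp, drop = FALSE] > 0)
  log2fc <- log2((mean_in + 1) / (mean_out + 1))
  keep <- log2fc > max(min_logfc, 0) & pmax(pct_in, pct_out) >= min_pct
  if (!any(keep)) {
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0)))
  }
  ws <- rowwise_ranksum(norm[keep, , drop = FALSE], grp)
  out <- data.frame(gene = rownames(norm)[keep],
                    log2fc = log2fc[keep],
                    pct_in = pct_in[keep], pct_out = pct_out[keep],
                    p_value = ws$p,
                    p_adj = p.adjust(ws$p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, -out$log2fc, out$gene), , drop = FALSE]
}
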