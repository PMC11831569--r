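# CRISPR-screen integration: per-dataset z-score normalization of logFC,
# cross-screen aggregation and ascending ranking (most negative
# aggregated z = strongest immune-resistance candidate), top-fraction
# flagging, hypergeometric signature enrichment, and hub-gene
# intersection with prognostic features.

#' Z-score normalize screen logFC tables
#'
#' Per dataset, `z = (logFC - mean) / sd` over the finite entries, with
#' the sample (n-1 denominator) standard deviation.
#'
#' @param screens Named list of data.frames with columns `gene`, `logfc`.
#' @return Same structure with a `z` column added.
#' @export
zscore_screens <- function(screens) {
  stopifnot(length(screens) >= 1L)
  lapply(screens, function(df) {
    ok <- is.finite(df$logfc)
    if (sum(ok) < 2L) stop("fewer than 2 finite logFC values in a screen")
    s <- sd(df$logfc[ok])
    if (s == 0) {
      stop(sprintf("zero logFC variance in screen (genes: %s, ...)",
                   df$gene[1]))
    }
    df$z <- (df$logfc - mean(df$logfc[ok])) / s
    df
  })
}

#' Aggregate z-scores across screens and rank genes
#'
#' The aggregated z of a gene is the mean of its per-dataset z over the
#' screens where it is measured. Genes measured in fewer than
#' `min_support` screens are excluded. Ranks ascend from the most
#' negative aggregated z (rank 1 = strongest candidate: knockout of
#' depleted genes enhances immune killing); ties break by gene id. The
#' top `ceil(fraction * G)` genes are flagged.
#'
#' @param screens Z-scored screens from [zscore_screens()].
#' @param min_support Minimum number of measuring screens (default 1).
#' @param fraction Flagged top fraction (default 0.10).
#' @param descending Flip the ranking direction (default FALSE).
#' @return data.frame (`gene`, `z`, `support`, `rank`, `flagged`),
#'   ordered by rank; class `gene_ranking`.
#' @export
aggregate_rank <- function(screens, min_support = 1, fraction = 0.10,
                           descending = FALSE) {
  stopifnot(length(screens) >= 1L)
  long_gene <- unlist(lapply(screens, `[[`, "gene"), use.names = FALSE)
  long_z <- unlist(lapply(screens, `[[`, "z"), use.names = FALSE)
  ok <- is.finite(long_z)
  agg <- tapply(long_z[ok], long_gene[ok], mean)
  support <- tapply(long_z[ok], long_gene[ok], length)
  keep <- support >= min_support
  if (!any(keep)) stop("no gene passes the support filter")
  genes <- names(agg)[keep]
  z <- unname(agg[keep])
  sup <- unname(support[keep])
  ord <- if (descending) order(-z, genes) else order(z, genes)
  out <- data.frame(gene = genes[ord], z = z[ord],
                    support = as.integer(sup[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out$flagged <- out$rank <= ceiling(fraction * nrow(out))
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Hypergeometric enrichment of a signature among flagged genes
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k`
#' flagged signature genes given `N` ranked genes, `K` flagged, and `n`
#' signature genes in the universe; identical to a one-sided Fisher test
#' on the 2x2 table.
#'
#' @param ranking A `gene_ranking` from [aggregate_rank()].
#' @param signature Character vector of signature genes (or
#'   `fss_signature`).
#' @return List: `overlap` (k), `n_flagged` (K), `n_signature` (n),
#'   `n_universe` (N), `expected` (K*n/N), `p` (one-sided),
#'   `overlap_genes`.
#' @export
enrichment_test <- function(ranking, signature) {
  if (inherits(signature, "fss_signature")) signature <- signature$members
  sig <- intersect(signature, ranking$gene)
  if (length(sig) == 0L) {
    stop("signature has no overlap with the ranked universe")
  }
  N <- nrow(ranking)
  K <- sum(ranking$flagged)
  n <- length(sig)
  hits <- intersect(sig, ranking$gene[ranking$flagged])
  k <- length(hits)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, n_flagged = K, n_signature = n, n_universe = N,
       expected = K * n / N, p = p, overlap_genes = sort(hits))
}

#' Intersect flagged signature genes with prognostic genes
#'
#' @param flagged_signature_genes Signature genes flagged by the screen
#'   ranking (e.g. `enrichment_test(...)$overlap_genes`).
#' @param prognostic_genes Prognostic feature genes (e.g. from
#'   [select_de_features()]).
#' @return Character vector of hub genes in gene-id order (possibly
#'   empty, with a message).
#' @export
intersect_hub <- function(flagged_signature_genes, prognostic_genes) {
  stopifnot(length(flagged_signature_genes) > 0L,
            length(prognostic_genes) > 0L)
  hub <- sort(intersect(flagged_signature_genes, prognostic_genes))
  if (length(hub) == 0L) {
    message("no hub gene: flagged signature and prognostic lists are disjoint")
  }
  hub
}
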