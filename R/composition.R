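#' Per-sample cell-type composition table
#'
#' Cross-tabulates cells by sample and annotated cell type, with
#' row-normalized proportions.
#'
#' @param meta per-cell data frame with `sample_id` and `cell_type`
#'   columns, no missing values.
#' @return object of class `composition_table`: list with integer matrix
#'   `counts` (samples x types) and matrix `proportions` (rows sum to 1).
#' @export
composition_table <- function(meta) {
  if (!all(c("sample_id", "cell_type") %in% names(meta)))
    stop2("meta must have sample_id and cell_type columns")
  if (anyNA(meta$sample_id) || anyNA(meta$cell_type))
    stop2("missing sample or cell-type labels")
  counts <- as.matrix(table(meta$sample_id, meta$cell_type))
  storage.mode(counts) <- "integer"
  props <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = props),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Cell composition:", nrow(x$counts), "samples x", ncol(x$counts),
      "cell types,", sum(x$counts), "cells\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Hierarchical clustering of samples by composition
#'
#' Agglomerative clustering of the composition proportion rows
#' (Ward linkage on Euclidean distances by default), with the dendrogram
#' serialized in Newick.
#'
#' @param table a `composition_table` (>= 2 samples).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage linkage method passed to [stats::hclust()]; `"ward"` maps
#'   to `"ward.D2"`.
#' @param k optional number of flat groups to cut.
#' @return list with the `hclust` object, `newick` string, and `groups`
#'   (named integer vector when `k` is given).
#' @export
cluster_samples <- function(table, metric = "euclidean", linkage = "ward",
                            k = NULL) {
  if (nrow(table$proportions) < 2) stop2("need at least 2 samples")
  if (linkage == "ward") linkage <- "ward.D2"
  d <- stats::dist(table$proportions, method = metric)
  hc <- stats::hclust(d, method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  groups <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, newick = newick, groups = groups)
}

#' Fisher exact enrichment of a cell type in a sample
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[type in sample, other in sample; type elsewhere, other elsewhere]`,
#' with the p-value from summing hypergeometric probabilities no larger
#' than the observed table's (the minimum-likelihood two-sided rule). The
#' reported odds ratio is the sample odds ratio `(a d) / (b c)`; a 0.5
#' continuity correction is applied for display only when a cell is zero,
#' and flagged.
#'
#' @param table a `composition_table`.
#' @param cell_type,sample the type and sample of interest (must exist).
#' @return list with `odds_ratio`, `p_two_sided`, the 2x2 `table`, and
#'   `continuity_corrected`.
#' @export
fisher_enrichment <- function(table, cell_type, sample) {
  cm <- table$counts
  if (!sample %in% rownames(cm)) stop2("unknown sample: ", sample)
  if (!cell_type %in% colnames(cm)) stop2("unknown cell type: ", cell_type)
  a <- cm[sample, cell_type]
  b <- sum(cm[sample, ]) - a
  c_ <- sum(cm[, cell_type]) - a
  d <- sum(cm) - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("in_sample", "elsewhere"),
                                c("type", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop2("empty margin: enrichment undefined")
  p <- stats::fisher.test(tab)$p.value
  cc <- any(tab == 0)
  orr <- if (cc) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
         else (a * d) / (b * c_)
  list(odds_ratio = unname(orr), p_two_sided = unname(p), table = tab,
       continuity_corrected = cc)
}
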