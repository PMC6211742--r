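#' Score cell groups against subtype signatures
#'
#' For each group of cells and each signature gene set, the score is the
#' mean over signature genes of the per-gene relative enrichment: mean
#' normalized expression over the group's cells divided by mean normalized
#' expression over all cells. A uniformly expressed signature therefore
#' scores 1 everywhere. Genes with zero global mean are skipped with a
#' warning.
#'
#' @param norm normalized genes x cells matrix.
#' @param grouping per-cell group labels named by barcode (a partition of
#'   the columns), or an unnamed vector aligned to the columns.
#' @param signatures named list of gene sets (for the TCGA comparison:
#'   differentiated, immunoreactive, mesenchymal, proliferative).
#' @return a groups x signatures numeric score matrix.
#' @export
score_groups <- function(norm, grouping, signatures) {
  if (is.null(names(grouping))) names(grouping) <- colnames(norm)
  if (!setequal(names(grouping), colnames(norm)))
    stop2("grouping must cover exactly the matrix's cells")
  grouping <- grouping[colnames(norm)]
  groups <- sort(unique(as.character(grouping)))
  global_mean <- rowMeans(norm)
  eff <- lapply(signatures, function(gs) {
    gs2 <- intersect(gs, rownames(norm))
    if (!length(gs2)) stop2("signature has no genes in the matrix")
    zero <- gs2[global_mean[gs2] == 0]
    if (length(zero)) {
      warning("signature genes with zero global mean skipped: ",
              paste(zero, collapse = ", "), call. = FALSE)
      gs2 <- setdiff(gs2, zero)
    }
    if (!length(gs2)) stop2("signature empty after zero-mean removal")
    gs2
  })
  scores <- matrix(NA_real_, length(groups), length(signatures),
                   dimnames = list(groups, names(signatures)))
  for (gr in groups) {
    cells <- names(grouping)[grouping == gr]
    if (!length(cells)) stop2("empty group: ", gr)
    gm <- rowMeans(norm[, cells, drop = FALSE])
    for (s in names(signatures)) {
      gs <- eff[[s]]
      scores[gr, s] <- mean(gm[gs] / global_mean[gs])
    }
  }
  scores
}

#' Classify groups by the pooled mean + 2 SD rule
#'
#' Pools every entry of every supplied score matrix into one reference
#' distribution; the classification threshold is the pooled mean plus two
#' pooled standard deviations (population SD by default). A group is called
#' as the subtype with its highest score strictly above the threshold, or
#' `"unclassified"` when no score clears it.
#'
#' @param matrices a score matrix or a list of score matrices with
#'   identical column sets (e.g. a per-sample and a per-cluster matrix
#'   pooled together).
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @param pool `"all"` (default: one mean/SD over every entry of every
#'   matrix), `"per_matrix"`, or `"per_column"` — alternative readings kept
#'   behind this switch.
#' @return a data frame of class `subtype_calls` with columns `group`,
#'   `subtype` (or `"unclassified"`), `score`, `threshold`.
#' @export
classify_subtypes <- function(matrices, sd_type = c("population", "sample"),
                              pool = c("all", "per_matrix", "per_column")) {
  sd_type <- match.arg(sd_type)
  pool <- match.arg(pool)
  if (is.matrix(matrices)) matrices <- list(matrices)
  cols <- colnames(matrices[[1]])
  for (m in matrices)
    if (!identical(colnames(m), cols))
      stop2("score matrices must share an identical column set")
  psd <- function(x) if (sd_type == "sample") stats::sd(x)
                     else sqrt(mean((x - mean(x))^2))
  thr_of <- function(x) {
    if (length(x) < 2) stop2("fewer than 2 pooled entries; SD undefined")
    mean(x) + 2 * psd(x)
  }
  thr_all <- if (pool == "all") thr_of(unlist(lapply(matrices, as.vector)))
             else NULL
  thr_col <- if (pool == "per_column")
    vapply(cols, function(cc) thr_of(unlist(lapply(matrices, function(m) m[, cc]))),
           numeric(1)) else NULL
  out <- list()
  for (mi in seq_along(matrices)) {
    m <- matrices[[mi]]
    thr_m <- if (pool == "per_matrix") thr_of(as.vector(m)) else NULL
    for (i in seq_len(nrow(m))) {
      thr_i <- switch(pool, all = rep(thr_all, length(cols)),
                      per_matrix = rep(thr_m, length(cols)),
                      per_column = thr_col)
      cand <- which(m[i, ] > thr_i)
      if (length(cand)) {
        j <- cand[which.max(m[i, cand])]
        rec <- data.frame(group = rownames(m)[i], subtype = cols[j],
                          score = m[i, j], threshold = thr_i[j])
      } else {
        rec <- data.frame(group = rownames(m)[i], subtype = "unclassified",
                          score = max(m[i, ]), threshold = thr_i[which.max(m[i, ])])
      }
      out[[length(out) + 1]] <- rec
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  stopifnot(all(calls$subtype == "unclassified" |
                  calls$score > calls$threshold))
  class(calls) <- c("subtype_calls", "data.frame")
  calls
}
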