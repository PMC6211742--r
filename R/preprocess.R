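#' QC filter on genes then cells
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells, then
#' cells with at least `min_genes` detected genes among the retained genes.
#' Single pass, in that order. Removal counts are recorded in the
#' `"provenance"` attribute of the result.
#'
#' @param counts genes x cells count matrix.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @param min_genes minimum number of detected genes a cell must have.
#' @return the filtered count matrix with a `provenance` attribute.
#' @export
filter_matrix <- function(counts, min_cells = 3, min_genes = 200) {
  validate_counts(counts)
  keep_g <- row_detect(counts) >= min_cells
  m <- counts[keep_g, , drop = FALSE]
  keep_c <- col_detect(m) >= min_genes
  m <- m[, keep_c, drop = FALSE]
  if (nrow(m) == 0 || ncol(m) == 0)
    stop2("all genes or cells removed by QC filter")
  attr(m, "provenance") <- list(
    genes_removed = sum(!keep_g), cells_removed = sum(!keep_c),
    min_cells = min_cells, min_genes = min_genes)
  m
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a common library size and natural-log
#' transformed: `x_gi = ln(1 + c_gi * scale_factor / total_i)`.
#'
#' @param counts filtered genes x cells count matrix; no zero-total cells.
#' @param scale_factor common library size (default 1e4, the droplet
#'   convention).
#' @return a dense genes x cells matrix of normalized expression with a
#'   `provenance` attribute.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  totals <- col_totals(counts)
  if (any(totals == 0)) stop2("zero-total cells present; filter first")
  x <- as_dense(counts)
  x <- log1p(sweep(x, 2, scale_factor / totals, `*`))
  attr(x, "provenance") <- c(attr(counts, "provenance"),
                             list(scale_factor = scale_factor, log_base = "e"))
  x
}

#' Cell-cycle phase scores
#'
#' Per phase (S and G2M), the score of a cell is the mean normalized
#' expression of the phase gene set minus the mean of a control set of
#' genes drawn (seeded) from the same average-expression bins, the standard
#' binned-control enrichment score. Positive scores indicate phase-specific
#' expression above expression-matched background.
#'
#' @param norm normalized genes x cells matrix.
#' @param s_set,g2m_set character vectors of phase genes.
#' @param n_bins number of equal-frequency average-expression bins.
#' @param n_ctrl control genes drawn per phase gene.
#' @param seed integer seed for the control draws.
#' @return data frame with columns `barcode`, `S`, `G2M`.
#' @export
cell_cycle_score <- function(norm, s_set, g2m_set, n_bins = 25, n_ctrl = 50,
                             seed = 1L) {
  universe <- rownames(norm)
  gene_means <- rowMeans(norm)
  brk <- unique(stats::quantile(gene_means, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(gene_means, breaks = brk, include.lowest = TRUE, labels = FALSE)
  score_one <- function(set, tag) {
    set <- intersect(set, universe)
    if (!length(set)) stop2("no ", tag, " phase genes present in the matrix")
    ctrl <- character(0)
    for (g in set) {
      # sorted pool: control draws depend on gene identity, not row order
      pool <- sort(universe[bins == bins[match(g, universe)]])
      ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
    }
    ctrl <- unique(ctrl)
    colMeans(norm[set, , drop = FALSE]) - colMeans(norm[ctrl, , drop = FALSE])
  }
  set.seed(seed)
  s <- score_one(s_set, "S")
  g2m <- score_one(g2m_set, "G2M")
  data.frame(barcode = colnames(norm), S = s, G2M = g2m,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress technical covariates out of normalized expression
#'
#' Per gene, ordinary least squares of expression on
#' `[1, log10(total_umis), S, G2M]`; the output is the residual matrix.
#' Constant covariates are dropped with a warning so the design stays full
#' rank.
#'
#' @param norm normalized genes x cells matrix.
#' @param total_umis per-cell total UMI counts.
#' @param s,g2m per-cell cell-cycle scores; may be `NULL` to omit.
#' @return residual genes x cells matrix (same dimnames), with the list of
#'   regressed covariates in the `provenance` attribute.
#' @export
regress_covariates <- function(norm, total_umis, s = NULL, g2m = NULL) {
  nc <- ncol(norm)
  covs <- list(log10_total_umis = log10(total_umis))
  if (!is.null(s)) covs$S <- s
  if (!is.null(g2m)) covs$G2M <- g2m
  bad <- !vapply(covs, function(v) length(v) == nc && all(is.finite(v)),
                 logical(1))
  if (any(bad)) stop2("covariates must be complete and finite: ",
                      paste(names(covs)[bad], collapse = ", "))
  constant <- vapply(covs, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(covs)[constant], collapse = ", "), call. = FALSE)
    covs <- covs[!constant]
  }
  X <- cbind(intercept = rep(1, nc))
  for (nm in names(covs)) X <- cbind(X, covs[[nm]])
  colnames(X) <- c("intercept", names(covs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_ix <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning("dropping collinear covariate(s): ",
            paste(colnames(X)[drop_ix], collapse = ", "), call. = FALSE)
    X <- X[, -drop_ix, drop = FALSE]
    qrX <- qr(X)
  }
  # residuals for all genes at once: R = Y - Y X (X'X)^-1 X'
  res <- t(qr.resid(qrX, t(norm)))
  dimnames(res) <- dimnames(norm)
  attr(res, "provenance") <- c(attr(norm, "provenance"),
                               list(regressed = colnames(X)[-1]))
  res
}

#' Select highly variable genes
#'
#' Computes per-gene dispersion (variance / mean of the back-transformed
#' expression `expm1(x)`), bins genes by mean into `n_bins` equal-frequency
#' bins, z-scores the log dispersion within each bin, and returns genes
#' with z >= `z_cutoff`, capped at `max_genes` by descending z.
#'
#' @param norm normalized genes x cells matrix.
#' @param n_bins number of equal-frequency mean bins.
#' @param z_cutoff within-bin dispersion z-score threshold.
#' @param max_genes cap on the number of genes returned.
#' @return character vector of selected gene symbols (possibly empty, with
#'   a warning, for a constant matrix).
#' @export
select_variable_genes <- function(norm, n_bins = 20, z_cutoff = 1.0,
                                  max_genes = 2000) {
  if (nrow(norm) < n_bins)
    stop2("fewer genes (", nrow(norm), ") than bins (", n_bins, ")")
  ex <- expm1(norm)
  mu <- rowMeans(ex)
  v <- apply(ex, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  ok <- is.finite(disp) & disp > 0
  if (!any(ok)) {
    warning("no dispersion signal (constant matrix?); no genes selected",
            call. = FALSE)
    return(character(0))
  }
  ld <- log(disp[ok])
  m <- mu[ok]
  brk <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(m, breaks = brk, include.lowest = TRUE, labels = FALSE)
  z <- rep(NA_real_, length(ld))
  for (b in unique(bins)) {
    ix <- bins == b
    s <- stats::sd(ld[ix])
    z[ix] <- if (is.na(s) || s == 0) 0 else (ld[ix] - mean(ld[ix])) / s
  }
  sel <- rownames(norm)[ok][z >= z_cutoff]
  zz <- z[z >= z_cutoff]
  sel[order(zz, decreasing = TRUE)][seq_len(min(length(sel), max_genes))]
}

#' Per-gene z-scaling with outlier clipping
#'
#' Centers and scales each gene across cells and clips the result at
#' `+/- clip` to bound outlier leverage before PCA. Genes with zero
#' variance scale to 0.
#'
#' @param norm genes x cells matrix (typically residuals).
#' @param clip clipping bound (default 10).
#' @return the scaled, clipped matrix.
#' @export
scale_clip <- function(norm, clip = 10) {
  mu <- rowMeans(norm)
  sdv <- apply(norm, 1, stats::sd)
  sdv[sdv == 0] <- Inf
  z <- (norm - mu) / sdv
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}
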