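#' PCA embedding of cells
#'
#' Singular value decomposition of the cells x genes matrix (genes centered
#' across cells): component scores are projections onto the top right
#' singular directions, and explained-variance fractions come from the
#' squared singular values over the total variance.
#'
#' @param scaled genes x cells matrix (typically [scale_clip()] output).
#' @param n_components number of components, at most `min(genes, cells)`.
#' @return object of class `pca_result`: list with `scores` (cells x k),
#'   `var_frac` (length k, non-increasing) and `rotation` (genes x k).
#' @export
pca_embed <- function(scaled, n_components) {
  X <- t(as_dense(scaled))           # cells x genes
  if (n_components > min(dim(X)))
    stop2("n_components exceeds min(genes, cells)")
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  tot <- sum(sv$d^2)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 var_frac = if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k),
                 rotation = sv$v[, seq_len(k), drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA embedding:", nrow(x$scores), "cells x", ncol(x$scores),
      "components\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$var_frac, 8)), collapse = " "),
      if (length(x$var_frac) > 8) "...\n" else "\n")
  invisible(x)
}

#' Elbow selection of the number of components
#'
#' Automates the visual elbow plot: on the scree curve `(i, v_i)` the
#' selected `k` is the index with maximum perpendicular distance to the
#' chord from the first to the last point. Ties break toward smaller `k`.
#' A warning is emitted when the rule lands at an endpoint-adjacent index
#' (near-linear decay carries no elbow information).
#'
#' @param variance_fractions non-increasing explained-variance fractions,
#'   length >= 3.
#' @return integer `k` (1-based component index).
#' @export
select_elbow <- function(variance_fractions) {
  n <- length(variance_fractions)
  if (n < 3) stop2("need at least 3 variance fractions")
  d <- .chord_distance(seq_len(n), variance_fractions)
  k <- which.max(d)     # which.max takes the first maximum: ties -> smaller k
  span <- max(variance_fractions) - min(variance_fractions)
  if (max(d) <= 1e-9 * max(span, 1e-12) || k <= 1 || k >= n - 1)
    warning("elbow at an endpoint-adjacent index or near-linear scree ",
            "curve (k = ", k, ")", call. = FALSE)
  as.integer(k)
}

#' Shared-nearest-neighbor graph
#'
#' Builds the k-nearest-neighbor graph by Euclidean distance in embedding
#' space (each cell's neighborhood includes itself), weights each edge by
#' the Jaccard overlap of the two neighborhoods, and drops edges below the
#' prune threshold.
#'
#' @param embeddings cells x k numeric matrix (e.g. PCA scores).
#' @param k_neighbors neighborhood size.
#' @param prune minimum Jaccard weight retained (default 1/15).
#' @return a weighted undirected `igraph` with one vertex per cell.
#' @export
build_snn_graph <- function(embeddings, k_neighbors = 20, prune = 1 / 15) {
  n <- nrow(embeddings)
  if (n < k_neighbors + 1)
    stop2("need at least k_neighbors + 1 cells")
  d <- as.matrix(stats::dist(embeddings))
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k_neighbors)])
  # candidate edges: pairs sharing at least one neighborhood membership
  inv <- matrix(FALSE, n, n)
  for (i in seq_len(n)) inv[i, nb[[i]]] <- TRUE
  shared <- tcrossprod(inv * 1)            # |A intersect B|
  jac <- shared / (2 * k_neighbors - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(embeddings) %||% as.character(seq_len(n))
  g
}

#' Modularity clustering of a weighted graph
#'
#' Louvain-style multilevel modularity optimization with deterministic
#' seeded restarts; the partition with the highest modularity (at the
#' requested resolution) is kept. Isolated vertices become singleton
#' clusters.
#'
#' @param graph a weighted undirected `igraph`.
#' @param resolution modularity resolution parameter.
#' @param seed integer seed; restart seeds are derived from it.
#' @param restarts number of seeded restarts.
#' @return list with `membership` (0-based integer cluster ids, named by
#'   vertex), `K`, and `modularity` (standard resolution-1 modularity of
#'   the returned partition).
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 1L, restarts = 10L) {
  w <- igraph::E(graph)$weight
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("louvain", r)))
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    q <- igraph::modularity(graph, igraph::membership(cl), weights = w,
                            resolution = resolution)
    if (q > best_q) { best_q <- q; best <- cl }
  }
  mem <- igraph::membership(best) - 1L
  mod <- igraph::modularity(graph, mem + 1L, weights = w)
  list(membership = mem, K = length(unique(mem)), modularity = mod)
}

#' SNN modularity clustering of cells
#'
#' The full graph-clustering stage: SNN graph from the embedding, then
#' seeded modularity optimization.
#'
#' @inheritParams build_snn_graph
#' @param resolution modularity resolution.
#' @param seed integer seed.
#' @return object of class `cluster_result`: list with `cluster` (0-based
#'   per-cell ids named by barcode), `K`, `modularity`, and `labels`
#'   (per-cluster annotation, filled by [annotate_clusters()]).
#' @export
snn_cluster <- function(embeddings, k_neighbors = 20, prune = 1 / 15,
                        resolution = 1.0, seed = 1L) {
  g <- build_snn_graph(embeddings, k_neighbors, prune)
  if (any(igraph::degree(g) == 0))
    msg(sum(igraph::degree(g) == 0), " isolated cells form singleton clusters")
  # canonical vertex order: the partition depends on cell identities,
  # not on the order the cells arrive in
  g <- igraph::permute(g, rank(igraph::V(g)$name, ties.method = "first"))
  res <- cluster_graph(g, resolution, seed)
  mem <- res$membership[rownames(embeddings) %||%
                          as.character(seq_len(nrow(embeddings)))]
  structure(list(cluster = mem, K = res$K,
                 modularity = res$modularity, labels = NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("SNN clustering:", length(x$cluster), "cells in", x$K,
      "clusters (modularity", sprintf("%.3f", x$modularity), ")\n")
  if (!is.null(x$labels)) {
    cat("labels:\n")
    print(x$labels)
  }
  invisible(x)
}

#' t-SNE visualization coordinates
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of the cell
#' embedding, seeded for determinism. Visualization only; no downstream
#' computation consumes it.
#'
#' @param embeddings cells x k matrix (>= 5 cells).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; default adapts to small n.
#' @return cells x 2 coordinate matrix.
#' @export
tsne_embed <- function(embeddings, seed = 1L, perplexity = NULL) {
  n <- nrow(embeddings)
  if (n < 5) stop2("need at least 5 cells for t-SNE")
  if (is.null(perplexity)) perplexity <- max(1, min(30, floor((n - 1) / 3)))
  set.seed(seed)
  out <- Rtsne::Rtsne(embeddings, dims = 2, perplexity = perplexity,
                      pca = FALSE, theta = if (n < 200) 0.0 else 0.5,
                      max_iter = 500, check_duplicates = FALSE)$Y
  rownames(out) <- rownames(embeddings)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' Annotate clusters with marker panels
#'
#' Per cluster and marker panel, the panel score is the mean over panel
#' genes of the detection fraction (cells with expression > 0) in the
#' cluster. The cluster label is the argmax panel if its score reaches
#' `min_frac`, else `"unassigned"`; ties go to `"unassigned"` with a
#' warning. When per-cell metadata is supplied and one site exceeds 60% of
#' a cluster, the label is suffixed with that site (e.g.
#' `"myeloid/metastatic"`).
#'
#' @param norm normalized (or raw) genes x cells matrix; only detection
#'   (> 0) is used.
#' @param clusters a `cluster_result` or a per-cell cluster id vector named
#'   by barcode.
#' @param panels named list of marker gene vectors (one entry per cell
#'   type).
#' @param min_frac minimum panel score for assignment.
#' @param meta optional per-cell data frame with `barcode` and `site` for
#'   the site suffix.
#' @param site_frac majority fraction for the site suffix.
#' @return a `cluster_result` with `labels` (per-cluster) and
#'   `cell_labels` (per-cell) filled in, plus the `scores` matrix
#'   (clusters x panels).
#' @export
annotate_clusters <- function(norm, clusters, panels, min_frac = 0.25,
                              meta = NULL, site_frac = 0.6) {
  cl <- if (inherits(clusters, "cluster_result")) clusters$cluster else clusters
  if (is.null(names(cl))) names(cl) <- colnames(norm)
  ids <- sort(unique(cl))
  universe <- rownames(norm)
  pan <- lapply(panels, function(p) {
    known <- intersect(p, universe)
    if (length(known) < length(p))
      warning("marker genes absent from matrix skipped: ",
              paste(setdiff(p, universe), collapse = ", "), call. = FALSE)
    known
  })
  if (all(lengths(pan) == 0)) stop2("no panel gene overlaps the gene universe")
  det <- norm > 0
  scores <- matrix(0, length(ids), length(pan),
                   dimnames = list(as.character(ids), names(pan)))
  labels <- character(length(ids)); names(labels) <- as.character(ids)
  for (i in seq_along(ids)) {
    cells <- names(cl)[cl == ids[i]]
    for (j in seq_along(pan)) {
      if (!length(pan[[j]])) next
      scores[i, j] <- mean(rowMeans(det[pan[[j]], cells, drop = FALSE]))
    }
    best <- max(scores[i, ])
    top <- names(pan)[scores[i, ] == best]
    if (best < min_frac) {
      labels[i] <- "unassigned"
    } else if (length(top) > 1) {
      warning("tied panel scores for cluster ", ids[i], "; unassigned",
              call. = FALSE)
      labels[i] <- "unassigned"
    } else {
      labels[i] <- top
      if (!is.null(meta)) {
        sites <- meta$site[match(cells, meta$barcode)]
        tab <- table(sites) / length(sites)
        if (length(tab) && max(tab) > site_frac)
          labels[i] <- paste0(top, "/", names(tab)[which.max(tab)])
      }
    }
  }
  out <- if (inherits(clusters, "cluster_result")) clusters else
    structure(list(cluster = cl, K = length(ids), modularity = NA_real_),
              class = "cluster_result")
  out$labels <- labels
  out$scores <- scores
  out$cell_labels <- stats::setNames(labels[as.character(cl)], names(cl))
  out
}
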