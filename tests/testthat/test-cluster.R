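test_that("PCA recovers rank and reconstructs the centered matrix", {
  set.seed(5)
  u <- rnorm(30); v <- rnorm(40)
  r1 <- outer(u, v)
  dimnames(r1) <- list(paste0("g", 1:30), paste0("b", 1:40))
  pc <- pca_embed(r1, 3)
  expect_equal(pc$var_frac[1], 1, tolerance = 1e-8)
  expect_lt(sum(pc$var_frac[-1]), 1e-8)

  m <- matrix(rnorm(20 * 25), 20, 25,
              dimnames = list(paste0("g", 1:20), paste0("b", 1:25)))
  pc <- pca_embed(m, 20)
  rec <- pc$scores %*% t(pc$rotation)
  centered <- sweep(t(m), 2, colMeans(t(m)))
  expect_lt(norm(rec - centered, "F"), 1e-6)
  expect_true(all(diff(pc$var_frac) <= 1e-12))

  # sign flips leave pairwise distances unchanged
  flipped <- pc$scores
  flipped[, 2] <- -flipped[, 2]
  expect_equal(as.matrix(dist(flipped)), as.matrix(dist(pc$scores)),
               tolerance = 1e-10)
  expect_error(pca_embed(m, 26), "n_components")
})

test_that("elbow selection matches brute-force chord distances", {
  bf_elbow <- function(v) {
    n <- length(v); x <- seq_len(n)
    x1 <- 1; y1 <- v[1]; xn <- n; yn <- v[n]
    len <- sqrt((xn - x1)^2 + (yn - y1)^2)
    d <- abs((yn - y1) * x - (xn - x1) * v + xn * y1 - yn * x1) / len
    which.max(d)
  }
  v <- c(0.5, 0.049, 0.048, 0.0478, 0.0475, 0.047)
  expect_lte(select_elbow(v), 2)
  expect_equal(select_elbow(v), bf_elbow(v))
  for (s in 1:10) {
    set.seed(s)
    v <- sort(runif(15), decreasing = TRUE)
    expect_equal(suppressWarnings(select_elbow(v)), bf_elbow(v))
  }
  expect_warning(select_elbow(seq(0.5, 0.1, length.out = 8)), "near-linear")
  expect_error(select_elbow(c(0.9, 0.1)), "at least 3")
})

test_that("well-separated blobs give exactly two clusters, ARI 1", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    emb <- rbind(matrix(rnorm(100, 0, 1), 50), matrix(rnorm(100, 10, 1), 50))
    rownames(emb) <- paste0("c", 1:100)
    # neighborhoods sized to the 50-cell blobs: k well below the blob size
    # fragments dense blobs into higher-modularity chunks
    cl <- snn_cluster(emb, k_neighbors = 30, seed = s)
    cl$K == 2 && ari(cl$cluster, rep(1:2, each = 50)) == 1
  }, logical(1))
  expect_equal(sum(ok), 20)
})

test_that("achieved modularity beats the trivial partition and is exact on toys", {
  set.seed(1)
  emb <- rbind(matrix(rnorm(100, 0, 1), 50), matrix(rnorm(100, 10, 1), 50))
  cl <- snn_cluster(emb, seed = 1)
  g <- build_snn_graph(emb)
  triv <- igraph::modularity(g, rep(1, 100), weights = igraph::E(g)$weight)
  expect_gte(cl$modularity, triv)

  toys <- list(
    igraph::make_graph(~ A - B, B - C, C - A, D - E, E - F, F - D, C - D),
    igraph::disjoint_union(igraph::make_full_graph(4),
                           igraph::make_full_graph(4)),
    igraph::make_ring(8))
  for (gt in toys) {
    igraph::E(gt)$weight <- 1
    best <- max(vapply(all_partitions(igraph::vcount(gt)), function(p)
      igraph::modularity(gt, p, weights = igraph::E(gt)$weight), numeric(1)))
    expect_equal(cluster_graph(gt, seed = 3)$modularity, best,
                 tolerance = 1e-12)
  }
})

test_that("cluster labels are a partition, stable under cell permutation", {
  set.seed(9)
  emb <- rbind(matrix(rnorm(160, 0, 1), 80), matrix(rnorm(160, 8, 1), 80))
  rownames(emb) <- paste0("c", 1:160)
  cl <- snn_cluster(emb, seed = 2)
  expect_setequal(names(cl$cluster), rownames(emb))
  expect_equal(sort(unique(cl$cluster)), 0:(cl$K - 1))
  perm <- sample(160)
  cl2 <- snn_cluster(emb[perm, ], seed = 2)
  expect_equal(ari(cl$cluster[rownames(emb)], cl2$cluster[rownames(emb)]), 1)
})

test_that("t-SNE is seed-deterministic and separates blobs", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(60, 0, 1), 30), matrix(rnorm(60, 10, 1), 30))
  rownames(emb) <- paste0("c", 1:60)
  y1 <- tsne_embed(emb, seed = 7)
  y2 <- tsne_embed(emb, seed = 7)
  expect_identical(y1, y2)
  c1 <- colMeans(y1[1:30, ]); c2 <- colMeans(y1[31:60, ])
  spread <- max(sqrt(rowSums(sweep(y1[1:30, ], 2, c1)^2)),
                sqrt(rowSums(sweep(y1[31:60, ], 2, c2)^2)))
  expect_gt(sqrt(sum((c1 - c2)^2)), spread)
  expect_error(tsne_embed(emb[1:4, ]), "at least 5")
})

test_that("marker panels annotate clusters by detection fractions", {
  nm <- matrix(0, 6, 30,
               dimnames = list(c("EPCAM", "KRT8", "CD3E", "PTPRC", "x1", "x2"),
                               paste0("b", 1:30)))
  nm[c("EPCAM", "KRT8"), 1:15] <- 1
  nm[c("CD3E", "PTPRC"), 16:25] <- 1
  cl <- setNames(c(rep(0, 15), rep(1, 10), rep(2, 5)), colnames(nm))
  panels <- list(epithelial = c("EPCAM", "KRT8"),
                 lymphocyte = c("CD3E", "PTPRC"))
  out <- annotate_clusters(nm, cl, panels, min_frac = 0.25)
  expect_equal(unname(out$labels[c("0", "1", "2")]),
               c("epithelial", "lymphocyte", "unassigned"))
  # tie between identical panels -> unassigned with a warning
  expect_warning(
    tie <- annotate_clusters(nm, cl, list(a = "EPCAM", b = "KRT8")),
    "tied")
  expect_equal(unname(tie$labels["0"]), "unassigned")
  # unknown panel genes are skipped with a warning
  expect_warning(annotate_clusters(nm, cl,
                                   list(epithelial = c("EPCAM", "absent"))),
                 "absent")
})

test_that("true-type clusters are annotated with their generating panel", {
  ch <- generate_cohort(balanced_cohort_config(seed = 3))
  nm <- log_normalize(filter_matrix(ch$counts, 0, 0))
  truth <- ch$truth$cell_type[match(colnames(nm), ch$truth$barcode)]
  panels <- lapply(ch$truth$markers, function(ix) rownames(ch$counts)[ix])
  out <- annotate_clusters(nm, setNames(match(truth, names(panels)) - 1,
                                        colnames(nm)), panels)
  agreement <- mean(out$labels[as.character(0:5)] == names(panels))
  expect_gte(agreement, 0.95)
})

test_that("site suffix is appended for site-dominated clusters", {
  nm <- matrix(1, 2, 10, dimnames = list(c("EPCAM", "KRT8"), paste0("b", 1:10)))
  cl <- setNames(rep(0, 10), colnames(nm))
  meta <- data.frame(barcode = colnames(nm),
                     site = c(rep("metastatic", 8), rep("primary", 2)))
  out <- annotate_clusters(nm, cl, list(epithelial = c("EPCAM", "KRT8")),
                           meta = meta)
  expect_equal(unname(out$labels["0"]), "epithelial/metastatic")
})
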