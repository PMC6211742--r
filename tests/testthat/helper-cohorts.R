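# shared fixtures and mini-pipelines used across test files

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# balanced six-type cohort satisfying the recovery preconditions
# (>= 40 cells per type, marker effect 2)
balanced_cohort_config <- function(seed, n_genes = 1000, n_per_sample = 180,
                                   n_marker = 60) {
  types <- names(composition_preset("primary"))
  markers <- split(seq_len(n_marker * 6), rep(1:6, each = n_marker))
  names(markers) <- types
  samples <- data.frame(sample_id = c("S1", "S2"),
                        patient_id = c("P1", "P2"),
                        site = "primary", grade = "HGSOC",
                        n_cells = c(n_per_sample, n_per_sample))
  cohort_config(n_genes = n_genes, cell_types = markers, samples = samples,
                composition = stats::setNames(rep(1 / 6, 6), types),
                seed = seed)
}

# standard preprocessing + clustering path used by the recovery tests
cluster_cohort <- function(cohort, seed) {
  f <- filter_matrix(cohort$counts, 3, 100)
  nm <- log_normalize(f)
  mt <- cell_metadata(f)
  res <- regress_covariates(nm, mt$total_umis)
  hvg <- select_variable_genes(nm)
  pc <- pca_embed(scale_clip(res[hvg, , drop = FALSE]), 20)
  k <- max(select_elbow(pc$var_frac), 5)
  cl <- snn_cluster(pc$scores[, seq_len(k), drop = FALSE],
                    seed = derive_seed(seed, "cl"))
  truth <- cohort$truth$cell_type[match(names(cl$cluster),
                                        cohort$truth$barcode)]
  list(clusters = cl, truth = truth, norm = nm, hvg = hvg)
}

# small ZINB null pair, normalized without any filtering, for DE tests
null_pair_norm <- function(seed, n_genes, n_per_group) {
  np <- generate_null_pair(cohort_config(n_genes = n_genes, seed = seed),
                           n_per_group)
  list(pair = np, norm = log_normalize(filter_matrix(np$counts, 0, 0)),
       a = np$truth$barcode[np$groups == "A"],
       b = np$truth$barcode[np$groups == "B"])
}

# exhaustive two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood rule)
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force knee: max perpendicular distance to the chord in log-log
knee_bruteforce <- function(totals) {
  tot <- sort(totals[totals > 0], decreasing = TRUE)
  x <- log10(seq_along(tot)); y <- log10(tot)
  x1 <- x[1]; y1 <- y[1]; xn <- x[length(x)]; yn <- y[length(y)]
  len <- sqrt((xn - x1)^2 + (yn - y1)^2)
  d <- abs((yn - y1) * x - (xn - x1) * y + xn * y1 - yn * x1) / len
  knee <- max(which(d >= max(d) - 1e-12))
  list(knee_rank = knee, umi_threshold = tot[knee],
       retained = sum(tot >= tot[knee]))
}

# all set partitions of n labelled nodes (for exhaustive modularity)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1))
    for (k in seq_len(max(p) + 1L))
      out[[length(out) + 1L]] <- c(p, k)
  out
}
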