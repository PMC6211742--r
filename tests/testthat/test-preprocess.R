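mk_counts <- function(m) {
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("b%03d", seq_len(ncol(m))))
  m
}

test_that("gene then cell filtering honours thresholds at the boundary", {
  # gene detected in 2 of 5 cells is removed at min_cells = 3
  m <- mk_counts(rbind(c(1, 2, 0, 0, 0),
                       c(1, 1, 1, 0, 0),
                       c(2, 2, 2, 2, 2),
                       c(0, 1, 1, 1, 1),
                       c(3, 0, 3, 3, 3)))
  f <- filter_matrix(m, min_cells = 3, min_genes = 1)
  expect_false("g001" %in% rownames(f))
  expect_equal(nrow(f), 4)

  # cell with 199 detected genes after gene filtering removed, 200 retained
  set.seed(1)
  big <- matrix(1L, 250, 5)
  big[201:250, 1] <- 0L   # cell 1: 200 detected
  big[200:250, 2] <- 0L   # cell 2: 199 detected
  big <- mk_counts(big)
  f <- filter_matrix(big, min_cells = 1, min_genes = 200)
  expect_true("b001" %in% colnames(f))
  expect_false("b002" %in% colnames(f))

  expect_error(filter_matrix(mk_counts(matrix(0L, 4, 4))), "removed")
})

test_that("filtering equals the brute-force two-pass recount", {
  set.seed(7)
  m <- mk_counts(matrix(rpois(300 * 300, 0.08), 300, 300))
  f <- filter_matrix(m, min_cells = 4, min_genes = 10)
  keep_g <- rowSums(m > 0) >= 4
  m2 <- m[keep_g, ]
  keep_c <- colSums(m2 > 0) >= 10
  expect_equal(as.matrix(f), m2[, keep_c], ignore_attr = TRUE)
  prov <- attr(f, "provenance")
  expect_equal(prov$genes_removed, sum(!keep_g))
  expect_equal(prov$cells_removed, sum(!keep_c))
  # idempotence
  f2 <- filter_matrix(f, min_cells = 4, min_genes = 10)
  expect_equal(as.matrix(f2), as.matrix(f), ignore_attr = TRUE)
  expect_equal(attr(f2, "provenance")$genes_removed, 0)
  expect_equal(attr(f2, "provenance")$cells_removed, 0)
})

test_that("log-normalization has the stated closed form and invariances", {
  m <- mk_counts(rbind(c(100, 50), c(9900, 50)))
  x <- log_normalize(m, scale_factor = 10000)
  expect_equal(x["g001", "b001"], log(101), tolerance = 1e-12)
  expect_equal(log_normalize(mk_counts(rbind(c(0, 1), c(5, 1))))[1, 1], 0)
  # per-cell scale invariance: doubling a cell's counts changes nothing
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(log_normalize(m2)[, 1], x[, 1])
  # monotone within a cell
  ord <- order(m[, 1])
  expect_true(all(diff(x[ord, 1]) >= 0))
  expect_error(log_normalize(mk_counts(cbind(c(0, 0)))), "zero-total")
})

test_that("cell-cycle scores behave as binned-control enrichments", {
  set.seed(11)
  nm <- mk_counts(matrix(abs(rnorm(400 * 60, 1, 0.3)), 400, 60))
  # a set of genes that is identically zero scores <= 0
  nm[1:10, ] <- 0
  sc <- cell_cycle_score(nm, rownames(nm)[1:10], rownames(nm)[380:400],
                         seed = 5)
  expect_true(all(sc$S <= 0))
  # permuting gene order leaves scores unchanged
  perm <- sample(nrow(nm))
  sc2 <- cell_cycle_score(nm[perm, ], rownames(nm)[1:10],
                          rownames(nm)[380:400], seed = 5)
  expect_equal(sc$S, sc2$S)
  expect_equal(sc$G2M, sc2$G2M)
  expect_error(cell_cycle_score(nm, "absent_gene", rownames(nm)[2], seed = 1),
               "phase genes")
})

test_that("spiked phase genes raise the scores of spiked cells", {
  wins <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_genes = 300, seed = s,
                         samples = data.frame(sample_id = "S",
                                              patient_id = "P",
                                              site = "primary",
                                              grade = "HGSOC", n_cells = 120))
    ch <- generate_cohort(cfg)
    sgenes <- names(sort(ch$truth$lambda, decreasing = TRUE))[1:20]
    half <- ch$meta$barcode[1:60]
    sp <- spike_signature(ch, sgenes, half, 2)
    nm <- log_normalize(filter_matrix(sp$counts, 0, 0))
    sc <- cell_cycle_score(nm, sgenes, sgenes, seed = s)
    mean(sc$S[sc$barcode %in% half]) > mean(sc$S[!sc$barcode %in% half])
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("covariate regression solves the least-squares problem", {
  set.seed(3)
  n <- 80
  nm <- mk_counts(matrix(rnorm(50 * n), 50, n))
  tot <- exp(rnorm(n, 8, 0.5))
  s <- rnorm(n); g2m <- rnorm(n)
  res <- regress_covariates(nm, tot, s, g2m)
  X <- cbind(1, log10(tot), s, g2m)
  # residuals orthogonal to every design column, zero mean per gene
  dots <- abs(res %*% X)
  expect_lt(max(dots), 1e-6)
  expect_lt(max(abs(rowMeans(res))), 1e-8)
  # matches lm() per gene
  r1 <- residuals(lm(nm[1, ] ~ log10(tot) + s + g2m))
  expect_equal(unname(res[1, ]), unname(r1), tolerance = 1e-10)

  # expression exactly linear in the covariate leaves ~0 residuals
  lin <- mk_counts(matrix(rep(2 + 3 * log10(tot), 5), 5, n, byrow = TRUE))
  res_lin <- regress_covariates(lin, tot)
  expect_lt(max(abs(res_lin)), 1e-8)

  # constant covariate is dropped with a warning
  expect_warning(regress_covariates(nm, rep(10, n), s, g2m), "constant")
  expect_error(regress_covariates(nm, c(tot[-1], NA), s, g2m), "finite")
})

test_that("variable-gene selection is calibrated and recovers structure", {
  # i.i.d. genes: selected fraction ~ P(Z >= 1)
  set.seed(17)
  m <- mk_counts(matrix(rnbinom(600 * 300, size = 2, mu = 1), 600, 300))
  nm <- log_normalize(filter_matrix(m, 0, 0))
  sel <- select_variable_genes(nm, n_bins = 20, z_cutoff = 1)
  expect_lt(abs(length(sel) / nrow(nm) - pnorm(1, lower.tail = FALSE)), 0.05)

  # a bimodal gene across two cell types is selected nearly always
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    flat <- matrix(rnbinom(200 * 200, size = 2, mu = 1), 200, 200)
    flat[1, ] <- c(rnbinom(100, size = 2, mu = 8), rnbinom(100, size = 2, mu = 0.2))
    nm <- log_normalize(filter_matrix(mk_counts(flat), 0, 0))
    "g001" %in% select_variable_genes(nm)
  }, logical(1))
  expect_gte(sum(hits), 19)

  expect_error(select_variable_genes(nm[1:10, ], n_bins = 20), "fewer genes")
  cst <- mk_counts(matrix(1, 30, 30))
  expect_warning(out <- select_variable_genes(log_normalize(cst), n_bins = 5),
                 "no dispersion")
  expect_length(out, 0)
})

test_that("scaling clips symmetric outliers and centers genes", {
  set.seed(2)
  nm <- mk_counts(matrix(rnorm(20 * 50), 20, 50))
  nm[1, 1] <- 1e4
  z <- scale_clip(nm, clip = 10)
  expect_lte(max(z), 10)
  expect_gte(min(z), -10)
  expect_lt(max(abs(rowMeans(z[-1, ]))), 1e-12)
})
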