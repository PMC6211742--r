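test_that("configuration contracts are enforced", {
  expect_error(cohort_config(theta = -1), "theta")
  expect_error(cohort_config(composition = c(cellA = 0.5)), "sum to 1")
  samples <- data.frame(sample_id = "S", patient_id = "P", site = "primary",
                        grade = "HGSOC", n_cells = 0)
  expect_error(cohort_config(samples = samples), "positive")
  expect_error(cohort_config(n_genes = 10,
                             cell_types = list(a = c(5L, 11L))),
               "out of range")
})

test_that("generation is deterministic and counts are valid", {
  cfg <- cohort_config(n_genes = 100, seed = 9)
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_identical(as.matrix(ch1$counts), as.matrix(ch2$counts))
  expect_silent(validate_counts(ch1$counts))
})

test_that("Poisson limit: no dropout, huge theta gives mean s*lambda", {
  samples <- data.frame(sample_id = "S", patient_id = "P", site = "primary",
                        grade = "HGSOC", n_cells = 600)
  cfg <- cohort_config(n_genes = 200, samples = samples,
                       theta = 1e6, dropout_coeffs = c(-30, 0),
                       libsize_logparams = c(0, 0), seed = 4)
  ch <- generate_cohort(cfg)
  lam <- ch$truth$lambda
  m <- Matrix::rowMeans(ch$counts)
  se <- sqrt(lam / ncol(ch$counts))    # Poisson variance
  frac_in <- mean(abs(m - lam) <= 3 * se)
  expect_gte(frac_in, 0.97)
})

test_that("zero fractions match the closed-form ZINB zero probability", {
  samples <- data.frame(sample_id = "S", patient_id = "P", site = "primary",
                        grade = "HGSOC", n_cells = 1000)
  cfg <- cohort_config(n_genes = 150, samples = samples, seed = 6)
  ch <- generate_cohort(cfg)
  tr <- ch$truth
  mu <- tr$lambda %o% tr$s[!is.na(tr$s)]
  pii <- stats::plogis(tr$dropout_coeffs[1] + tr$dropout_coeffs[2] * log(mu))
  p0 <- rowMeans(zinb_zero_prob(mu, tr$theta, pii))
  obs <- Matrix::rowMeans(ch$counts == 0)
  se <- sqrt(p0 * (1 - p0) / ncol(ch$counts))
  frac_in <- mean(abs(obs - p0) <= 3 * pmax(se, 1e-4))
  expect_gte(frac_in, 0.97)
})

test_that("empirical ZINB moments match theory on large draws", {
  samples <- data.frame(sample_id = "S", patient_id = "P", site = "primary",
                        grade = "HGSOC", n_cells = 10000)
  cfg <- cohort_config(n_genes = 20, samples = samples,
                       libsize_logparams = c(0, 0), seed = 8)
  ch <- generate_cohort(cfg)
  tr <- ch$truth
  mu <- tr$lambda
  pii <- stats::plogis(tr$dropout_coeffs[1] + tr$dropout_coeffs[2] * log(mu))
  m_th <- (1 - pii) * mu
  v_th <- (1 - pii) * mu * (1 + mu / tr$theta + pii * mu)
  m_obs <- Matrix::rowMeans(ch$counts)
  v_obs <- apply(as.matrix(ch$counts), 1, var)
  expect_lt(max(abs(m_obs - m_th) / pmax(m_th, 0.05)), 0.10)
  expect_lt(max(abs(v_obs - v_th) / pmax(v_th, 0.05)), 0.20)
})

test_that("site composition presets are realized within multinomial error", {
  types <- names(composition_preset("primary"))
  markers <- stats::setNames(lapply(1:6, function(i) integer(0)), types)
  samples <- data.frame(sample_id = c("PRI", "MET"),
                        patient_id = "P", site = c("primary", "metastatic"),
                        grade = "HGSOC", n_cells = c(400, 400))
  comp <- rbind(composition_preset("primary"), composition_preset("metastatic"))
  rownames(comp) <- samples$sample_id
  ch <- generate_cohort(cohort_config(n_genes = 50, cell_types = markers,
                                      samples = samples, composition = comp,
                                      seed = 12))
  tt <- table(ch$meta$sample_id, ch$truth$cell_type[match(ch$meta$barcode,
                                                          ch$truth$barcode)])
  for (sid in c("PRI", "MET")) {
    p_hat <- tt[sid, types] / 400
    p_true <- comp[sid, types]
    se <- sqrt(p_true * (1 - p_true) / 400)
    expect_true(all(abs(p_hat - p_true) <= 3 * pmax(se, 1e-3)),
                info = sid)
  }
  # the preset fractions themselves
  expect_equal(composition_preset("primary")[["epithelial"]], 0.683)
  expect_equal(composition_preset("metastatic")[["lymphocyte"]], 0.662)
})

test_that("null pairs are identically distributed and deterministic", {
  cfg <- cohort_config(n_genes = 40, seed = 21)
  np1 <- generate_null_pair(cfg, 50)
  np2 <- generate_null_pair(cfg, 50)
  expect_identical(as.matrix(np1$counts), as.matrix(np2$counts))
  expect_equal(as.vector(table(np1$groups)), c(50, 50))
  expect_error(generate_null_pair(cfg, 1), ">= 2")
})

test_that("spike_signature multiplies means and is seed-deterministic", {
  cfg <- cohort_config(n_genes = 120, seed = 31,
                       samples = data.frame(sample_id = "S", patient_id = "P",
                                            site = "primary", grade = "HGSOC",
                                            n_cells = 400))
  ch <- generate_cohort(cfg)
  genes <- names(sort(ch$truth$lambda, decreasing = TRUE))[1:50]
  target <- ch$meta$barcode[1:100]
  other <- setdiff(ch$meta$barcode, target)

  sp0a <- spike_signature(ch, genes, target, 0)
  sp0b <- spike_signature(ch, genes, target, 0)
  expect_identical(as.matrix(sp0a$counts), as.matrix(sp0b$counts))

  sp2 <- spike_signature(ch, genes, target, 2)
  m_in <- Matrix::rowMeans(sp2$counts[genes, target])
  m_out <- Matrix::rowMeans(sp2$counts[genes, other])
  ratio <- sum(m_in) / sum(m_out)   # aggregate over genes for stable SE
  expect_lt(abs(ratio - 4), 0.5)
  # untouched entries identical
  expect_identical(as.matrix(sp2$counts[setdiff(rownames(ch$counts), genes), ]),
                   as.matrix(ch$counts[setdiff(rownames(ch$counts), genes), ]))

  expect_error(spike_signature(ch, "nope", target, 1), "unknown genes")
  expect_error(spike_signature(ch, genes, "nope", 1), "unknown cells")
  expect_error(spike_signature(ch, genes, character(0), 1), "empty")
})
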