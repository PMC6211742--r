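#' Site-specific cell-type composition presets
#'
#' Canonical composition vectors over six cell types (epithelial,
#' lymphocyte, myeloid, fibroblast, stromal, endothelial) emulating serous
#' ovarian tumor samples: primary tumors dominated by epithelial cells
#' (68.3% epithelial vs 11.1% lymphocytes), omental metastases dominated by
#' immune cells (66.2% lymphocytes vs 10.5% epithelial), and normal ovary
#' dominated by fibroblasts and stromal cells.
#'
#' @param site one of `"primary"`, `"metastatic"`, `"normal"`.
#' @return a named numeric vector summing to 1.
#' @export
composition_preset <- function(site = c("primary", "metastatic", "normal")) {
  site <- match.arg(site)
  switch(site,
    primary = c(epithelial = 0.683, lymphocyte = 0.111, myeloid = 0.060,
                fibroblast = 0.060, stromal = 0.050, endothelial = 0.036),
    metastatic = c(epithelial = 0.105, lymphocyte = 0.662, myeloid = 0.080,
                   fibroblast = 0.070, stromal = 0.050, endothelial = 0.033),
    normal = c(epithelial = 0.000, lymphocyte = 0.100, myeloid = 0.050,
               fibroblast = 0.400, stromal = 0.350, endothelial = 0.100))
}

#' Cohort simulation configuration
#'
#' Assembles and validates the configuration of the zero-inflated
#' negative-binomial (ZINB) cohort generator. For cell `i` of type `t` the
#' expected count of gene `g` is `mu_gi = s_i * lambda_g * 2^f_gt`, where
#' `lambda_g` is a log-normal baseline rate, `s_i` a log-normal library-size
#' factor, and `f_gt` the marker log2 effect. Counts are drawn
#' `ZINB(mu_gi, theta_g, pi_gi)` with mean-dependent structural-zero
#' probability `logit pi_gi = a + b * log(mu_gi)`.
#'
#' Defaults are sized to shallow droplet data (a few hundred UMIs and a few
#' hundred detected genes per cell) so the standard QC thresholds bind
#' realistically.
#'
#' @param n_genes number of genes.
#' @param cell_types named list: per type, an integer vector of marker gene
#'   indices. May be `NULL` for a single unstructured type.
#' @param marker_log2_effect marker effect `f_gt` applied to each type's
#'   marker genes (scalar, log2 scale).
#' @param samples data frame with columns `sample_id`, `patient_id`, `site`,
#'   `grade`, `n_cells`.
#' @param composition matrix (samples x types) of composition vectors, each
#'   row summing to 1; or a single named vector recycled for all samples.
#' @param baseline_mean_logparams `c(meanlog, sdlog)` of `lambda_g`.
#' @param theta NB dispersion, scalar (shared) or length `n_genes`.
#' @param dropout_coeffs `c(a, b)` of the logit-linear dropout model.
#' @param libsize_logparams `c(meanlog, sdlog)` of `s_i`.
#' @param ambient_barcodes `list(n =, mean_umis =)`: extra ambient (empty
#'   droplet) barcodes whose counts are Poisson with library-proportional
#'   rates, for knee-calling tests.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1500,
                          cell_types = NULL,
                          marker_log2_effect = 2,
                          samples = data.frame(sample_id = "S1",
                                               patient_id = "P1",
                                               site = "primary",
                                               grade = "HGSOC",
                                               n_cells = 200),
                          composition = NULL,
                          baseline_mean_logparams = c(-1, 1),
                          theta = 2,
                          dropout_coeffs = c(-1.5, -0.5),
                          libsize_logparams = c(0, 0.3),
                          ambient_barcodes = list(n = 0, mean_umis = 15),
                          seed = 1L) {
  if (is.null(cell_types)) cell_types <- list(cellA = integer(0))
  types <- names(cell_types)
  if (is.null(composition)) {
    composition <- matrix(1 / length(types), nrow(samples), length(types),
                          dimnames = list(samples$sample_id, types))
  }
  if (is.null(dim(composition))) {
    composition <- matrix(composition, nrow(samples), length(composition),
                          byrow = TRUE,
                          dimnames = list(samples$sample_id, names(composition)))
  }
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              marker_log2_effect = marker_log2_effect, samples = samples,
              composition = composition,
              baseline_mean_logparams = baseline_mean_logparams,
              theta = theta, dropout_coeffs = dropout_coeffs,
              libsize_logparams = libsize_logparams,
              ambient_barcodes = ambient_barcodes, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$theta <= 0)) stop2("dispersion theta must be > 0")
  if (any(cfg$samples$n_cells <= 0)) stop2("n_cells must be positive")
  if (!setequal(colnames(cfg$composition), names(cfg$cell_types)))
    stop2("composition columns must match cell type names")
  rs <- rowSums(cfg$composition)
  if (any(abs(rs - 1) > 1e-8))
    stop2("composition rows must sum to 1 (max deviation ",
          format(max(abs(rs - 1))), ")")
  if (any(cfg$composition < 0)) stop2("composition entries must be >= 0")
  mk <- unlist(cfg$cell_types)
  if (length(mk) && (min(mk) < 1 || max(mk) > cfg$n_genes))
    stop2("marker gene indices out of range")
  invisible(cfg)
}

#' Default six-type tumor cohort configuration
#'
#' Six cell types with 60 disjoint marker genes each (marker log2 effect 2),
#' emulating the broad lineage expression programs that separate epithelial,
#' immune and stromal populations; four samples (two primaries, one omental
#' metastasis, one normal ovary) with the site composition presets, ~800
#' cells and 1500 genes.
#'
#' @param seed integer seed.
#' @param n_cells_per_sample optional length-4 override of sample sizes.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L,
                                  n_cells_per_sample = c(250, 200, 250, 100)) {
  types <- names(composition_preset("primary"))
  markers <- split(1:(60 * length(types)),
                   rep(seq_along(types), each = 60))
  names(markers) <- types
  samples <- data.frame(
    sample_id = c("P1-P", "P1-M", "P2-P", "P2-N"),
    patient_id = c("P1", "P1", "P2", "P2"),
    site = c("primary", "metastatic", "primary", "normal"),
    grade = c("HGSOC", "HGSOC", "LGSOC", "normal"),
    n_cells = n_cells_per_sample,
    stringsAsFactors = FALSE
  )
  comp <- rbind(composition_preset("primary"),
                composition_preset("metastatic"),
                composition_preset("primary"),
                composition_preset("normal"))
  rownames(comp) <- samples$sample_id
  cohort_config(n_genes = 1500, cell_types = markers,
                samples = samples, composition = comp, seed = seed)
}

#' Generate a synthetic ZINB cohort
#'
#' Draws a UMI count matrix, per-cell metadata and the generative ground
#' truth from a [cohort_config()]. Deterministic given the config seed.
#'
#' @param config a `cohort_config`.
#' @return a list of class `synthetic_cohort` with elements `counts`
#'   (sparse genes x cells), `meta` (cells only, no ambient barcodes) and
#'   `truth` (per-barcode true type incl. ambient, `lambda`, `theta`,
#'   `effects` genes x types log2 matrix, per-cell `s`, dropout
#'   coefficients, seed).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(ng))
  types <- names(config$cell_types)

  lambda <- stats::rlnorm(ng, config$baseline_mean_logparams[1],
                          config$baseline_mean_logparams[2])
  theta <- if (length(config$theta) == 1) rep(config$theta, ng) else config$theta
  effects <- matrix(0, ng, length(types), dimnames = list(genes, types))
  for (t in seq_along(types)) {
    idx <- config$cell_types[[t]]
    if (length(idx)) effects[idx, t] <- config$marker_log2_effect
  }

  samples <- config$samples
  cell_type <- character(0); sample_of <- character(0)
  for (j in seq_len(nrow(samples))) {
    comp <- config$composition[samples$sample_id[j], types]
    tt <- sample(types, samples$n_cells[j], replace = TRUE, prob = comp)
    cell_type <- c(cell_type, tt)
    sample_of <- c(sample_of, rep(samples$sample_id[j], samples$n_cells[j]))
  }
  nc <- length(cell_type)
  barcodes <- sprintf("%s_c%04d", sample_of, stats::ave(seq_len(nc), sample_of,
                                                        FUN = seq_along))
  s <- stats::rlnorm(nc, config$libsize_logparams[1], config$libsize_logparams[2])
  tix <- match(cell_type, types)

  y <- .draw_zinb_matrix(lambda, s, effects[, tix, drop = FALSE], theta,
                         config$dropout_coeffs)

  # ambient barcodes: Poisson soup with library-proportional gene rates
  amb <- config$ambient_barcodes
  if ((amb$n %||% 0) > 0) {
    rate <- amb$mean_umis * lambda / sum(lambda)
    ya <- matrix(stats::rpois(ng * amb$n, rate), ng, amb$n)
    amb_bc <- sprintf("AMB_%05d", seq_len(amb$n))
    y <- cbind(y, ya)
    barcodes <- c(barcodes, amb_bc)
  }
  dimnames(y) <- list(genes, barcodes)
  counts <- Matrix::Matrix(y, sparse = TRUE)

  is_cell <- seq_len(ncol(counts)) <= nc
  meta <- cell_metadata(counts[, is_cell, drop = FALSE],
                        data.frame(barcode = barcodes[is_cell],
                                   sample_id = sample_of,
                                   stringsAsFactors = FALSE))
  meta <- merge(meta, samples[, c("sample_id", "patient_id", "site", "grade")],
                by = "sample_id", sort = FALSE)
  meta <- meta[match(barcodes[is_cell], meta$barcode), ]
  rownames(meta) <- NULL

  truth <- list(
    barcode = barcodes,
    cell_type = c(cell_type, rep("ambient", ncol(counts) - nc)),
    lambda = stats::setNames(lambda, genes),
    theta = stats::setNames(theta, genes),
    effects = effects,
    s = stats::setNames(c(s, rep(NA_real_, ncol(counts) - nc)), barcodes),
    type_index = stats::setNames(c(tix, rep(NA_integer_, ncol(counts) - nc)),
                                 barcodes),
    dropout_coeffs = config$dropout_coeffs,
    markers = config$cell_types,
    seed = config$seed
  )
  structure(list(counts = counts, meta = meta, truth = truth),
            class = "synthetic_cohort")
}

# vectorized ZINB draw; effects_by_cell is genes x cells log2 effect matrix
.draw_zinb_matrix <- function(lambda, s, effects_by_cell, theta, dropout) {
  ng <- length(lambda); nc <- length(s)
  mu <- (lambda %o% s) * 2^effects_by_cell
  pii <- stats::plogis(dropout[1] + dropout[2] * log(mu))
  z <- stats::rbinom(ng * nc, 1L, as.vector(pii))
  yy <- stats::rnbinom(ng * nc, size = rep(theta, nc), mu = as.vector(mu))
  matrix(ifelse(z == 1L, 0L, yy), ng, nc)
}

#' Generate a matched null pair for DE calibration
#'
#' Draws two groups of cells of a single type from identical generative
#' parameters, so any differential-expression signal between them is a
#' false positive by construction.
#'
#' @param config a `cohort_config` supplying the gene-level parameters
#'   (cell types and samples in it are ignored).
#' @param n_per_group cells per group (>= 2).
#' @return list with `counts`, `groups` (factor `A`/`B`), `truth`.
#' @export
generate_null_pair <- function(config, n_per_group) {
  if (n_per_group < 2) stop2("n_per_group must be >= 2")
  samples <- data.frame(sample_id = c("A", "B"), patient_id = c("A", "B"),
                        site = "primary", grade = "HGSOC",
                        n_cells = c(n_per_group, n_per_group),
                        stringsAsFactors = FALSE)
  cfg <- cohort_config(n_genes = config$n_genes,
                       cell_types = list(cellA = integer(0)),
                       samples = samples,
                       baseline_mean_logparams = config$baseline_mean_logparams,
                       theta = config$theta,
                       dropout_coeffs = config$dropout_coeffs,
                       libsize_logparams = config$libsize_logparams,
                       seed = config$seed)
  ch <- generate_cohort(cfg)
  list(counts = ch$counts,
       groups = factor(ch$meta$sample_id, levels = c("A", "B")),
       truth = ch$truth)
}

#' Spike a gene signature into a cell group
#'
#' Regenerates the counts of the given genes in the given cells with their
#' ZINB means multiplied by `2^log2_effect`, leaving all other entries
#' untouched. Deterministic given `seed`; with `log2_effect = 0` the spiked
#' entries are redrawn from the unchanged distribution.
#'
#' @param cohort a `synthetic_cohort`.
#' @param genes character vector of gene symbols to spike.
#' @param cells character vector of target cell barcodes (non-ambient).
#' @param log2_effect log2 fold change applied to the means.
#' @param seed integer; defaults to a seed derived from the cohort's.
#' @return the modified `synthetic_cohort`; `truth$spike` records the spike.
#' @export
spike_signature <- function(cohort, genes, cells, log2_effect, seed = NULL) {
  tr <- cohort$truth
  gi <- match(genes, rownames(cohort$counts))
  if (anyNA(gi)) stop2("unknown genes: ", paste(genes[is.na(gi)], collapse = ", "))
  ci <- match(cells, colnames(cohort$counts))
  if (anyNA(ci)) stop2("unknown cells: ", paste(cells[is.na(ci)], collapse = ", "))
  if (!length(ci)) stop2("empty target group")
  if (any(tr$cell_type[ci] == "ambient")) stop2("cannot spike ambient barcodes")
  if (is.null(seed)) seed <- derive_seed(tr$seed, "spike")
  set.seed(seed)
  eff <- tr$effects[gi, tr$type_index[ci], drop = FALSE] + log2_effect
  y <- .draw_zinb_matrix(tr$lambda[gi], tr$s[ci], eff, tr$theta[gi],
                         tr$dropout_coeffs)
  m <- as.matrix(cohort$counts[gi, ci, drop = FALSE])
  cohort$counts[gi, ci] <- y
  cohort$counts <- Matrix::drop0(cohort$counts)
  cohort$truth$spike <- list(genes = genes, cells = cells,
                             log2_effect = log2_effect, seed = seed)
  # refresh derived per-cell metadata
  keep <- cohort$meta$barcode
  info <- cohort$meta[, setdiff(names(cohort$meta),
                                c("total_umis", "n_genes_detected"))]
  cohort$meta <- cell_metadata(cohort$counts[, keep, drop = FALSE], info)
  cohort
}

#' ZINB zero probability
#'
#' Closed-form probability of a zero count under
#' `ZINB(mu, theta, pi)`: `pi + (1 - pi) * (theta / (theta + mu))^theta`.
#' Used in generator moment checks.
#'
#' @param mu,theta,pi ZINB parameters (vectorized).
#' @return numeric vector of zero probabilities.
#' @export
zinb_zero_prob <- function(mu, theta, pi) {
  pi + (1 - pi) * (theta / (theta + mu))^theta
}
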