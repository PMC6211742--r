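## End-to-end pipeline orchestration: ten stages from cell calling to
## subtype classification, driven by a YAML configuration, with a run
## manifest sufficient to re-run identically.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; the thresholds of the
#' standard analysis (gene filter in >= 3 cells, >= 200 genes per cell,
#' adjusted p < 0.05, log2 fold change > 1, 50%/50% biomarker detection
#' rules, pooled mean + 2 SD subtype rule) are the configuration defaults,
#' so an unmodified run performs the canonical analysis.
#'
#' @param seed global seed fanned out to per-stage seeds.
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = list(synthetic = TRUE, matrix = NULL, genes = NULL,
                 barcodes = NULL, meta = NULL),
    cell_calling = list(enabled = TRUE),
    qc = list(min_cells = 3, min_genes = 200),
    normalize = list(scale_factor = 10000),
    cell_cycle = list(gmt = NULL, n_bins = 25, n_ctrl = 50),
    variable_genes = list(n_bins = 20, z_cutoff = 1.0, max_genes = 2000),
    pca = list(n_components = 30, k = NULL, clip = 10),
    cluster = list(k_neighbors = 20, prune = 1 / 15, resolution = 1.0),
    annotate = list(gmt = NULL, min_frac = 0.25),
    diffexp = list(enabled = TRUE, cluster = NULL, min_pct_test = 0.10,
                   adjust = "bonferroni", alpha = 0.05, min_lfc = 1.0,
                   min_pct = 0.5, min_pct_diff = 0.5),
    composition = list(fisher_cell_type = NULL, fisher_sample = NULL,
                       cut_k = NULL),
    subtype = list(gmt = NULL, grouping = "sample", sd_type = "population",
                   pool = "all")
  )
}

#' Read / write a pipeline configuration
#'
#' Structured YAML; missing keys fall back to [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(user$seed %||% 1L), user)
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}

.stage <- function(manifest, name, params, n_in, n_out, outputs = character(0)) {
  manifest$stages[[length(manifest$stages) + 1]] <- list(
    name = name, params = params, n_in = n_in, n_out = n_out,
    outputs = outputs)
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the ten stages in order: cell calling, QC filter,
#' normalization with covariate regression, variable-gene selection,
#' PCA with elbow selection, SNN clustering, marker annotation,
#' differential expression with biomarker thresholds, composition analysis
#' with Fisher enrichment, and subtype scoring/classification. Each
#' stage's tabular outputs and a run manifest are written under `out_dir`.
#' Identical configuration and seed give identical outputs. Any stage
#' error aborts with the stage name; the partial manifest is still
#' written.
#'
#' @param config a configuration list, or a path to a YAML configuration.
#' @param out_dir output directory (created if needed).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(config$seed %||% 1L),
                              config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("serocell")),
                   seed = config$seed, config = config, stages = list())
  current <- "setup"
  on_fail <- function(e) {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    stop2("pipeline aborted in stage '", current, "': ", conditionMessage(e))
  }
  tryCatch({
    ## stage 1: cell calling -------------------------------------------
    current <- "cell_calling"
    inp <- config$input
    if (isTRUE(inp$synthetic) && is.null(inp$matrix)) {
      cohort <- generate_cohort(default_cohort_config(seed = derive_seed(
        config$seed, "cohort")))
      counts <- cohort$counts
      sample_info <- cohort$meta[, c("barcode", "sample_id", "patient_id",
                                     "site", "grade")]
    } else {
      counts <- read_counts(inp$matrix, inp$genes, inp$barcodes)
      sample_info <- if (!is.null(inp$meta))
        utils::read.delim(inp$meta, stringsAsFactors = FALSE) else NULL
    }
    n0 <- ncol(counts)
    if (isTRUE(config$cell_calling$enabled)) {
      called <- call_cells(counts)
      counts <- called$counts
      thr <- called$threshold$umi_threshold
    } else thr <- NA
    manifest <- .stage(manifest, "cell_calling",
                       list(enabled = config$cell_calling$enabled,
                            umi_threshold = thr), n0, ncol(counts))

    ## stage 2: QC filter ----------------------------------------------
    current <- "qc_filter"
    counts <- filter_matrix(counts, config$qc$min_cells, config$qc$min_genes)
    if (!is.null(sample_info))
      sample_info <- sample_info[sample_info$barcode %in% colnames(counts), ,
                                 drop = FALSE]
    meta <- cell_metadata(counts, sample_info)
    manifest <- .stage(manifest, "qc_filter", config$qc,
                       n0, ncol(counts))

    ## stage 3: normalize + cell cycle + regression --------------------
    current <- "normalize_regress"
    norm <- log_normalize(counts, config$normalize$scale_factor)
    cc <- NULL
    if (!is.null(config$cell_cycle$gmt)) {
      sets <- read_gene_sets(config$cell_cycle$gmt)
      cc <- cell_cycle_score(norm, sets$S, sets$G2M,
                             config$cell_cycle$n_bins,
                             config$cell_cycle$n_ctrl,
                             seed = derive_seed(config$seed, "cc"))
    }
    resid <- regress_covariates(norm, meta$total_umis,
                                s = cc$S, g2m = cc$G2M)
    manifest <- .stage(manifest, "normalize_regress",
                       list(scale_factor = config$normalize$scale_factor,
                            cell_cycle = !is.null(cc)),
                       ncol(counts), ncol(counts))

    ## stage 4: variable genes -----------------------------------------
    current <- "variable_genes"
    hvg <- select_variable_genes(norm, config$variable_genes$n_bins,
                                 config$variable_genes$z_cutoff,
                                 config$variable_genes$max_genes)
    if (length(hvg) < 10) stop2("too few variable genes selected")
    manifest <- .stage(manifest, "variable_genes", config$variable_genes,
                       nrow(norm), length(hvg))

    ## stage 5: PCA + elbow --------------------------------------------
    current <- "pca_elbow"
    scaled <- scale_clip(resid[hvg, , drop = FALSE], config$pca$clip)
    ncomp <- min(config$pca$n_components, length(hvg) - 1, ncol(scaled) - 1)
    pca <- pca_embed(scaled, ncomp)
    k <- config$pca$k %||% max(select_elbow(pca$var_frac), 5)
    emb <- pca$scores[, seq_len(k), drop = FALSE]
    manifest <- .stage(manifest, "pca_elbow",
                       list(n_components = ncomp, k = k),
                       length(hvg), k)

    ## stage 6: clustering ---------------------------------------------
    current <- "cluster"
    cl <- snn_cluster(emb, config$cluster$k_neighbors, config$cluster$prune,
                      config$cluster$resolution,
                      seed = derive_seed(config$seed, "cluster"))
    tsne <- tsne_embed(emb, seed = derive_seed(config$seed, "tsne"))
    manifest <- .stage(manifest, "cluster",
                       c(config$cluster, list(K = cl$K,
                                              modularity = cl$modularity)),
                       ncol(counts), cl$K)

    ## stage 7: annotation ---------------------------------------------
    current <- "annotate"
    panels <- if (!is.null(config$annotate$gmt))
      read_gene_sets(config$annotate$gmt) else default_marker_panels()
    cl <- annotate_clusters(norm, cl, panels, config$annotate$min_frac,
                            meta = meta)
    meta$cluster <- cl$cluster[meta$barcode]
    meta$cell_type <- cl$cell_labels[meta$barcode]
    cl_path <- file.path(out_dir, "clusters.tsv")
    utils::write.table(data.frame(barcode = meta$barcode,
                                  cluster = meta$cluster,
                                  cell_type = meta$cell_type,
                                  tsne1 = tsne[meta$barcode, 1],
                                  tsne2 = tsne[meta$barcode, 2]),
                       cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage(manifest, "annotate",
                       list(min_frac = config$annotate$min_frac),
                       cl$K, length(unique(cl$labels)), cl_path)

    ## stage 8: differential expression --------------------------------
    current <- "diffexp"
    de_path <- character(0)
    if (isTRUE(config$diffexp$enabled)) {
      target <- config$diffexp$cluster %||%
        as.integer(names(which.max(table(meta$cluster))))
      in_cells <- meta$barcode[meta$cluster == target]
      out_cells <- meta$barcode[meta$cluster != target]
      de <- lrt_de(counts, norm, in_cells, out_cells,
                   min_pct = config$diffexp$min_pct_test,
                   adjust = config$diffexp$adjust)
      bio <- biomarker_filter(de, config$diffexp$alpha,
                              config$diffexp$min_lfc, config$diffexp$min_pct,
                              config$diffexp$min_pct_diff)
      de_path <- file.path(out_dir, c("diffexp.tsv", "biomarkers.tsv"))
      utils::write.table(de, de_path[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(bio, de_path[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- .stage(manifest, "diffexp",
                         list(cluster = target, n_tested = nrow(de),
                              n_biomarkers = nrow(bio)),
                         nrow(norm), nrow(de), de_path)
    } else {
      manifest <- .stage(manifest, "diffexp", list(enabled = FALSE), 0, 0)
    }

    ## stage 9: composition --------------------------------------------
    current <- "composition"
    comp <- composition_table(meta)
    dendro <- cluster_samples(comp, k = config$composition$cut_k)
    comp_path <- file.path(out_dir, "composition.tsv")
    utils::write.table(cbind(sample_id = rownames(comp$counts), comp$counts),
                       comp_path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(dendro$newick, file.path(out_dir, "sample_dendrogram.nwk"))
    fisher <- NULL
    if (!is.null(config$composition$fisher_cell_type))
      fisher <- fisher_enrichment(comp, config$composition$fisher_cell_type,
                                  config$composition$fisher_sample)
    manifest <- .stage(manifest, "composition",
                       list(fisher = if (is.null(fisher)) NULL else
                         list(p = fisher$p_two_sided,
                              odds_ratio = fisher$odds_ratio)),
                       nrow(meta), nrow(comp$counts),
                       comp_path)

    ## stage 10: subtype scoring + classification ----------------------
    current <- "subtype"
    sub_path <- character(0)
    if (!is.null(config$subtype$gmt)) {
      sigs <- read_gene_sets(config$subtype$gmt)
      grouping <- if (config$subtype$grouping == "cluster")
        stats::setNames(as.character(meta$cluster), meta$barcode)
      else stats::setNames(meta$sample_id, meta$barcode)
      sc <- score_groups(norm, grouping, sigs)
      calls <- classify_subtypes(sc, sd_type = config$subtype$sd_type,
                                 pool = config$subtype$pool)
      sub_path <- file.path(out_dir, c("subtype_scores.tsv",
                                       "subtype_calls.tsv"))
      utils::write.table(cbind(group = rownames(sc), as.data.frame(sc)),
                         sub_path[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(calls, sub_path[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- .stage(manifest, "subtype",
                         list(grouping = config$subtype$grouping,
                              n_classified = sum(calls$subtype != "unclassified")),
                         nrow(sc), nrow(calls), sub_path)
    } else {
      manifest <- .stage(manifest, "subtype", list(enabled = FALSE), 0, 0)
    }
  }, error = on_fail)

  meta_path <- file.path(out_dir, "cell_metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write the packaged demo fixture
#'
#' Generates a small synthetic cohort (six cell types, four samples, ~800
#' cells, 1500 genes, plus ambient barcodes for the cell-calling stage) and
#' writes everything a demo run needs: the sparse count matrix with gene
#' and barcode lists, per-cell sample metadata, the generative truth, a
#' marker-panel GMT, synthetic cell-cycle and subtype-signature GMTs, the
#' published subtype score matrices, and a ready-to-run configuration.
#'
#' @param out_dir destination directory.
#' @param seed integer seed.
#' @return named list of written paths, invisibly.
#' @export
make_fixture <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- default_cohort_config(seed = seed)
  cfg$ambient_barcodes <- list(n = 1500, mean_umis = 12)
  cohort <- generate_cohort(cfg)
  p <- list(
    matrix = file.path(out_dir, "counts.mtx"),
    genes = file.path(out_dir, "genes.txt"),
    barcodes = file.path(out_dir, "barcodes.txt"),
    meta = file.path(out_dir, "cell_meta.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    markers = file.path(out_dir, "markers.gmt"),
    cell_cycle = file.path(out_dir, "cell_cycle.gmt"),
    subtypes = file.path(out_dir, "subtype_signatures.gmt"),
    scores_samples = file.path(out_dir, "published_scores_samples.tsv"),
    scores_clusters = file.path(out_dir, "published_scores_clusters.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_counts(cohort$counts, p$matrix, p$genes, p$barcodes)
  utils::write.table(cohort$meta[, c("barcode", "sample_id", "patient_id",
                                     "site", "grade")],
                     p$meta, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = cohort$truth$barcode,
                                cell_type = cohort$truth$cell_type),
                     p$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- rownames(cohort$counts)
  panels <- lapply(cohort$truth$markers, function(ix) genes[ix])
  write_gene_sets(panels, p$markers, "synthetic marker panel")
  write_gene_sets(list(S = genes[1001:1020], G2M = genes[1021:1040]),
                  p$cell_cycle, "synthetic phase set")
  write_gene_sets(list(differentiated = panels$epithelial,
                       immunoreactive = c(panels$lymphocyte, panels$myeloid),
                       mesenchymal = c(panels$fibroblast, panels$stromal),
                       proliferative = genes[1041:1060]),
                  p$subtypes, "synthetic subtype signature")
  file.copy(extdata_path("subtype_scores_samples.tsv"), p$scores_samples,
            overwrite = TRUE)
  file.copy(extdata_path("subtype_scores_clusters.tsv"), p$scores_clusters,
            overwrite = TRUE)
  cfg_run <- default_pipeline_config(seed)
  cfg_run$input <- list(synthetic = FALSE, matrix = p$matrix,
                        genes = p$genes, barcodes = p$barcodes, meta = p$meta)
  cfg_run$cell_cycle$gmt <- p$cell_cycle
  cfg_run$annotate$gmt <- p$markers
  cfg_run$subtype$gmt <- p$subtypes
  write_pipeline_config(cfg_run, p$config)
  invisible(p)
}
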