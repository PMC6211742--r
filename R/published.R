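## Accessors for the small published-values fixtures shipped under
## inst/extdata: the study-cohort sample table, the printed subtype score
## matrices, and the printed biomarker tables, all transcribed from a
## published single-cell survey of serous epithelial ovarian tumors. These
## are inputs for worked examples and acceptance checks, not outputs of
## this package.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "serocell")
  if (p == "") stop2("fixture not found: ", file)
  p
}

#' Published study cohort sample table
#'
#' Fourteen samples from nine patients (ages, neoplasm grade, stage, site,
#' and cells captured per sample) of a published serous ovarian tumor
#' single-cell cohort.
#'
#' @return a data frame with one row per sample.
#' @export
published_sample_table <- function() {
  utils::read.delim(extdata_path("ovarian_cohort_samples.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published subtype score matrices
#'
#' The printed per-sample (14 x 4) and per-cluster (16 x 4) TCGA-subtype
#' signature score matrices of the published cohort, transcribed as
#' printed. Input to [classify_subtypes()].
#'
#' @return list with numeric matrices `samples` and `clusters`, columns
#'   `differentiated`, `immunoreactive`, `mesenchymal`, `proliferative`.
#' @export
published_subtype_scores <- function() {
  read_one <- function(f) {
    df <- utils::read.delim(extdata_path(f), stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m
  }
  list(samples = read_one("subtype_scores_samples.tsv"),
       clusters = read_one("subtype_scores_clusters.tsv"))
}

#' Published biomarker tables
#'
#' The printed differential-expression tables of the published cohort:
#' tumor-epithelial vs all other cells (`"epithelial"`), per-epithelial-
#' cluster biomarkers (`"epithelial_subsets"`), and tumor fibroblast/
#' stromal vs normal (`"stromal_vs_normal"`). Columns follow the printed
#' headers: average log2 fold change, detection fraction in and out of the
#' defining cluster, adjusted p-value.
#'
#' @param which which table to load.
#' @return a data frame.
#' @export
published_biomarkers <- function(which = c("epithelial", "epithelial_subsets",
                                           "stromal_vs_normal")) {
  which <- match.arg(which)
  f <- switch(which,
              epithelial = "epithelial_biomarkers.tsv",
              epithelial_subsets = "epithelial_subset_biomarkers.tsv",
              stromal_vs_normal = "stromal_vs_normal_biomarkers.tsv")
  utils::read.delim(extdata_path(f), stringsAsFactors = FALSE)
}

#' Canonical cell-type marker panels
#'
#' The marker panels used to annotate clusters: epithelial/mesothelial
#' (EPCAM, keratins), lymphocyte (PTPRC, CD3E, CD19, MS4A1), myeloid,
#' endothelial (PECAM1, CD34), fibroblast (ACTA2, DCN, ACTB), and stromal
#' (THY1, ENG, VIM, CD44).
#'
#' @return a named list of gene-symbol vectors.
#' @export
default_marker_panels <- function() {
  read_gene_sets(extdata_path("marker_panels.gmt"))
}

#' Standard human cell-cycle phase gene lists
#'
#' The widely used 43-gene S-phase and 54-gene G2/M-phase human gene-symbol
#' lists, for [cell_cycle_score()] on human data.
#'
#' @return a list with elements `S` and `G2M`.
#' @export
cell_cycle_gene_sets <- function() {
  read_gene_sets(extdata_path("cell_cycle_human.gmt"))
}
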