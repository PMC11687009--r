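# End-to-end pipeline drivers. Both drivers either consume user files (TSV
# counts/design, TSV abundance matrices + metadata, GMT sets) or simulate
# inputs, write every intermediate as a file, and emit a JSON manifest with
# configuration, seeds and input checksums so a run can be reproduced.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its canonical default: contrast and
#' interaction significance 0.05 (BH-adjusted), non-additive effect floor 1
#' log2 unit, response-gene expression floor 2 TPM, cohort expression filter
#' 3 TPM, top 2000 genes for PCA, 1000 gene-set permutations, core genes in
#' >= 3 leading edges.
#'
#' @param padj_threshold adjusted-p significance threshold.
#' @param delta_threshold non-additive effect floor (log2, strict).
#' @param min_tpm_response expression floor for response genes (TPM).
#' @param min_tpm_filter cohort expression filter (TPM).
#' @param top_k genes for PCA / top-expressed selection.
#' @param n_perm gene-set permutations.
#' @param min_occurrence leading-edge subsets for core genes.
#' @param min_lfc response-gene fold-change floor (log2).
#' @param lrt_ref LRT reference distribution (`"f"` or `"chisq"`).
#' @param seed integer seed for simulation and permutation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(padj_threshold = 0.05, delta_threshold = 1,
                            min_tpm_response = 2, min_tpm_filter = 3,
                            top_k = 2000, n_perm = 1000, min_occurrence = 3,
                            min_lfc = 1, lrt_ref = "f", seed = 1L) {
  cfg <- list(padj_threshold = padj_threshold,
              delta_threshold = delta_threshold,
              min_tpm_response = min_tpm_response,
              min_tpm_filter = min_tpm_filter, top_k = as.integer(top_k),
              n_perm = as.integer(n_perm),
              min_occurrence = as.integer(min_occurrence),
              min_lfc = min_lfc, lrt_ref = lrt_ref, seed = as.integer(seed))
  num <- unlist(cfg[c("padj_threshold", "delta_threshold",
                      "min_tpm_response", "min_tpm_filter", "top_k",
                      "n_perm", "min_occurrence", "min_lfc")])
  if (any(num <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [pipeline_config()] arguments; absent fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

write_manifest <- function(out_dir, config, inputs, extra = list()) {
  files <- list.files(out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- c(list(
    package = "synergyseq",
    version = as.character(utils::packageVersion("synergyseq")),
    config = unclass(config),
    inputs = inputs,
    output_checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                               basename(files)))), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_msg <- function(...) message("[synergyseq] ", ...)

#' Run the factorial pipeline end to end
#'
#' Stages: size factors -> per-gene dispersion -> interaction fits ->
#' response-gene filter -> non-additive classification -> overlap enrichment
#' of the non-additive set against a gene-set collection. Inputs are either
#' file paths (`counts_path`, `design_path`) or simulated from
#' `sim_config`. All outputs land in `out_dir` as TSV/JSON plus a manifest.
#'
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param counts_path,design_path TSV inputs (ignored when simulating).
#' @param sim_config a [sim_factorial_config()] to simulate inputs, or
#'   `NULL` to read the paths.
#' @param gmt_path optional GMT collection for overlap enrichment of the
#'   non-additive gene set (defaults to the planted-class GMT when
#'   simulating).
#' @return (invisibly) list with fits, calls, summary, retained genes,
#'   enrichment table and the manifest.
#' @export
run_factorial_pipeline <- function(out_dir, config = pipeline_config(),
                                   counts_path = NULL, design_path = NULL,
                                   sim_config = NULL, gmt_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (!is.null(sim_config)) {
    stage_msg("simulating factorial experiment (", sim_config$n_genes,
              " genes, ", sim_config$n_reps, " reps/condition)")
    sim <- simulate_factorial(sim_config)
    paths <- write_fixture_bundle(sim, out_dir)
    counts <- sim$counts
    design <- sim$design
    if (is.null(gmt_path)) gmt_path <- paths[["classes"]]
    inputs$simulated <- unclass(sim_config)[setdiff(names(sim_config),
                                                    "class_fractions")]
    inputs$simulated$class_fractions <- as.list(sim_config$class_fractions)
  } else {
    if (is.null(counts_path) || !file.exists(counts_path))
      stop("counts file not found: ",
           if (is.null(counts_path)) "<missing>" else counts_path)
    if (is.null(design_path) || !file.exists(design_path))
      stop("design file not found: ",
           if (is.null(design_path)) "<missing>" else design_path)
    counts <- read_matrix_tsv(counts_path, unit = "counts")
    design <- read_design_tsv(design_path)
    inputs$counts <- unname(tools::md5sum(counts_path))
    inputs$design <- unname(tools::md5sum(design_path))
  }

  stage_msg("estimating size factors for ", ncol(counts), " samples")
  sf <- estimate_size_factors(counts)
  stage_msg("estimating dispersions for ", nrow(counts), " genes")
  disp <- estimate_dispersion(counts, design, sf)
  stage_msg("fitting interaction models")
  fits <- fit_interaction(counts, design, sf, disp, lrt_ref = config$lrt_ref)
  utils::write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cpm_like <- sweep(counts, 2, colSums(counts), "/") * 1e6
  attr(cpm_like, "unit") <- "TPM"
  retained <- response_gene_filter(fits, cpm_like,
                                   min_tpm = config$min_tpm_response,
                                   min_lfc = config$min_lfc,
                                   padj_threshold = config$padj_threshold)
  stage_msg(length(retained), " response genes pass the expression and ",
            "fold-change filters")
  writeLines(retained, file.path(out_dir, "response_genes.txt"))

  cls <- classify_all(fits, retained,
                      padj_threshold = config$padj_threshold,
                      delta_threshold = config$delta_threshold,
                      deg_threshold = config$padj_threshold)
  stage_msg(cls$summary[["total"]], " non-additive genes (",
            paste(sprintf("%s=%d", NONADD_CATEGORIES,
                          cls$summary[NONADD_CATEGORIES]), collapse = ", "),
            ")")
  utils::write.table(cls$calls, file.path(out_dir, "nonadditive_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(cls$summary),
                       file.path(out_dir, "category_summary.json"),
                       auto_unbox = TRUE)

  enr <- NULL
  nonadd <- cls$calls$gene[!is.na(cls$calls$is_nonadditive) &
                             cls$calls$is_nonadditive]
  if (!is.null(gmt_path) && length(nonadd) > 0) {
    collection <- read_gmt(gmt_path)
    enr <- overlap_enrichment(nonadd, collection, rownames(counts))
    utils::write.table(enr, file.path(out_dir, "overlap_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- write_manifest(out_dir, config, inputs,
                             list(n_genes = nrow(counts),
                                  n_response = length(retained),
                                  summary = as.list(cls$summary)))
  invisible(list(fits = fits, calls = cls$calls, summary = cls$summary,
                 retained = retained, enrichment = enr,
                 manifest = manifest))
}

#' Run the cohort pipeline end to end
#'
#' Stages: wild-type filter -> TPM expression filter -> log2(TPM+1) ->
#' response scores -> marker stratification (halves and quartiles by the
#' MITF-like marker, high/low split of induced PD-L1) -> association
#' statistics -> PCA -> gene-set enrichment of treated high-vs-low groups
#' with leading-edge core genes. Inputs are file paths or a simulated
#' cohort.
#'
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param untreated_path,treated_path,metadata_path TSV inputs (ignored when
#'   simulating).
#' @param sim_config a [sim_cohort_config()] to simulate inputs, or `NULL`.
#' @param response_set gene ids of the cytokine response signature (defaults
#'   to the simulated ISG panel when simulating).
#' @param mitf_gene,pdl1_gene marker gene ids (defaults `"MITF"`,
#'   `"CD274"`).
#' @param gmt_path optional GMT collection for enrichment over the treated
#'   marker-low vs marker-high comparison.
#' @return (invisibly) list with strata, associations, PCA, enrichment,
#'   core genes and the manifest.
#' @export
run_cohort_pipeline <- function(out_dir, config = pipeline_config(),
                                untreated_path = NULL, treated_path = NULL,
                                metadata_path = NULL, sim_config = NULL,
                                response_set = NULL, mitf_gene = "MITF",
                                pdl1_gene = "CD274", gmt_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (!is.null(sim_config)) {
    stage_msg("simulating cohort (", sim_config$n_lines, " wild-type lines)")
    sim <- simulate_cohort(sim_config)
    cohort <- list(untreated = sim$untreated, treated = sim$treated)
    metadata <- sim$metadata
    if (is.null(response_set))
      response_set <- grep("^ISG", rownames(sim$treated), value = TRUE)
    inputs$simulated <- unclass(sim_config)[
      setdiff(names(sim_config), "latent_dediff")]
  } else {
    for (p in c(untreated_path, treated_path, metadata_path))
      if (is.null(p) || !file.exists(p))
        stop("input file not found: ", if (is.null(p)) "<missing>" else p)
    cohort <- list(untreated = read_matrix_tsv(untreated_path, unit = "TPM"),
                   treated = read_matrix_tsv(treated_path, unit = "TPM"))
    metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    inputs$untreated <- unname(tools::md5sum(untreated_path))
    inputs$treated <- unname(tools::md5sum(treated_path))
    inputs$metadata <- unname(tools::md5sum(metadata_path))
    if (is.null(response_set)) stop("response_set is required for file input")
  }
  miss <- setdiff(union(colnames(cohort$untreated), colnames(cohort$treated)),
                  metadata$line)
  if (length(miss) > 0)
    stop("metadata missing line(s): ", paste(miss, collapse = ", "))
  if (!setequal(colnames(cohort$untreated), colnames(cohort$treated)))
    stop("unpaired line(s): ",
         paste(union(setdiff(colnames(cohort$untreated),
                             colnames(cohort$treated)),
                     setdiff(colnames(cohort$treated),
                             colnames(cohort$untreated))), collapse = ", "))

  wt <- filter_wildtype(cohort, metadata)
  stage_msg(ncol(wt$treated), " of ", ncol(cohort$treated),
            " lines retained by the wild-type filter")

  keep_expr <- filter_min_tpm(cbind(wt$untreated, wt$treated),
                              config$min_tpm_filter)
  genes_kept <- rownames(keep_expr)
  stage_msg(length(genes_kept), " of ", nrow(wt$treated),
            " genes pass the ", config$min_tpm_filter, " TPM filter")
  sub_unit <- function(m) {
    out <- m[genes_kept, , drop = FALSE]; attr(out, "unit") <- "TPM"; out
  }
  l2_untreated <- log2_tpm1(sub_unit(wt$untreated))
  l2_treated <- log2_tpm1(sub_unit(wt$treated))

  score <- ifng_response_score(l2_treated,
                               intersect(response_set, genes_kept))
  mitf <- l2_treated[mitf_gene, ]
  pdl1_ind <- l2_treated[pdl1_gene, ] - l2_untreated[pdl1_gene, ]

  halves <- rank_and_split(mitf, "halves")
  quart <- rank_and_split(mitf, "quartiles")
  low_lines <- names(quart)[!is.na(quart) & quart == "low"]
  pdl1_split <- split_high_low(pdl1_ind[low_lines], "largest_gap")
  strata <- data.frame(line = names(mitf), ifng_score = unname(score),
                       mitf = unname(mitf), pdl1_induction = unname(pdl1_ind),
                       half = unname(halves), quartile = unname(quart),
                       pdl1_group = NA_character_, stringsAsFactors = FALSE)
  strata$pdl1_group[match(names(pdl1_split), strata$line)] <-
    unname(pdl1_split)
  utils::write.table(strata, file.path(out_dir, "strata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- list(
    pdl1_vs_score = associate(l2_treated[pdl1_gene, ], score, "spearman"),
    pdl1_induction_vs_mitf = associate(mitf, pdl1_ind, "spearman"),
    pdl1_vs_mitf_linreg = associate(mitf, l2_treated[pdl1_gene, ], "linreg"),
    pdl1_by_mitf_half = compare_groups(
      l2_treated[pdl1_gene, ], halves, "two_group"))
  jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  z <- zscore_genes(cbind(l2_untreated, l2_treated))
  pca <- pca_embed(z, min(config$top_k, nrow(z)))
  utils::write.table(
    data.frame(sample = rownames(pca$scores), pca$scores[, 1:2],
               check.names = FALSE),
    file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  enr <- NULL; core <- NULL
  sets <- if (!is.null(gmt_path)) read_gmt(gmt_path)
          else list(cytokine_response = response_set)
  extreme <- !is.na(quart)
  z_tr <- zscore_genes(l2_treated[, extreme, drop = FALSE])
  usable <- vapply(sets, function(s)
    sum(rownames(z_tr) %in% s) >= 2 &&
      sum(rownames(z_tr) %in% s) < nrow(z_tr), TRUE)
  if (any(usable)) {
    ranked <- rank_genes(z_tr, quart[extreme], ref = "low")
    enr <- gsea_permutation(ranked, sets[usable], n_perm = config$n_perm,
                            seed = config$seed)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    les <- strsplit(enr$leading_edge, ",", fixed = TRUE)
    if (length(les) >= config$min_occurrence) {
      core <- core_genes(les, config$min_occurrence)
      utils::write.table(core, file.path(out_dir, "core_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- write_manifest(out_dir, config, inputs,
                             list(n_lines = ncol(wt$treated),
                                  n_genes = length(genes_kept)))
  invisible(list(strata = strata, associations = assoc, pca = pca,
                 enrichment = enr, core = core, manifest = manifest))
}
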