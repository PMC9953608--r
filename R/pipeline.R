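# End-to-end orchestration: sample QC -> coverage harmonization -> tiered
# filtering -> collapsing analysis -> gene-set burden test -> enrichment and
# exclusivity. Every exclusion count is collected into a machine-readable
# report; stage artifacts are written as TSV/JSON when an output directory is
# given.

#' Run the full analysis pipeline on a cohort bundle
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()] / [read_cohort()],
#'   or any list with elements `samples`, `variants`, `coverage`,
#'   `gene_sets`, `curated`.
#' @param thresholds Coverage QC thresholds ([coverage_thresholds()]).
#' @param alpha Nominal significance level used throughout; default 0.05.
#' @param max_af Collapsing-tier MAF bound (inclusive); default 0.01.
#' @param min_cadd Strict-tier CADD bound; default 20.
#' @param enrichment_subpopulation Optional subpopulation restriction on case
#'   samples for the enrichment gene lists.
#' @param hits_override Optional explicit hit-gene list for the burden test.
#' @param out_dir Optional directory for stage artifacts (`gca_results.tsv`,
#'   `gene_exclusions.tsv`, `burden.json`, `enrichment_case.tsv`,
#'   `exclusivity.tsv`, `report.json`).
#' @return A list of class `pipeline_run` with elements `samples`,
#'   `harmonized`, `gca`, `burden`, `enrichment` (list of three tibbles),
#'   `exclusivity`, `report`.
#' @export
run_pipeline <- function(bundle,
                         thresholds = coverage_thresholds(),
                         alpha = 0.05,
                         max_af = 0.01,
                         min_cadd = 20,
                         enrichment_subpopulation = NULL,
                         hits_override = NULL,
                         out_dir = NULL) {
  for (el in c("samples", "variants", "coverage", "gene_sets", "curated")) {
    if (is.null(bundle[[el]])) abort(paste0("bundle lacks element '", el, "'"))
  }

  ## stage 1: sample QC
  samples <- sample_qc(bundle$coverage, bundle$samples, thresholds)

  ## stage 2: coverage harmonization
  harmonized <- harmonize_genes(bundle$coverage, samples, thresholds)
  genes_ok <- analyzable_genes(harmonized)

  ## stage 3: tiered filtering
  vs_gca <- apply_filter(bundle$variants, profile_gca(genes_ok, max_af = max_af))
  vs_gsea <- apply_filter(bundle$variants, profile_gsea(genes_ok, min_cadd = min_cadd))
  vs_syn <- apply_filter(bundle$variants, profile_synonymous(genes_ok, min_cadd = min_cadd))

  ## stage 4: collapsing analysis
  cm <- build_carrier_matrix(vs_gca, samples)
  gca <- run_gca(cm, alpha = alpha)

  ## stage 5: gene-set burden test of the curated list
  burden <- run_burden_test(gca, bundle$curated, hits = hits_override)

  ## stage 6: enrichment + exclusivity
  lists <- gene_lists_for_enrichment(vs_gsea, vs_syn, samples,
                                     subpopulation = enrichment_subpopulation)
  enr <- list(
    case = enrich(lists$case, bundle$gene_sets, genes_ok, alpha = alpha),
    control = enrich(lists$control, bundle$gene_sets, genes_ok, alpha = alpha),
    case_synonymous = enrich(lists$case_synonymous, bundle$gene_sets, genes_ok,
                             alpha = alpha)
  )
  excl <- exclusivity(enr$case, enr$control, enr$case_synonymous, alpha = alpha)

  report <- list(
    n_samples_input = nrow(bundle$samples),
    n_samples_pass = sum(samples$qc_pass),
    failed_samples = samples$sample_id[!samples$qc_pass],
    n_genes_input = nrow(harmonized),
    n_genes_analyzable = length(genes_ok),
    gene_exclusions_by_rule = as.list(table(harmonized$reason[!harmonized$analyzable])),
    n_variants_input = n_variants(bundle$variants),
    n_variants_gca = n_variants(vs_gca),
    n_variants_gsea = n_variants(vs_gsea),
    n_variants_synonymous = n_variants(vs_syn),
    gca_rejections = as.list(attr(vs_gca, "rejections")),
    gsea_rejections = as.list(attr(vs_gsea, "rejections")),
    universe_size = length(gca$universe),
    n_nominal_hits = length(gca$hits),
    enrichment_list_sizes = lapply(lists, length),
    burden = list(
      N = burden$universe_N, K = burden$list_K, n = burden$hits_n,
      k = burden$overlap_k, overlap_genes = burden$overlap_genes,
      p_value = burden$p_value
    )
  )

  run <- structure(
    list(samples = samples, harmonized = harmonized, gca = gca,
         burden = burden, enrichment = enr, exclusivity = excl,
         gene_lists = lists, report = report),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat("<pipeline_run>\n")
  cat(sprintf("  samples: %d -> %d passing QC\n", r$n_samples_input, r$n_samples_pass))
  cat(sprintf("  genes:   %d -> %d analyzable\n", r$n_genes_input, r$n_genes_analyzable))
  cat(sprintf("  variants: %d input; %d collapsing-tier, %d strict-tier\n",
              r$n_variants_input, r$n_variants_gca, r$n_variants_gsea))
  cat(sprintf("  collapsing: universe %d, %d nominal hit(s)\n",
              r$universe_size, r$n_nominal_hits))
  cat(sprintf("  burden: overlap %d/%d among %d hits, p = %.3g\n",
              r$burden$k, r$burden$K, r$burden$n, r$burden$p_value))
  invisible(x)
}

fmt_sci <- function(x) formatC(x, format = "e", digits = 5)

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run$gca$results
  res$p_value <- fmt_sci(res$p_value)
  res$bonferroni_p <- fmt_sci(res$bonferroni_p)
  readr::write_tsv(res, file.path(out_dir, "gca_results.tsv"))
  readr::write_tsv(run$harmonized, file.path(out_dir, "gene_exclusions.tsv"))
  jsonlite::write_json(run$report$burden, file.path(out_dir, "burden.json"),
                       auto_unbox = TRUE, digits = NA)
  enr_case <- run$enrichment$case %>%
    mutate(
      overlap_genes = vapply(.data$overlap_genes, paste, character(1), collapse = ";"),
      nominal_p = fmt_sci(.data$nominal_p),
      adjusted_p = fmt_sci(.data$adjusted_p)
    )
  readr::write_tsv(enr_case, file.path(out_dir, "enrichment_case.tsv"))
  readr::write_tsv(run$exclusivity, file.path(out_dir, "exclusivity.tsv"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the statistical layer from a published-style counts table
#'
#' Convenience wrapper for exercising the collapsing statistics and the
#' gene-set burden test from a per-gene carrier-count table alone (no
#' genotype data), e.g. a published results table.
#'
#' @param counts Tibble `gene, cases_with, controls_with`.
#' @param n_cases,n_controls Group sizes.
#' @param curated Curated gene list.
#' @param universe_extra Additional universe gene symbols beyond those in
#'   `counts` (a counts table usually lists significant genes only; the
#'   burden test needs the full universe). Alternatively `universe_n`: pad
#'   the universe with unnamed symbols up to this total size.
#' @param universe_n Optional total universe size (see above).
#' @param hits Optional explicit hit-list override.
#' @param alpha Nominal level; default 0.05.
#' @return A list with the `gca_result` and the `overlap_test`.
#' @export
counts_mode <- function(counts, n_cases, n_controls, curated,
                        universe_extra = NULL, universe_n = NULL,
                        hits = NULL, alpha = 0.05) {
  gca <- gca_from_counts(counts, n_cases, n_controls, alpha = alpha)
  if (!is.null(universe_extra)) {
    gca$universe <- union(gca$universe, universe_extra)
  }
  if (!is.null(universe_n)) {
    pad <- universe_n - length(gca$universe)
    if (pad < 0) abort("universe_n smaller than the number of listed genes")
    gca$universe <- c(gca$universe, sprintf("PAD%05d", seq_len(pad)))
  }
  burden <- run_burden_test(gca, curated, hits = hits)
  list(gca = gca, burden = burden)
}
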