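# Tiered ultra-rare variant selection. Two tiers are used in practice: a
# strict tier for gene-set enrichment (variants absent from gnomAD and CADD
# PHRED >= 20) and a permissive tier for the gene-based collapsing analysis
# (MAF <= 0.01, no CADD restriction). Synonymous variants under the strict
# AF/CADD rules form a comparator stream for enrichment.

#' Define a variant filter profile
#'
#' A profile is a named tier of inclusion rules. A record is retained iff it
#' has FILTER `PASS` (when `require_pass`), its gene is in `genes` (when
#' supplied), its consequence class is listed, its population allele frequency
#' satisfies the AF rule (`absent_required`: no record in the resource;
#' otherwise absent-or-`<= max_af`), and its CADD PHRED score reaches
#' `min_cadd` (an unscored variant fails a CADD-thresholded profile).
#'
#' @param name Profile label used in logs and reports.
#' @param require_pass Keep only records with FILTER `PASS` (default `TRUE`).
#' @param max_af Maximum population allele frequency, in (0, 1]; ignored when
#'   `absent_required`. `NULL` disables the frequency bound.
#' @param absent_required Require the variant to be absent from the population
#'   frequency resource.
#' @param min_cadd Minimum CADD PHRED score, or `NULL` for no restriction.
#' @param consequences Consequence classes retained; defaults to the
#'   protein-altering set.
#' @param genes Optional restriction to analyzable gene symbols.
#' @return A list of class `filter_profile`.
#' @export
filter_profile <- function(name,
                           require_pass = TRUE,
                           max_af = NULL,
                           absent_required = FALSE,
                           min_cadd = NULL,
                           consequences = protein_altering_classes(),
                           genes = NULL) {
  if (!is.null(max_af) && (max_af <= 0 || max_af > 1)) {
    abort("max_af must lie in (0, 1]")
  }
  if (length(consequences) == 0) abort("consequences must be non-empty")
  bad <- setdiff(consequences, CONSEQUENCES)
  if (length(bad)) abort(paste0("unknown consequence class(es): ", toString(bad)))
  structure(
    list(
      name = name, require_pass = isTRUE(require_pass),
      max_af = max_af, absent_required = isTRUE(absent_required),
      min_cadd = min_cadd, consequences = consequences, genes = genes
    ),
    class = "filter_profile"
  )
}

#' Preset filter tiers
#'
#' `profile_gsea()` is the strict enrichment tier: PASS, protein-altering,
#' absent from the population resource, CADD PHRED >= 20. `profile_gca()` is
#' the permissive collapsing tier: PASS, protein-altering, population
#' frequency absent or <= 0.01, no CADD restriction. `profile_synonymous()`
#' applies the strict tier's AF/CADD rules to synonymous variants only.
#'
#' @param genes Optional restriction to analyzable gene symbols.
#' @param max_af MAF bound for the collapsing tier (inclusive); default 0.01.
#' @param min_cadd CADD bound for the strict tier; default 20.
#' @return A [filter_profile()].
#' @export
profile_gsea <- function(genes = NULL, min_cadd = 20) {
  filter_profile("gsea_strict", absent_required = TRUE, min_cadd = min_cadd,
                 genes = genes)
}

#' @rdname profile_gsea
#' @export
profile_gca <- function(genes = NULL, max_af = 0.01) {
  filter_profile("gca_permissive", max_af = max_af, genes = genes)
}

#' @rdname profile_gsea
#' @export
profile_synonymous <- function(genes = NULL, min_cadd = 20) {
  filter_profile("synonymous_comparator", absent_required = TRUE,
                 min_cadd = min_cadd, consequences = "synonymous",
                 genes = genes)
}

#' Apply a filter profile to a variant set
#'
#' Pure selection: returns the subset of records satisfying every rule of the
#' profile, with per-rule rejection counts attached as attribute
#' `"rejections"` (a record is attributed to the first rule it fails, in the
#' order PASS, gene restriction, consequence class, allele frequency, CADD).
#'
#' @param vs A [variant_set()].
#' @param profile A [filter_profile()].
#' @return The filtered `variant_set`.
#' @export
apply_filter <- function(vs, profile) {
  stopifnot(inherits(vs, "variant_set"), inherits(profile, "filter_profile"))
  v <- vs$variants
  ok_pass <- if (profile$require_pass) !is.na(v$filter) & v$filter == "PASS" else rep(TRUE, nrow(v))
  ok_gene <- if (is.null(profile$genes)) rep(TRUE, nrow(v)) else {
    !is.na(v$gene) & v$gene %in% profile$genes
  }
  ok_csq <- v$consequence %in% profile$consequences
  ok_af <- if (profile$absent_required) {
    is.na(v$gnomad_af)
  } else if (!is.null(profile$max_af)) {
    is.na(v$gnomad_af) | v$gnomad_af <= profile$max_af
  } else {
    rep(TRUE, nrow(v))
  }
  ok_cadd <- if (is.null(profile$min_cadd)) rep(TRUE, nrow(v)) else {
    !is.na(v$cadd_phred) & v$cadd_phred >= profile$min_cadd
  }

  keep <- ok_pass & ok_gene & ok_csq & ok_af & ok_cadd
  rejections <- c(
    not_pass = sum(!ok_pass),
    gene_restricted = sum(ok_pass & !ok_gene),
    consequence = sum(ok_pass & ok_gene & !ok_csq),
    allele_frequency = sum(ok_pass & ok_gene & ok_csq & !ok_af),
    cadd = sum(ok_pass & ok_gene & ok_csq & ok_af & !ok_cadd)
  )

  out <- variant_set(v[keep, , drop = FALSE], vs$geno[keep, , drop = FALSE])
  attr(out, "profile") <- profile$name
  attr(out, "rejections") <- rejections
  out
}

#' Gene lists for enrichment analysis
#'
#' Builds the three query gene lists compared in the enrichment stage: genes
#' with qualifying protein-altering variants carried by at least one case,
#' the same for controls, and genes with qualifying synonymous variants
#' carried by at least one case. The protein-altering input must already be
#' filtered with the strict enrichment tier and the synonymous input with the
#' synonymous comparator tier. An optional subpopulation restriction limits
#' the *case* samples considered (controls are always all passing controls),
#' mirroring designs where enrichment is restricted to the ancestry-matched
#' subset of cases.
#'
#' @param pa_vs Protein-altering `variant_set` (strict tier applied).
#' @param syn_vs Synonymous `variant_set` (comparator tier applied).
#' @param samples Sample tibble; only `qc_pass` samples are used.
#' @param subpopulation Optional subpopulation label restricting cases.
#' @return A list with character vectors `case`, `control`, `case_synonymous`.
#' @export
gene_lists_for_enrichment <- function(pa_vs, syn_vs, samples,
                                      subpopulation = NULL) {
  passing <- filter(samples, .data$qc_pass)
  cases <- filter(passing, .data$group == "case")
  if (!is.null(subpopulation)) {
    cases <- filter(cases, .data$subpopulation %in% !!subpopulation)
  }
  controls <- filter(passing, .data$group == "control")

  carried_genes <- function(vs, ids) {
    if (n_variants(vs) == 0 || length(ids) == 0) return(character())
    g <- vs$geno[, intersect(colnames(vs$geno), ids), drop = FALSE]
    carried <- rowSums(g >= 1, na.rm = TRUE) > 0
    sort(unique(vs$variants$gene[carried & !is.na(vs$variants$gene)]))
  }

  out <- list(
    case = carried_genes(pa_vs, cases$sample_id),
    control = carried_genes(pa_vs, controls$sample_id),
    case_synonymous = carried_genes(syn_vs, cases$sample_id)
  )
  empty <- names(out)[lengths(out) == 0]
  if (length(empty)) {
    warn(paste0("empty enrichment gene list(s): ", toString(empty)))
  }
  out
}
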