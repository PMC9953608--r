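# Gene-based collapsing analysis (GCA). Each subject is recoded per gene as
# carrier / non-carrier of at least one qualifying variant; carrier frequency
# is compared between cases and controls with a two-sided Fisher's exact
# test. No multiple-testing correction is applied inside GCA: the nominal
# hits feed the gene-set burden test, and a Bonferroni column is emitted for
# reference only.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `(a, b; c, d)` under the
#' minimum-likelihood rule: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (the convention of R's standard
#' implementation). This rule is genuinely two-sided: enrichment in either
#' group can contribute.
#'
#' @param a,b Cases with / without a qualifying variant.
#' @param c,d Controls with / without a qualifying variant.
#' @return The exact two-sided p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  if (length(a) != 1 || length(b) != 1 || length(c) != 1 || length(d) != 1) {
    abort("fisher_two_sided takes scalar counts")
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0) abort("both row margins must be positive")
  m1 <- a + b              # cases
  k <- a + c               # carriers
  n_tot <- a + b + c + d
  lo <- max(0, k - (c + d))
  hi <- min(k, m1)
  support <- lo:hi
  logp <- dhyper(support, m1, n_tot - m1, k, log = TRUE)
  log_obs <- dhyper(a, m1, n_tot - m1, k, log = TRUE)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(exp(logp[logp <= log_obs + 1e-7]))
  min(p, 1)
}

#' Build a binary carrier matrix
#'
#' One row per gene with at least one qualifying variant, one column per
#' QC-passing sample; cell 1 when the sample carries >= 1 qualifying variant
#' in the gene (any positive dosage). Missing genotypes count as non-carrier;
#' the number of missing calls treated this way is reported in a message.
#'
#' @param vs A tier-filtered [variant_set()].
#' @param samples Sample tibble; only `qc_pass` samples become columns.
#' @return An object of class `carrier_matrix`: list with the binary matrix
#'   `m` (genes x samples) and the sample tibble `samples`.
#' @export
build_carrier_matrix <- function(vs, samples) {
  stopifnot(inherits(vs, "variant_set"))
  passing <- filter(samples, .data$qc_pass)
  ids <- intersect(colnames(vs$geno), passing$sample_id)
  passing <- filter(passing, .data$sample_id %in% ids)
  if (n_variants(vs) == 0) {
    m <- matrix(0L, 0, nrow(passing),
                dimnames = list(NULL, passing$sample_id))
    return(structure(list(m = m, samples = passing), class = "carrier_matrix"))
  }
  geno <- vs$geno[, passing$sample_id, drop = FALSE]
  n_missing <- sum(is.na(geno))
  if (n_missing > 0) {
    inform(sprintf("%d missing genotype call(s) treated as non-carrier", n_missing))
  }
  geno[is.na(geno)] <- 0L
  carrier <- geno >= 1L
  genes <- vs$variants$gene
  keep <- !is.na(genes)
  agg <- rowsum((carrier[keep, , drop = FALSE]) * 1L, genes[keep])
  m <- (agg > 0) * 1L
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  structure(list(m = m, samples = passing), class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("<carrier_matrix> %d genes x %d samples (%d cases, %d controls)\n",
              nrow(x$m), ncol(x$m),
              sum(x$samples$group == "case"), sum(x$samples$group == "control")))
  invisible(x)
}

#' Run the gene-based collapsing analysis
#'
#' For every gene in the carrier matrix, tabulates cases/controls with and
#' without a qualifying variant, computes the two-sided Fisher exact p-value,
#' and ranks genes by ascending p (ties broken by descending case-carrier
#' count, then symbol). The nominal-hit set contains case-enriched genes with
#' `p < alpha`. The universe (genes with >= 1 qualifying variant) is carried
#' along for the gene-set burden test.
#'
#' @param cm A [build_carrier_matrix()] result.
#' @param alpha Nominal significance level; default 0.05.
#' @return An object of class `gca_result`: list with `results` (tibble
#'   `gene, cases_with, cases_without, controls_with, controls_without,
#'   p_value, bonferroni_p, direction, rank`), `hits` (character), `universe`
#'   (character), `n_cases`, `n_controls`, `alpha`.
#' @export
run_gca <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "carrier_matrix"), alpha > 0, alpha < 1)
  if (nrow(cm$m) == 0) abort("carrier matrix is empty")
  case_ids <- cm$samples$sample_id[cm$samples$group == "case"]
  ctrl_ids <- cm$samples$sample_id[cm$samples$group == "control"]
  n_cases <- length(case_ids)
  n_controls <- length(ctrl_ids)
  a <- rowSums(cm$m[, case_ids, drop = FALSE])
  c_ <- rowSums(cm$m[, ctrl_ids, drop = FALSE])

  res <- gca_from_counts(
    tibble(gene = rownames(cm$m), cases_with = a, controls_with = c_),
    n_cases = n_cases, n_controls = n_controls, alpha = alpha
  )
  res
}

#' Collapsing analysis from a pre-built carrier-count table
#'
#' Runs the statistical layer of the collapsing analysis directly from
#' per-gene carrier counts (e.g. a published results table), without
#' genotype-level data.
#'
#' @param counts Tibble with columns `gene`, `cases_with`, `controls_with`
#'   (carriers per group).
#' @param n_cases,n_controls Group sizes.
#' @param alpha Nominal significance level.
#' @return A `gca_result` (see [run_gca()]).
#' @export
gca_from_counts <- function(counts, n_cases, n_controls, alpha = 0.05) {
  counts <- as_tibble(counts)
  need <- c("gene", "cases_with", "controls_with")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("counts table lacks column(s): ", toString(missing_cols)))
  }
  universe <- counts$gene
  counts <- filter(counts, .data$cases_with + .data$controls_with > 0)
  if (nrow(counts) == 0) abort("no gene has any carrier")

  a <- counts$cases_with
  c_ <- counts$controls_with
  # cache: many genes share the same (a, c) table under fixed margins
  key <- paste(a, c_)
  uniq <- !duplicated(key)
  p_uniq <- vapply(which(uniq), function(i) {
    fisher_two_sided(a[i], n_cases - a[i], c_[i], n_controls - c_[i])
  }, double(1))
  p <- p_uniq[match(key, key[uniq])]

  rate_case <- a / n_cases
  rate_ctrl <- c_ / n_controls
  direction <- dplyr::case_when(
    rate_case > rate_ctrl ~ "case_enriched",
    rate_case < rate_ctrl ~ "control_enriched",
    TRUE ~ "none"
  )
  res <- tibble(
    gene = counts$gene,
    cases_with = as.integer(a),
    cases_without = as.integer(n_cases - a),
    controls_with = as.integer(c_),
    controls_without = as.integer(n_controls - c_),
    p_value = p,
    bonferroni_p = pmin(p * length(universe), 1),
    direction = direction
  ) %>%
    arrange(.data$p_value, desc(.data$cases_with), .data$gene) %>%
    mutate(rank = dplyr::row_number())

  hits <- res$gene[res$p_value < alpha & res$direction == "case_enriched"]
  structure(
    list(results = res, hits = hits, universe = universe,
         n_cases = n_cases, n_controls = n_controls, alpha = alpha),
    class = "gca_result"
  )
}

#' @export
print.gca_result <- function(x, ...) {
  cat(sprintf(
    "<gca_result> %d tested genes (universe %d), %d/%d cases/controls, %d nominal hit(s) at p < %g\n",
    nrow(x$results), length(x$universe), x$n_cases, x$n_controls,
    length(x$hits), x$alpha
  ))
  print(head(x$results, 10))
  invisible(x)
}

#' Compare homozygous ultra-rare burden between two sample strata
#'
#' Counts, per sample, the genes harbouring at least one homozygous
#' (dosage 2) qualifying variant, and compares the two strata with an
#' unpaired Wilcoxon rank-sum (Mann-Whitney) test. This is the appropriate
#' unpaired form for strata of unequal size (a signed-rank test would require
#' pairing).
#'
#' @param vs Tier-filtered [variant_set()].
#' @param samples Sample tibble; only `qc_pass` samples are counted.
#' @param strata Named list of two character vectors of `subpopulation`
#'   labels, e.g. `list(IRN = "IRN", ITA = "ITA")`, defining the strata.
#' @return A list with `summary` (per-stratum tibble: n samples, total
#'   homozygous gene count, mean per sample), `counts` (named list of
#'   per-sample count vectors) and `p_value`.
#' @export
compare_homozygous_burden <- function(vs, samples, strata) {
  stopifnot(inherits(vs, "variant_set"), length(strata) == 2)
  if (is.null(names(strata))) names(strata) <- c("stratum1", "stratum2")
  passing <- filter(samples, .data$qc_pass)
  counts <- lapply(strata, function(labels) {
    ids <- passing$sample_id[passing$subpopulation %in% labels]
    if (length(ids) == 0) abort("stratum with no samples")
    vapply(ids, function(s) {
      hom <- !is.na(vs$geno[, s]) & vs$geno[, s] == 2L
      length(unique(vs$variants$gene[hom & !is.na(vs$variants$gene)]))
    }, integer(1))
  })
  p <- suppressWarnings(
    wilcox.test(counts[[1]], counts[[2]], exact = FALSE)$p.value
  )
  if (is.nan(p)) p <- 1  # both strata constant and equal: no difference detectable
  summary <- tibble(
    stratum = names(counts),
    n_samples = lengths(counts),
    total_homozygous_genes = vapply(counts, sum, double(1)),
    mean_per_sample = vapply(counts, mean, double(1))
  )
  list(summary = summary, counts = counts, p_value = p)
}
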