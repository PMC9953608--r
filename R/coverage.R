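# Coverage quality control. Per-gene x per-sample depth summaries are inputs
# (computed upstream from alignments); this module decides which samples and
# which genes enter the burden analysis. Harmonizing coverage between cases
# and controls prevents spurious burden signal from differential callability.

#' Coverage QC thresholds
#'
#' Bundles every coverage bound used by [sample_qc()] and [harmonize_genes()].
#' A gene is analyzable when (i) its cohort mean depth exceeds
#' `min_gene_mean_depth` (strict), (ii) its cohort mean fraction of target
#' bases covered at >= 10x reaches `min_frac_ge10x` (inclusive), (iii) the
#' fraction of bases under 20x stays below `max_frac_lt20x_per_sample`
#' (strict) in every passing sample, and (iv) case and control group mean
#' depths agree within `max_rel_mean_diff`.
#'
#' @param min_gene_mean_depth Minimum cohort-wide mean depth per gene (x);
#'   default 50.
#' @param min_frac_ge10x Minimum cohort-mean fraction of bases covered at
#'   least 10x; default 0.95.
#' @param max_frac_lt20x_per_sample Per-sample cap on the fraction of bases
#'   covered below 20x; default 0.20.
#' @param max_rel_mean_diff Maximum allowed case/control difference in mean
#'   depth; default 0.10.
#' @param mean_diff_mode `"relative"` (difference divided by the larger group
#'   mean, the default) or `"absolute"` (difference in x).
#' @param min_sample_mean_depth Per-sample QC: minimum cohort-wide mean depth;
#'   default 50.
#' @param max_sample_frac_lt20x Per-sample QC: maximum cohort-wide fraction of
#'   bases covered below 20x; default 0.20.
#' @return A list of class `coverage_thresholds`.
#' @export
coverage_thresholds <- function(min_gene_mean_depth = 50,
                                min_frac_ge10x = 0.95,
                                max_frac_lt20x_per_sample = 0.20,
                                max_rel_mean_diff = 0.10,
                                mean_diff_mode = c("relative", "absolute"),
                                min_sample_mean_depth = 50,
                                max_sample_frac_lt20x = 0.20) {
  mean_diff_mode <- match.arg(mean_diff_mode)
  stopifnot(
    min_gene_mean_depth >= 0, min_sample_mean_depth >= 0,
    min_frac_ge10x >= 0, min_frac_ge10x <= 1,
    max_frac_lt20x_per_sample >= 0, max_frac_lt20x_per_sample <= 1,
    max_rel_mean_diff >= 0,
    max_sample_frac_lt20x >= 0, max_sample_frac_lt20x <= 1
  )
  structure(
    list(
      min_gene_mean_depth = min_gene_mean_depth,
      min_frac_ge10x = min_frac_ge10x,
      max_frac_lt20x_per_sample = max_frac_lt20x_per_sample,
      max_rel_mean_diff = max_rel_mean_diff,
      mean_diff_mode = mean_diff_mode,
      min_sample_mean_depth = min_sample_mean_depth,
      max_sample_frac_lt20x = max_sample_frac_lt20x
    ),
    class = "coverage_thresholds"
  )
}

#' Read a per-gene x per-sample coverage TSV
#'
#' Header `gene,sample_id,mean_depth,frac_lt20x,frac_ge10x`, tab-separated.
#'
#' @param path Path to the TSV.
#' @return A coverage tibble.
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), sample_id = readr::col_character(),
    mean_depth = readr::col_double(), frac_lt20x = readr::col_double(),
    frac_ge10x = readr::col_double()
  ))
}

check_coverage <- function(coverage) {
  need <- c("gene", "sample_id", "mean_depth", "frac_lt20x", "frac_ge10x")
  missing_cols <- setdiff(need, names(coverage))
  if (length(missing_cols)) {
    abort(paste0("coverage table lacks column(s): ", toString(missing_cols)))
  }
  if (any(coverage$frac_lt20x < 0 | coverage$frac_lt20x > 1, na.rm = TRUE) ||
      any(coverage$frac_ge10x < 0 | coverage$frac_ge10x > 1, na.rm = TRUE)) {
    abort("coverage fractions must lie in [0, 1]")
  }
  invisible(coverage)
}

#' Per-sample coverage QC
#'
#' Flags samples whose cohort-wide coverage fails the per-sample bounds: mean
#' of per-gene mean depth below `min_sample_mean_depth`, or mean fraction of
#' bases under 20x above `max_sample_frac_lt20x`. Failing samples are marked
#' `qc_pass = FALSE` and must be excluded from all downstream stages.
#'
#' @param coverage Coverage tibble ([read_coverage()]).
#' @param samples Sample tibble ([sample_table()]).
#' @param thresholds A [coverage_thresholds()] object.
#' @return The sample tibble with `qc_pass` updated.
#' @export
sample_qc <- function(coverage, samples, thresholds = coverage_thresholds()) {
  check_coverage(coverage)
  no_cov <- setdiff(samples$sample_id, unique(coverage$sample_id))
  if (length(no_cov)) {
    abort(paste0("sample(s) without coverage records: ", toString(head(no_cov, 5))))
  }
  per_sample <- coverage %>%
    group_by(.data$sample_id) %>%
    summarise(
      mean_depth = mean(.data$mean_depth),
      frac_lt20x = mean(.data$frac_lt20x),
      .groups = "drop"
    )
  out <- left_join(samples, per_sample, by = "sample_id") %>%
    mutate(
      qc_pass = .data$mean_depth >= thresholds$min_sample_mean_depth &
        .data$frac_lt20x <= thresholds$max_sample_frac_lt20x
    ) %>%
    select("sample_id", "group", "subpopulation", "qc_pass")
  n_fail <- sum(!out$qc_pass)
  if (n_fail > 0) {
    inform(sprintf(
      "sample QC: %d of %d sample(s) failed and are excluded (%s)",
      n_fail, nrow(out), toString(head(out$sample_id[!out$qc_pass], 10))
    ))
  }
  out
}

#' Harmonize per-gene coverage between cases and controls
#'
#' Applies the four gene-inclusion rules (see [coverage_thresholds()]) over
#' QC-passing samples only and returns, for every gene, whether it is
#' analyzable and the first failing rule otherwise. Rule order: (i) cohort
#' mean depth, (ii) cohort fraction >= 10x, (iii) per-sample fraction < 20x,
#' (iv) case/control mean-depth difference. A gene with coverage records in
#' only one group is excluded with reason `"one-sided coverage"`.
#'
#' @inheritParams sample_qc
#' @return A tibble `gene`, `analyzable`, `reason` (`NA` when analyzable). The
#'   analyzable symbols are in `attr(, "analyzable_genes")`.
#' @export
harmonize_genes <- function(coverage, samples, thresholds = coverage_thresholds()) {
  check_coverage(coverage)
  passing <- filter(samples, .data$qc_pass)
  if (nrow(passing) == 0) abort("no QC-passing samples")
  cov <- coverage %>%
    filter(.data$sample_id %in% passing$sample_id) %>%
    left_join(select(passing, "sample_id", "group"), by = "sample_id")

  per_gene <- cov %>%
    group_by(.data$gene) %>%
    summarise(
      mean_depth_all = mean(.data$mean_depth),
      mean_ge10x = mean(.data$frac_ge10x),
      worst_lt20x = max(.data$frac_lt20x),
      mean_case = mean(.data$mean_depth[.data$group == "case"]),
      mean_ctrl = mean(.data$mean_depth[.data$group == "control"]),
      .groups = "drop"
    )

  rel_diff <- if (thresholds$mean_diff_mode == "relative") {
    abs(per_gene$mean_case - per_gene$mean_ctrl) /
      pmax(per_gene$mean_case, per_gene$mean_ctrl)
  } else {
    abs(per_gene$mean_case - per_gene$mean_ctrl)
  }

  reason <- dplyr::case_when(
    is.na(per_gene$mean_case) | is.na(per_gene$mean_ctrl) ~ "one-sided coverage",
    per_gene$mean_depth_all <= thresholds$min_gene_mean_depth ~ "low mean depth",
    per_gene$mean_ge10x < thresholds$min_frac_ge10x ~ "low fraction >=10x",
    per_gene$worst_lt20x >= thresholds$max_frac_lt20x_per_sample ~
      "sample with excess bases <20x",
    rel_diff > thresholds$max_rel_mean_diff ~ "case/control depth imbalance",
    TRUE ~ NA_character_
  )

  out <- tibble(
    gene = per_gene$gene,
    analyzable = is.na(reason),
    reason = reason
  ) %>% arrange(.data$gene)
  attr(out, "analyzable_genes") <- out$gene[out$analyzable]
  out
}

#' Analyzable gene symbols from a harmonization report
#' @param harmonized Output of [harmonize_genes()].
#' @return Character vector of analyzable gene symbols.
#' @export
analyzable_genes <- function(harmonized) {
  attr(harmonized, "analyzable_genes") %||% harmonized$gene[harmonized$analyzable]
}
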