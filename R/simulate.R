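# Synthetic cohort generator. Emits everything the pipeline consumes (VCF,
# sample sheet, coverage summaries, annotation sidecar, GMT gene sets,
# curated list) together with a ground-truth manifest, so every stage can be
# exercised and its recovery measured without access to patient data.
#
# Qualifying (collapsing-tier) carrier events are drawn at the gene x sample
# level at exactly the configured carrier probabilities and then dressed with
# variant-level annotations; non-qualifying decoys (non-PASS, common-AF) and
# the synonymous comparator stream are layered on independently. This keeps
# the generator honest about what the collapsing statistic assumes and makes
# the power enumeration in expected_power() exact for the planted genes.

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a small case-control exome
#' study of non-syndromic cleft palate: 37 enrolled cases (30 of one
#' subpopulation, 7 of a consanguineous one) of which 2 fail per-sample
#' coverage QC leaving 35, 38 controls, 7,500 genes, protein-altering
#' consequence proportions of roughly 96.9% missense / 2.1% stop / 1.0%
#' splice, planted case-enriched risk genes, planted enriched gene sets, and
#' planted coverage-failing genes (one harmonization rule each).
#'
#' @param seed Integer seed; fully determines the bundle.
#' @param n_cases Cases surviving sample QC (default 35).
#' @param n_controls Controls (default 38).
#' @param n_cases_prefilter Enrolled cases, of which
#'   `n_cases_prefilter - n_cases` are planted to fail sample QC (default 37).
#' @param n_iranian_cases Cases in the consanguineous subpopulation `"IRN"`
#'   (default 7); the rest are `"ITA"`. Planted QC failures are drawn from
#'   the `"ITA"` stratum.
#' @param n_genes Number of genes (default 7500).
#' @param background_carrier_prob Per-sample probability of carrying a
#'   qualifying variant in a background gene (default 0.01).
#' @param n_risk_genes Planted risk genes (default 10).
#' @param risk_carrier_prob Case carrier probability in risk genes
#'   (default 0.25).
#' @param n_case_boost_genes Extra genes with elevated case carrier
#'   probability, used to populate the planted case-only gene set
#'   (default 10).
#' @param n_both_boost_genes Genes with elevated carrier probability in both
#'   groups, used for the planted non-exclusive gene set (default 15).
#' @param both_boost_prob Carrier probability (both groups) for those genes
#'   (default 0.15).
#' @param consequence_mix Named probabilities over the protein-altering
#'   classes (normalized internally).
#' @param synonymous_rate Per gene x sample probability of a synonymous
#'   comparator event (default 0.005).
#' @param af_absent_prob Probability that a qualifying variant is absent from
#'   the population frequency resource (default 0.6); otherwise its frequency
#'   is log-uniform on \[1e-6, 1e-2\].
#' @param cadd_mean,cadd_sd CADD PHRED scores are drawn Normal and truncated
#'   at 0 (defaults 18 and 8, spanning the 20 threshold).
#' @param hom_prob Probability a carrier event is homozygous (dosage 2;
#'   default 0.04).
#' @param consanguineous_multiplier Multiplier on `hom_prob` for the
#'   consanguineous subpopulation (default 2).
#' @param decoy_rate Per gene x sample rate of non-qualifying decoy variants
#'   (half non-PASS, half common-frequency; default 0.002).
#' @param missing_rate Probability a non-carrier genotype is emitted as
#'   missing (`./.`; default 0.002).
#' @param n_uneven_genes Planted coverage-harmonization failures, spread over
#'   the four gene rules (default 20).
#' @param n_gene_sets Null gene sets in the GMT (default 40).
#' @param n_curated_decoys Background genes added to the planted risk genes
#'   to form the curated disease list (default 15, giving a 25-gene list).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 35L,
                              n_controls = 38L,
                              n_cases_prefilter = 37L,
                              n_iranian_cases = 7L,
                              n_genes = 7500L,
                              background_carrier_prob = 0.01,
                              n_risk_genes = 10L,
                              risk_carrier_prob = 0.25,
                              n_case_boost_genes = 10L,
                              n_both_boost_genes = 15L,
                              both_boost_prob = 0.15,
                              consequence_mix = c(
                                missense = 0.969, stop_gained = 0.0188,
                                stop_lost = 0.002, splice_acceptor = 0.0051,
                                splice_donor = 0.0051
                              ),
                              synonymous_rate = 0.005,
                              af_absent_prob = 0.6,
                              cadd_mean = 18, cadd_sd = 8,
                              hom_prob = 0.04,
                              consanguineous_multiplier = 2,
                              decoy_rate = 0.002,
                              missing_rate = 0.002,
                              n_uneven_genes = 20L,
                              n_gene_sets = 40L,
                              n_curated_decoys = 15L) {
  cfg <- as.list(environment())
  probs <- c(background_carrier_prob, risk_carrier_prob, both_boost_prob,
             synonymous_rate, af_absent_prob, hom_prob, decoy_rate,
             missing_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_cases_prefilter < n_cases) {
    abort("n_cases_prefilter must be >= n_cases")
  }
  if (n_iranian_cases > n_cases) abort("n_iranian_cases must be <= n_cases")
  n_special <- n_risk_genes + n_case_boost_genes + n_both_boost_genes +
    n_uneven_genes + n_curated_decoys
  if (n_special > n_genes) {
    abort("planted gene counts exceed n_genes")
  }
  if (any(consequence_mix < 0) || sum(consequence_mix) <= 0) {
    abort("consequence_mix must be a non-negative, non-degenerate mixture")
  }
  bad <- setdiff(names(consequence_mix), protein_altering_classes())
  if (length(bad)) abort(paste0("consequence_mix has unknown class(es): ", toString(bad)))
  cfg$consequence_mix <- consequence_mix / sum(consequence_mix)
  structure(cfg, class = "sim_config")
}

# log-uniform draw on [lo, hi]
rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

sample_qualifying_annotations <- function(n, cfg) {
  tibble(
    consequence = sample(names(cfg$consequence_mix), n, replace = TRUE,
                         prob = cfg$consequence_mix),
    gnomad_af = ifelse(runif(n) < cfg$af_absent_prob, NA_real_,
                       rlogunif(n, 1e-6, 1e-2)),
    cadd_phred = round(pmax(rnorm(n, cfg$cadd_mean, cfg$cadd_sd), 0), 1),
    filter = "PASS"
  )
}

#' Simulate a synthetic case-control exome cohort
#'
#' Draws the full bundle in memory; see [simulation_config()] for what is
#' planted. Use [write_cohort()] to materialize it as files and
#' [generate_cohort()] for both at once.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cohort_bundle` with elements `samples`
#'   (pre-QC sample tibble), `variants` (a [variant_set()]), `coverage`
#'   (coverage tibble), `gene_sets` (GMT-style tibble), `curated`
#'   (character), `manifest` (ground-truth list) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## --- samples ------------------------------------------------------------
  n_ita <- cfg$n_cases_prefilter - cfg$n_iranian_cases
  case_ids <- sprintf("CASE%03d", seq_len(cfg$n_cases_prefilter))
  ctrl_ids <- sprintf("CTRL%03d", seq_len(cfg$n_controls))
  subpop <- c(rep("ITA", n_ita), rep("IRN", cfg$n_iranian_cases))
  samples <- sample_table(
    c(case_ids, ctrl_ids),
    c(rep("case", cfg$n_cases_prefilter), rep("control", cfg$n_controls)),
    c(subpop, rep("ITA", cfg$n_controls))
  )
  n_fail <- cfg$n_cases_prefilter - cfg$n_cases
  failing <- sort(sample(case_ids[seq_len(n_ita)], n_fail))

  ## --- gene roles ----------------------------------------------------------
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  special <- sample(genes, cfg$n_risk_genes + cfg$n_case_boost_genes +
                      cfg$n_both_boost_genes + cfg$n_uneven_genes +
                      cfg$n_curated_decoys)
  take <- function(n) {
    if (n == 0L) return(character())
    out <- special[seq_len(n)]
    special <<- special[-seq_len(n)]
    out
  }
  risk_genes <- sort(take(cfg$n_risk_genes))
  case_boost <- sort(take(cfg$n_case_boost_genes))
  both_boost <- sort(take(cfg$n_both_boost_genes))
  uneven <- take(cfg$n_uneven_genes)
  curated_decoys <- sort(take(cfg$n_curated_decoys))
  uneven_rules <- rep(c("low mean depth", "low fraction >=10x",
                        "sample with excess bases <20x",
                        "case/control depth imbalance"),
                      length.out = cfg$n_uneven_genes)
  names(uneven_rules) <- uneven

  ## --- coverage ------------------------------------------------------------
  all_ids <- samples$sample_id
  n_samp <- length(all_ids)
  is_case <- samples$group == "case"
  base_depth <- runif(cfg$n_genes, 80, 120)
  depth <- matrix(base_depth, cfg$n_genes, n_samp) +
    matrix(rnorm(cfg$n_genes * n_samp, 0, 5), cfg$n_genes, n_samp)
  lt20 <- matrix(runif(cfg$n_genes * n_samp, 0, 0.05), cfg$n_genes, n_samp)
  ge10 <- matrix(runif(cfg$n_genes * n_samp, 0.97, 1), cfg$n_genes, n_samp)
  rownames(depth) <- rownames(lt20) <- rownames(ge10) <- genes
  colnames(depth) <- colnames(lt20) <- colnames(ge10) <- all_ids

  passing_ids <- setdiff(all_ids, failing)
  for (g in uneven) {
    rule <- uneven_rules[[g]]
    if (rule == "low mean depth") {
      depth[g, ] <- 40 + rnorm(n_samp, 0, 2)
    } else if (rule == "low fraction >=10x") {
      ge10[g, ] <- runif(n_samp, 0.85, 0.93)
    } else if (rule == "sample with excess bases <20x") {
      victim <- sample(passing_ids, 1)
      lt20[g, victim] <- runif(1, 0.25, 0.35)
    } else {
      depth[g, is_case] <- 100 + rnorm(sum(is_case), 0, 2)
      depth[g, !is_case] <- 115 + rnorm(sum(!is_case), 0, 2)
    }
  }
  depth[, failing] <- depth[, failing, drop = FALSE] * 0.3  # fails sample QC
  depth <- pmax(depth, 1)

  coverage <- tibble(
    gene = rep(genes, times = n_samp),
    sample_id = rep(all_ids, each = cfg$n_genes),
    mean_depth = round(as.vector(depth), 2),
    frac_lt20x = round(as.vector(lt20), 4),
    frac_ge10x = round(as.vector(ge10), 4)
  )

  ## --- qualifying carrier events -------------------------------------------
  p_mat <- matrix(cfg$background_carrier_prob, cfg$n_genes, n_samp,
                  dimnames = list(genes, all_ids))
  p_mat[risk_genes, is_case] <- cfg$risk_carrier_prob
  p_mat[case_boost, is_case] <- cfg$risk_carrier_prob
  p_mat[both_boost, ] <- cfg$both_boost_prob
  events <- which(matrix(runif(length(p_mat)), nrow(p_mat)) < p_mat, arr.ind = TRUE)

  ev <- tibble(
    gene = genes[events[, 1]],
    sample_id = all_ids[events[, 2]],
    stream = "qualifying"
  )
  ann_q <- sample_qualifying_annotations(nrow(ev), cfg)

  ## homozygosity: dosage 2 with per-sample-adjusted probability
  hom_p <- ifelse(samples$subpopulation[match(ev$sample_id, samples$sample_id)] == "IRN",
                  pmin(cfg$hom_prob * cfg$consanguineous_multiplier, 1), cfg$hom_prob)
  dosage_q <- ifelse(runif(nrow(ev)) < hom_p, 2L, 1L)

  ## --- synonymous comparator stream ----------------------------------------
  ev_s_idx <- which(matrix(runif(cfg$n_genes * n_samp), cfg$n_genes) <
                      cfg$synonymous_rate, arr.ind = TRUE)
  ev_s <- tibble(
    gene = genes[ev_s_idx[, 1]],
    sample_id = all_ids[ev_s_idx[, 2]],
    stream = "synonymous"
  )
  ann_s <- sample_qualifying_annotations(nrow(ev_s), cfg)
  ann_s$consequence <- "synonymous"

  ## --- decoy stream (non-PASS or common-frequency) --------------------------
  ev_d_idx <- which(matrix(runif(cfg$n_genes * n_samp), cfg$n_genes) <
                      cfg$decoy_rate, arr.ind = TRUE)
  ev_d <- tibble(
    gene = genes[ev_d_idx[, 1]],
    sample_id = all_ids[ev_d_idx[, 2]],
    stream = "decoy"
  )
  ann_d <- sample_qualifying_annotations(nrow(ev_d), cfg)
  non_pass <- runif(nrow(ev_d)) < 0.5
  ann_d$filter[non_pass] <- "LowQual"
  ann_d$gnomad_af[!non_pass] <- rlogunif(sum(!non_pass), 0.011, 0.5)

  all_ev <- bind_rows(ev, ev_s, ev_d)
  all_ann <- bind_rows(ann_q, ann_s, ann_d)
  dosage <- c(dosage_q, rep(1L, nrow(ev_s)), rep(1L, nrow(ev_d)))

  ## --- variant records on a synthetic contig --------------------------------
  ## each gene owns a non-overlapping 10 kb interval on contig "chrS"
  gene_index <- match(all_ev$gene, genes)
  n_var <- nrow(all_ev)
  offset <- integer(n_var)
  for (gi in unique(gene_index)) {
    idx <- which(gene_index == gi)
    offset[idx] <- sample(9000L, length(idx))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  variants <- tibble(
    chrom = "chrS",
    pos = (gene_index - 1L) * 10000L + offset,
    ref = ref, alt = alt,
    gene = all_ev$gene,
    consequence = all_ann$consequence,
    gnomad_af = all_ann$gnomad_af,
    cadd_phred = all_ann$cadd_phred,
    filter = all_ann$filter
  )
  ord <- order(variants$pos)
  variants <- variants[ord, ]
  all_ev <- all_ev[ord, ]
  dosage <- dosage[ord]

  geno <- matrix(0L, n_var, n_samp, dimnames = list(NULL, all_ids))
  geno[cbind(seq_len(n_var), match(all_ev$sample_id, all_ids))] <- dosage
  miss <- matrix(runif(n_var * n_samp) < cfg$missing_rate, n_var)
  miss[geno > 0L] <- FALSE
  geno[miss] <- NA_integer_

  vs <- variant_set(variants, geno)

  ## --- gene sets -------------------------------------------------------------
  categories <- c("GO:MF", "GO:CC", "Pathway")
  null_sets <- lapply(seq_len(cfg$n_gene_sets), function(i) {
    list(
      term_id = sprintf("NULLSET%03d", i),
      category = categories[(i - 1L) %% 3L + 1L],
      members = sort(sample(genes, sample(10:50, 1)))
    )
  })
  planted_case_id <- "PLANTED_CASE_SET"
  planted_both_id <- "PLANTED_BOTH_SET"
  gene_sets <- tibble(
    term_id = c(planted_case_id, planted_both_id,
                vapply(null_sets, `[[`, character(1), "term_id")),
    term_name = c(planted_case_id, planted_both_id,
                  vapply(null_sets, `[[`, character(1), "term_id")),
    category = c("Pathway", "GO:MF",
                 vapply(null_sets, `[[`, character(1), "category")),
    members = c(list(sort(c(risk_genes, case_boost)), both_boost),
                lapply(null_sets, `[[`, "members"))
  )

  curated <- sort(c(risk_genes, curated_decoys))

  manifest <- list(
    seed = cfg$seed,
    n_cases = cfg$n_cases, n_controls = cfg$n_controls,
    n_cases_prefilter = cfg$n_cases_prefilter,
    failing_samples = failing,
    risk_genes = risk_genes,
    case_boost_genes = case_boost,
    both_boost_genes = both_boost,
    uneven_genes = as.list(uneven_rules),
    curated_genes = curated,
    planted_case_set = planted_case_id,
    planted_both_set = planted_both_id,
    n_variants = n_var,
    n_qualifying_events = nrow(ev)
  )

  structure(
    list(samples = samples, variants = vs, coverage = coverage,
         gene_sets = gene_sets, curated = curated, manifest = manifest,
         config = cfg),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> seed %d: %d samples, %d genes, %d variants\n",
    x$config$seed, nrow(x$samples), x$config$n_genes, n_variants(x$variants)
  ))
  invisible(x)
}

#' Write a simulated cohort bundle to disk
#'
#' Materializes a [simulate_cohort()] bundle as plain-text files: `cohort.vcf`
#' (VCF 4.2 with per-sample GTs and a `CSQ` INFO field), `annotations.tsv`
#' (sidecar annotation table), `samples.tsv`, `coverage.tsv`, `gene_sets.gmt`,
#' `curated_genes.txt` and `manifest.json`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- bundle$variants$variants
  geno <- bundle$variants$geno

  gt <- matrix("0/0", nrow(geno), ncol(geno))
  gt[!is.na(geno) & geno == 1L] <- "0/1"
  gt[!is.na(geno) & geno == 2L] <- "1/1"
  gt[is.na(geno)] <- "./."

  fmt_af <- ifelse(is.na(v$gnomad_af), "", formatC(v$gnomad_af, format = "g", digits = 6))
  fmt_cadd <- ifelse(is.na(v$cadd_phred), "", formatC(v$cadd_phred, format = "g", digits = 6))
  info <- sprintf("CSQ=%s|%s|%s|%s", v$gene, v$consequence, fmt_af, fmt_cadd)

  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"gene|consequence|gnomad_af|cadd_phred\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter, info, "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), file.path(dir, "cohort.vcf"))

  write_annotations(v, file.path(dir, "annotations.tsv"))
  readr::write_tsv(bundle$samples[, c("sample_id", "group", "subpopulation")],
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(bundle$coverage, file.path(dir, "coverage.tsv"))
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_lines(bundle$curated, file.path(dir, "curated_genes.txt"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate and optionally write a cohort bundle
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory passed to [write_cohort()].
#' @return The `cohort_bundle`, invisibly when written.
#' @export
generate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  bundle <- simulate_cohort(config)
  if (!is.null(out_dir)) {
    write_cohort(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Read a written cohort bundle back from disk
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A list with the same data elements as [simulate_cohort()] (the
#'   variant set is re-read from the VCF plus sidecar annotations).
#' @export
read_cohort <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  vs <- read_vcf(file.path(dir, "cohort.vcf"), samples, annotations = ann)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  structure(
    list(
      samples = samples,
      variants = vs,
      coverage = read_coverage(file.path(dir, "coverage.tsv")),
      gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
      curated = read_gene_list(file.path(dir, "curated_genes.txt")),
      manifest = manifest
    ),
    class = "cohort_bundle"
  )
}

#' Exact power of the collapsing test for a planted risk gene
#'
#' Enumerates case-carrier counts `a ~ Binomial(n_cases, risk_carrier_prob)`
#' and control-carrier counts `c ~ Binomial(n_controls,
#' background_carrier_prob)` and accumulates the probability that the
#' two-sided Fisher exact p-value falls below `alpha`.
#'
#' @param config A [simulation_config()].
#' @param alpha Nominal level; default 0.05.
#' @return The per-gene probability that a planted risk gene attains
#'   `p < alpha`.
#' @export
expected_power <- function(config = simulation_config(), alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  n1 <- config$n_cases
  n2 <- config$n_controls
  pa <- stats::dbinom(0:n1, n1, config$risk_carrier_prob)
  pc <- stats::dbinom(0:n2, n2, config$background_carrier_prob)
  power <- 0
  for (a in 0:n1) {
    if (pa[a + 1] < 1e-15) next
    for (cc in 0:n2) {
      if (pc[cc + 1] < 1e-15) next
      if (fisher_two_sided(a, n1 - a, cc, n2 - cc) < alpha) {
        power <- power + pa[a + 1] * pc[cc + 1]
      }
    }
  }
  power
}
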