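test_that("two-sided Fisher matches the enumeration oracle on random tables", {
  set.seed(101)
  for (i in 1:300) {
    t <- rand_table()
    expect_equal(fisher_two_sided(t["a"], t["b"], t["c"], t["d"]),
                 fisher_enum_oracle(t["a"], t["b"], t["c"], t["d"]),
                 tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(fisher_two_sided(t["a"], t["b"], t["c"], t["d"]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher test is symmetric under group swap and handles degeneracy", {
  expect_equal(fisher_two_sided(7, 28, 0, 38), fisher_two_sided(0, 38, 7, 28))
  expect_equal(fisher_two_sided(9, 26, 2, 36), fisher_two_sided(2, 36, 9, 26))
  expect_equal(fisher_two_sided(0, 35, 0, 38), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_two_sided(0, 0, 1, 2), "margin")
})

test_that("all published per-gene p-values reproduce at 4-decimal rounding", {
  tab <- gca_counts_table()
  p <- vapply(seq_len(nrow(tab)), function(i) {
    fisher_two_sided(tab$cases_with[i], 35 - tab$cases_with[i],
                     tab$controls_with[i], 38 - tab$controls_with[i])
  }, double(1))
  expect_equal(round(p, 4), tab$p_printed)
})

test_that("carrier coding is binary and aggregates per gene", {
  samples <- sample_table(sprintf("S%d", 1:6),
                          rep(c("case", "control"), each = 3))
  v <- tibble::tibble(
    chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A", alt = "G",
    gene = c("GA", "GA", "GA", "GB"),
    consequence = "missense", gnomad_af = NA_real_, cadd_phred = 30,
    filter = "PASS"
  )
  g <- rbind(
    c(1L, 0L, 0L, 0L, 0L, 0L),
    c(2L, 0L, 0L, 0L, 0L, 0L),  # same sample, 3 variants in GA -> still 1
    c(1L, 0L, 0L, 1L, 0L, 0L),
    c(0L, NA, 0L, 0L, 0L, 1L)   # missing genotype counts as non-carrier
  )
  colnames(g) <- samples$sample_id
  cm <- suppressMessages(build_carrier_matrix(variant_set(v, g), samples))
  expect_equal(sort(rownames(cm$m)), c("GA", "GB"))
  expect_equal(unname(cm$m["GA", ]), c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(unname(cm$m["GB", ]), c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(all(cm$m %in% 0:1))

  # empty variant collection -> empty matrix
  empty <- build_carrier_matrix(
    variant_set(v[0, ], g[0, , drop = FALSE]), samples)
  expect_equal(nrow(empty$m), 0)
})

test_that("collapsing results rank by p, flag direction, and expose the universe", {
  tab <- gca_counts_table()
  gca <- gca_from_counts(tab, n_cases = 35, n_controls = 38)
  expect_equal(nrow(gca$results), 39)
  expect_equal(sum(gca$results$p_value < 0.05), 39)
  expect_equal(sum(gca$results$direction == "case_enriched"), 38)
  expect_equal(gca$results$gene[gca$results$direction == "control_enriched"], "EXO1")
  # EXO1 is control-enriched, hence not a nominal hit
  expect_equal(length(gca$hits), 38)
  expect_false("EXO1" %in% gca$hits)
  # ranking: ascending p, ties by descending case carriers then symbol
  expect_equal(gca$results$gene[1], "ZFYVE26")
  expect_true(!is.unsorted(gca$results$p_value))
  expect_equal(gca$results$rank, seq_len(39))
  # identical carrier rates -> no hits
  null_gca <- gca_from_counts(
    tibble::tibble(gene = c("A", "B"), cases_with = c(2L, 1L),
                   controls_with = c(2L, 1L)),
    n_cases = 10, n_controls = 10)
  expect_equal(length(null_gca$hits), 0)
})

test_that("under the global null few genes reach nominal significance", {
  cfg <- small_config(seed = 9, n_genes = 800L, n_risk_genes = 0L,
                      n_case_boost_genes = 0L, n_both_boost_genes = 0L,
                      n_uneven_genes = 0L)
  bundle <- simulate_cohort(cfg)
  vs <- apply_filter(bundle$variants, profile_gca())
  samples <- bundle$samples
  samples$qc_pass <- TRUE
  cm <- suppressMessages(build_carrier_matrix(vs, samples))
  gca <- run_gca(cm)
  frac <- mean(gca$results$p_value < 0.05)
  n <- nrow(gca$results)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("homozygous burden comparison agrees with a permutation oracle", {
  # per-sample homozygous gene counts: 7 vs 27 samples, totals 8 and 19
  x <- c(rep(1, 6), 2)
  y <- c(rep(1, 19), rep(0, 8))
  build_hom_vs <- function(counts, ids) {
    genes <- sprintf("H%03d", seq_len(max(sum(counts), 1)))
    rows <- list(); dos <- list()
    gi <- 1
    for (s in seq_along(ids)) {
      if (counts[s] == 0) next
      take <- genes[gi:(gi + counts[s] - 1)]; gi <- gi + counts[s]
      rows[[s]] <- take
    }
    all_genes <- unlist(rows)
    v <- tibble::tibble(
      chrom = "1", pos = seq_along(all_genes) * 10L, ref = "A", alt = "G",
      gene = all_genes, consequence = "missense", gnomad_af = NA_real_,
      cadd_phred = 30, filter = "PASS")
    g <- matrix(0L, length(all_genes), length(ids),
                dimnames = list(NULL, ids))
    r <- 1
    for (s in seq_along(ids)) {
      if (counts[s] == 0) next
      g[r:(r + counts[s] - 1), s] <- 2L
      r <- r + counts[s]
    }
    variant_set(v, g)
  }
  ids <- c(sprintf("I%02d", seq_along(x)), sprintf("T%02d", seq_along(y)))
  samples <- sample_table(ids, "case",
                          subpopulation = rep(c("IRN", "ITA"), c(length(x), length(y))))
  # regenerate gene names uniquely across strata
  vs <- build_hom_vs(c(x, y), ids)
  res <- compare_homozygous_burden(vs, samples, list(IRN = "IRN", ITA = "ITA"))
  expect_equal(unname(res$summary$n_samples), c(7L, 27L))
  expect_equal(unname(res$summary$total_homozygous_genes), c(8, 19))
  p_perm <- ranksum_perm_oracle(x, y)
  expect_lt(abs(res$p_value - p_perm), 0.05)

  # identical count vectors: no detectable difference
  same <- compare_homozygous_burden(
    build_hom_vs(c(1, 1, 2, 1, 1, 2), sprintf("Z%d", 1:6)),
    sample_table(sprintf("Z%d", 1:6), "case",
                 subpopulation = rep(c("A", "B"), each = 3)),
    list(A = "A", B = "B"))
  expect_gt(same$p_value, 0.9)
})

test_that("a strongly inflated homozygote stratum is detected", {
  set.seed(21)
  ids <- sprintf("S%02d", 1:40)
  counts <- c(rpois(20, 5), rpois(20, 1))
  genes <- sprintf("H%04d", seq_len(sum(counts)))
  v <- tibble::tibble(
    chrom = "1", pos = seq_along(genes) * 10L, ref = "A", alt = "G",
    gene = genes, consequence = "missense", gnomad_af = NA_real_,
    cadd_phred = 30, filter = "PASS")
  g <- matrix(0L, length(genes), 40, dimnames = list(NULL, ids))
  r <- 1
  for (s in 1:40) {
    if (counts[s] > 0) {
      g[r:(r + counts[s] - 1), s] <- 2L
      r <- r + counts[s]
    }
  }
  samples <- sample_table(ids, "case",
                          subpopulation = rep(c("CONSANG", "OUTBRED"), each = 20))
  res <- compare_homozygous_burden(variant_set(v, g), samples,
                                   list(a = "CONSANG", b = "OUTBRED"))
  expect_lt(res$p_value, 0.05)
  expect_error(
    compare_homozygous_burden(variant_set(v, g), samples,
                              list(a = "CONSANG", b = "NOSUCH")),
    "no samples")
})
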