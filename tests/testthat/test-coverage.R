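# coverage grid builder: one row per gene x sample
cov_grid <- function(samples, genes, mean_depth = 100, frac_lt20x = 0.02,
                     frac_ge10x = 0.99) {
  tidyr::expand_grid(gene = genes, sample_id = samples$sample_id) |>
    dplyr::mutate(mean_depth = mean_depth, frac_lt20x = frac_lt20x,
                  frac_ge10x = frac_ge10x)
}

samples6 <- sample_table(sprintf("S%d", 1:6),
                         rep(c("case", "control"), each = 3))

test_that("sample QC flags samples below the cohort-wide bounds", {
  cov <- cov_grid(samples6, sprintf("G%d", 1:5))
  cov$mean_depth[cov$sample_id == "S2"] <- 30
  out <- suppressMessages(sample_qc(cov, samples6))
  expect_equal(out$sample_id[!out$qc_pass], "S2")
  expect_equal(sum(out$qc_pass), 5)

  # all above bounds -> all pass
  out2 <- sample_qc(cov_grid(samples6, "G1"), samples6)
  expect_true(all(out2$qc_pass))

  # sample with zero coverage records is a hard error
  expect_error(sample_qc(dplyr::filter(cov, sample_id != "S1"), samples6),
               "without coverage")
})

test_that("gene harmonization applies the four rules with stated boundaries", {
  genes <- c("OK", "DEPTH49", "DEPTH50", "GE10X", "LT20X", "IMBAL")
  cov <- cov_grid(samples6, genes)
  cov$mean_depth[cov$gene == "DEPTH49"] <- 49
  cov$mean_depth[cov$gene == "DEPTH50"] <- 50        # "> 50x" is strict
  cov$frac_ge10x[cov$gene == "GE10X"] <- 0.94
  cov$frac_lt20x[cov$gene == "LT20X" & cov$sample_id == "S5"] <- 0.25
  cov$mean_depth[cov$gene == "IMBAL"] <-
    ifelse(cov$sample_id[cov$gene == "IMBAL"] %in% c("S1", "S2", "S3"), 100, 115)

  out <- harmonize_genes(cov, samples6)
  reason <- setNames(out$reason, out$gene)
  expect_true(out$analyzable[out$gene == "OK"])
  expect_equal(reason[["DEPTH49"]], "low mean depth")
  expect_equal(reason[["DEPTH50"]], "low mean depth")
  expect_equal(reason[["GE10X"]], "low fraction >=10x")
  expect_equal(reason[["LT20X"]], "sample with excess bases <20x")
  # |100 - 115| / 115 = 0.1304 > 0.10
  expect_equal(reason[["IMBAL"]], "case/control depth imbalance")
  expect_setequal(analyzable_genes(out), "OK")
})

test_that("boundary conventions: >= 0.95 at 10x is inclusive, rel diff <= 0.10 kept", {
  cov <- cov_grid(samples6, c("A", "B"))
  cov$frac_ge10x[cov$gene == "A"] <- 0.95
  cov$mean_depth[cov$gene == "B"] <-
    ifelse(cov$sample_id[cov$gene == "B"] %in% c("S1", "S2", "S3"), 100, 110)
  out <- harmonize_genes(cov, samples6)
  expect_true(all(out$analyzable))  # 0.95 passes; |100-110|/110 = 0.0909 passes
})

test_that("absolute mean-difference mode is available", {
  cov <- cov_grid(samples6, "A")
  cov$mean_depth <- ifelse(cov$sample_id %in% c("S1", "S2", "S3"), 100, 115)
  rel <- harmonize_genes(cov, samples6)
  abs_loose <- harmonize_genes(cov, samples6, coverage_thresholds(
    mean_diff_mode = "absolute", max_rel_mean_diff = 20))
  abs_tight <- harmonize_genes(cov, samples6, coverage_thresholds(
    mean_diff_mode = "absolute", max_rel_mean_diff = 10))
  expect_false(rel$analyzable)
  expect_true(abs_loose$analyzable)
  expect_false(abs_tight$analyzable)
})

test_that("a gene covered in only one group is excluded as one-sided", {
  cov <- cov_grid(samples6, "A") |>
    dplyr::filter(sample_id %in% c("S1", "S2", "S3"))
  # give the controls records for another gene so they are QC-able
  cov2 <- dplyr::bind_rows(cov, cov_grid(samples6, "B"))
  out <- harmonize_genes(cov2, samples6)
  expect_equal(out$reason[out$gene == "A"], "one-sided coverage")
})

test_that("relaxing thresholds never shrinks the analyzable set", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:40)
  cov <- cov_grid(samples6, genes,
                  mean_depth = runif(240, 30, 130),
                  frac_lt20x = runif(240, 0, 0.3),
                  frac_ge10x = runif(240, 0.85, 1))
  strict <- analyzable_genes(harmonize_genes(cov, samples6))
  relaxed <- analyzable_genes(harmonize_genes(cov, samples6, coverage_thresholds(
    min_gene_mean_depth = 30, min_frac_ge10x = 0.85,
    max_frac_lt20x_per_sample = 0.35, max_rel_mean_diff = 0.5)))
  expect_true(all(strict %in% relaxed))
})

test_that("harmonization is independent of input record order", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:20)
  cov <- cov_grid(samples6, genes,
                  mean_depth = runif(120, 30, 130),
                  frac_lt20x = runif(120, 0, 0.3),
                  frac_ge10x = runif(120, 0.85, 1))
  shuffled <- cov[sample(nrow(cov)), ]
  expect_equal(harmonize_genes(cov, samples6),
               harmonize_genes(shuffled, samples6),
               ignore_attr = TRUE)
})
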