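samples4 <- sample_table(c("S1", "S2", "S3", "S4"),
                         c("case", "case", "control", "control"))

test_that("sample table enforces uniqueness and group levels", {
  expect_error(sample_table(c("A", "A"), c("case", "control")), "unique")
  expect_error(sample_table(c("A", "B"), c("case", "patient")), "group")
  expect_equal(nrow(samples4), 4)
})

test_that("VCF reading attaches CSQ annotations and preserves FILTER", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tCSQ=GENEA|missense|0.001|25\tGT\t0/1\t0/0\t0/0\t1/1",
    "chr1\t200\t.\tC\tT\t.\tLowQual\tCSQ=GENEA|synonymous||12\tGT\t0/0\t0/1\t./.\t0/0",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1\t0/0"
  ))
  vs <- read_vcf(path, samples4)
  expect_equal(n_variants(vs), 3)
  expect_equal(vs$variants$filter, c("PASS", "LowQual", "PASS"))
  expect_equal(vs$variants$gene[1:2], c("GENEA", "GENEA"))
  # un-annotated record retained as consequence "other"
  expect_equal(vs$variants$consequence[3], "other")
  # absent AF field -> NA
  expect_true(is.na(vs$variants$gnomad_af[2]))
  # dosages incl. missing call
  expect_equal(unname(vs$geno[1, ]), c(1L, 0L, 0L, 2L))
  expect_true(is.na(vs$geno[2, "S3"]))
})

test_that("multi-allelic sites split into one record per alt allele", {
  path <- write_test_vcf(
    "chr1\t500\t.\tG\tA,T\t.\tPASS\tCSQ=GENEB|missense|0.002|11\tGT\t0/1\t0/2\t1/2\t0/0"
  )
  vs <- read_vcf(path, samples4)
  expect_equal(n_variants(vs), 2)
  expect_equal(vs$variants$chrom, c("chr1", "chr1"))
  expect_equal(vs$variants$pos, c(500L, 500L))
  expect_equal(vs$variants$ref, c("G", "G"))
  expect_setequal(vs$variants$alt, c("A", "T"))
  # per-alt dosages: S3 is 1/2 -> one copy of each alt
  a_row <- which(vs$variants$alt == "A")
  t_row <- which(vs$variants$alt == "T")
  expect_equal(unname(vs$geno[a_row, ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(vs$geno[t_row, ]), c(0L, 1L, 1L, 0L))
})

test_that("genotype columns absent from the sample sheet are an error", {
  path <- write_test_vcf(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0\t0/0",
    samples = c("S1", "S2", "S3", "UNKNOWN")
  )
  expect_error(read_vcf(path, samples4), "absent from the sample sheet")
})

test_that("a recorded population frequency of zero is treated as absent", {
  # stop-gain with printed frequency 0 and CADD 46: absent from the resource
  vs <- col2a1_gli3_variants()
  i <- which(vs$variants$pos == 48373812L)
  expect_equal(vs$variants$consequence[i], "stop_gained")
  expect_true(is.na(vs$variants$gnomad_af[i]))
  expect_equal(vs$variants$cadd_phred[i], 46)
})

test_that("sidecar annotation TSV round-trips field-by-field", {
  vs <- col2a1_gli3_variants()
  path <- tempfile(fileext = ".tsv")
  write_annotations(vs$variants, path)
  back <- read_annotations(path)
  expect_equal(as.data.frame(back),
               as.data.frame(vs$variants[, names(back)]))
})

test_that("variant set rejects duplicated normalized keys and bad records", {
  v <- tibble::tibble(
    chrom = c("1", "1"), pos = c(10L, 10L), ref = c("A", "A"), alt = c("G", "G"),
    gene = "X", consequence = "missense", gnomad_af = NA_real_,
    cadd_phred = 10, filter = "PASS"
  )
  g <- matrix(0L, 2, 2, dimnames = list(NULL, c("S1", "S2")))
  expect_error(variant_set(v, g), "unique")
  v2 <- v[1, ]; v2$alt <- "A"
  expect_error(variant_set(v2, g[1, , drop = FALSE]), "differ")
})

test_that("GMT parsing handles categories, duplicates and malformed lines", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c(
    "ECM\tPathway\tCOL2A1\tLAMA3",
    "SETB\t\tG1\tG2\tG2\tG3"
  ), path)
  sets <- read_gmt(path)
  expect_equal(nrow(sets), 2)
  expect_setequal(sets$members[[1]], c("COL2A1", "LAMA3"))
  expect_equal(sets$category, c("Pathway", "uncategorized"))
  expect_equal(length(sets$members[[2]]), 3)  # duplicate dropped

  writeLines("ONLY\tTWO", path)
  expect_error(read_gmt(path), "fewer than 3")

  writeLines(character(), path)
  expect_equal(nrow(read_gmt(path)), 0)
})

test_that("a published 12-member pathway fixture keeps its set size", {
  members <- c("COL2A1", "COL4A2", "COL5A2", "ITGA10", "TNN", "LAMA1",
               "ITGA2B", "ITGB7", "LAMA3", "LAMA4", "LAMB2", "LAMB3")
  path <- tempfile(fileext = ".gmt")
  writeLines(paste(c("M7098", "Pathway", members), collapse = "\t"), path)
  sets <- read_gmt(path)
  expect_equal(length(sets$members[[1]]), 12)
})

test_that("curated gene lists are uppercased and de-duplicated", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("col2a1", "GLI3", "COL2A1", "", "  irf6 "), path)
  expect_setequal(read_gene_list(path), c("COL2A1", "GLI3", "IRF6"))
  writeLines(character(), path)
  expect_error(read_gene_list(path), "empty")
})
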