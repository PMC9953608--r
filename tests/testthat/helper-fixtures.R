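# Shared fixtures built in code.

# small, fast simulation settings for unit tests (cohort sizes kept at their
# defaults because carrier probabilities are calibrated to them)
small_config <- function(seed = 1, n_genes = 400L, n_gene_sets = 12L, ...) {
  simulation_config(seed = seed, n_genes = n_genes, n_gene_sets = n_gene_sets, ...)
}

# published per-gene carrier counts with their printed two-sided Fisher
# p-values (35 cases vs 38 controls)
gca_counts_table <- function() {
  tibble::tribble(
    ~gene, ~cases_with, ~controls_with, ~p_printed,
    "ZFYVE26", 7L, 0L, 0.0041,
    "THSD7B", 6L, 0L, 0.0095,
    "SPATC1", 6L, 0L, 0.0095,
    "IGHG1", 6L, 0L, 0.0095,
    "EXO1", 0L, 7L, 0.0119,
    "JAKMIP3", 9L, 2L, 0.0210,
    "AHNAK", 9L, 2L, 0.0210,
    "PLEKHN1", 5L, 0L, 0.0216,
    "NBEAL2", 5L, 0L, 0.0216,
    "USP42", 5L, 0L, 0.0216,
    "OR4K1", 5L, 0L, 0.0216,
    "STARD9", 5L, 0L, 0.0216,
    "UNC13A", 5L, 0L, 0.0216,
    "OLFML2B", 4L, 0L, 0.0481,
    "MROH9", 4L, 0L, 0.0481,
    "SLC4A5", 4L, 0L, 0.0481,
    "VWA3B", 4L, 0L, 0.0481,
    "CAND2", 4L, 0L, 0.0481,
    "USP4", 4L, 0L, 0.0481,
    "LRP2BP", 4L, 0L, 0.0481,
    "ERAP2", 4L, 0L, 0.0481,
    "DOPEY1", 4L, 0L, 0.0481,
    "GLI3", 4L, 0L, 0.0481,
    "TRBV6-7", 4L, 0L, 0.0481,
    "LOXL2", 4L, 0L, 0.0481,
    "APOBEC1", 4L, 0L, 0.0481,
    "COL2A1", 4L, 0L, 0.0481,
    "LIMA1", 4L, 0L, 0.0481,
    "HAL", 4L, 0L, 0.0481,
    "RAI1", 4L, 0L, 0.0481,
    "MPP3", 4L, 0L, 0.0481,
    "RSAD1", 4L, 0L, 0.0481,
    "CILP2", 4L, 0L, 0.0481,
    "ZNF600", 4L, 0L, 0.0481,
    "LILRA4", 4L, 0L, 0.0481,
    "TUBB1", 4L, 0L, 0.0481,
    "UTRN", 6L, 1L, 0.0497,
    "NLRC3", 6L, 1L, 0.0497,
    "URB1", 6L, 1L, 0.0497
  )
}

# the eight COL2A1/GLI3 variant annotations used by the tier-classification
# tests (CADD scores and population frequencies as published; a recorded
# frequency of 0 means absent from the resource)
col2a1_gli3_variants <- function(sample_ids = sprintf("S%02d", 1:8)) {
  v <- tibble::tribble(
    ~chrom, ~pos, ~ref, ~alt, ~gene, ~consequence, ~gnomad_af, ~cadd_phred,
    "12", 48377883L, "G", "T", "COL2A1", "missense", 7.16e-6, 28,
    "12", 48369250L, "C", "T", "COL2A1", "missense", 5.98e-4, 9,
    "12", 48373812L, "G", "A", "COL2A1", "stop_gained", 0, 46,
    "12", 48376305L, "C", "T", "COL2A1", "missense", 8.77e-6, 19,
    "7", 42007446L, "C", "T", "GLI3", "missense", 7.131e-3, 27.5,
    "7", 42063171L, "C", "G", "GLI3", "missense", 3.811e-3, 23.5,
    "7", 42187851L, "C", "T", "GLI3", "missense", 2.434e-3, 28.4,
    "7", 42187885L, "G", "A", "GLI3", "missense", 4.03e-6, 24.7
  )
  v$filter <- "PASS"
  geno <- diag(8L)
  colnames(geno) <- sample_ids
  variant_set(v, geno)
}

# minimal hand-written VCF with a CSQ INFO field, returned as a temp path
write_test_vcf <- function(lines, samples = c("S1", "S2", "S3", "S4")) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"gene|consequence|gnomad_af|cadd_phred\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}
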