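# Cohort model: sample sheets, annotated variants, gene lists, gene-set
# collections. A "variant set" couples a variant annotation table with an
# aligned dosage matrix; it is the atom every filter and statistic consumes.

#' Build a sample table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group `"case"` or `"control"` per sample.
#' @param subpopulation Optional subpopulation label per sample (e.g. `"ITA"`,
#'   `"IRN"`); defaults to `"NA"`-free `"ALL"`.
#' @param qc_pass Logical; whether the sample passed per-sample coverage QC.
#'   Defaults to `TRUE` (updated by [sample_qc()]).
#' @return A tibble with columns `sample_id`, `group`, `subpopulation`,
#'   `qc_pass`.
#' @export
sample_table <- function(sample_id, group, subpopulation = "ALL", qc_pass = TRUE) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    abort("sample_id values must be unique within a cohort")
  }
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) {
    abort(paste0("group must be 'case' or 'control'; found: ", toString(bad)))
  }
  tibble(
    sample_id = sample_id,
    group = group,
    subpopulation = rep_len(as.character(subpopulation), length(sample_id)),
    qc_pass = rep_len(as.logical(qc_pass), length(sample_id))
  )
}

#' Read a sample sheet TSV
#'
#' Expects columns `sample_id`, `group`, `subpopulation` (tab-separated, with
#' header). A `qc_pass` column is honoured if present.
#'
#' @param path Path to the TSV file.
#' @return A sample tibble as from [sample_table()].
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "group", "subpopulation")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("sample sheet lacks column(s): ", toString(missing_cols)))
  }
  qc <- if ("qc_pass" %in% names(df)) as.logical(df$qc_pass) else TRUE
  sample_table(df$sample_id, df$group, df$subpopulation, qc)
}

#' Construct a variant set
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `gnomad_af`, `cadd_phred`, `filter`. `gnomad_af` uses `NA`
#'   for "absent from the population resource" (a recorded frequency of exactly
#'   0 is normalized to absent); `cadd_phred` uses `NA` for unscored variants.
#' @param geno Integer matrix of alt-allele dosages (rows = variants, columns =
#'   samples, values 0/1/2 or `NA` for missing genotypes). Column names are
#'   sample ids.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, geno) {
  variants <- as_tibble(variants)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "gnomad_af", "cadd_phred", "filter")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols)) {
    abort(paste0("variant table lacks column(s): ", toString(missing_cols)))
  }
  if (!is.matrix(geno) || nrow(geno) != nrow(variants)) {
    abort("geno must be a matrix with one row per variant")
  }
  if (is.null(colnames(geno))) {
    abort("geno must have sample ids as column names")
  }
  if (any(variants$pos < 1, na.rm = TRUE)) abort("pos must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt must differ")
  bad_csq <- setdiff(unique(variants$consequence), CONSEQUENCES)
  if (length(bad_csq)) {
    abort(paste0("unknown consequence class(es): ", toString(bad_csq)))
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) {
    abort("(chrom, pos, ref, alt) must be unique after normalization")
  }
  # AF semantics: 0 in the resource means "not observed" -> absent (NA)
  variants$gnomad_af[!is.na(variants$gnomad_af) & variants$gnomad_af == 0] <- NA_real_
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "<variant_set> %d variants x %d samples; %d genes\n",
    nrow(x$variants), ncol(x$geno), dplyr::n_distinct(x$variants$gene)
  ))
  print(utils::head(x$variants, 5))
  invisible(x)
}

#' Number of variants in a variant set
#' @param x A `variant_set`.
#' @return Integer count of variant records.
#' @export
n_variants <- function(x) nrow(x$variants)

# Parse GT strings ("0/1", "1|1", "./.", "0/2", ...) into dosage of a given
# alt-allele index. Missing calls return NA.
gt_to_dosage <- function(gt, alt_index = 1L) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == "." | a == "")) {
      return(NA_integer_)
    }
    sum(a == as.character(alt_index))
  }, integer(1))
}

#' Read an annotated VCF into a variant set
#'
#' Reads a VCF 4.x file (plain or bgzip) with per-sample genotypes, splits
#' multi-allelic sites into one record per alt allele, and attaches per-variant
#' annotations (gene symbol, consequence class, gnomAD allele frequency, CADD
#' PHRED score) either from a sidecar annotation table keyed on
#' `chrom,pos,ref,alt` or from a `CSQ`-style INFO field of the form
#' `CSQ=gene|consequence|gnomad_af|cadd_phred` (first entry kept when several
#' are supplied). Records without a gene annotation are retained with
#' `consequence = "other"`. The VCF `FILTER` column is preserved verbatim.
#'
#' A recorded population frequency of exactly 0 is treated as "absent from the
#' resource", the same as no record at all.
#'
#' @param path Path to the VCF.
#' @param samples Sample tibble ([sample_table()]); every genotype column in
#'   the VCF must appear in it.
#' @param annotations Optional sidecar annotation tibble (see
#'   [read_annotations()]); when `NULL`, annotations are parsed from the INFO
#'   field.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, samples, annotations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variant_set(samples$sample_id))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | is.na(fix$REF) | is.na(fix$ALT) | fix$ALT == "")
  if (length(bad)) {
    abort(sprintf(
      "malformed VCF record(s) at data row(s) %s: POS/REF/ALT unparseable",
      toString(head(bad, 5))
    ))
  }

  gt_raw <- vcf@gt
  vcf_samples <- colnames(gt_raw)[-1]          # first column is FORMAT
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown)) {
    abort(paste0(
      "VCF genotype column(s) absent from the sample sheet: ",
      toString(head(unknown, 5))
    ))
  }

  # split multi-allelic sites: one record per alt allele
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))

  variants <- tibble(
    chrom = fix$CHROM[row_idx],
    pos = pos[row_idx],
    ref = fix$REF[row_idx],
    alt = unlist(alt_list),
    filter = ifelse(is.na(fix$FILTER[row_idx]), ".", fix$FILTER[row_idx])
  )

  geno <- matrix(NA_integer_, nrow(variants), length(vcf_samples),
                 dimnames = list(NULL, vcf_samples))
  for (s in seq_along(vcf_samples)) {
    gt_col <- gt_raw[, s + 1L]
    for (k in unique(alt_idx)) {
      rows <- which(alt_idx == k)
      geno[rows, s] <- gt_to_dosage(gt_col[row_idx[rows]], alt_index = k)
    }
  }

  if (is.null(annotations)) {
    info <- fix$INFO[row_idx]
    annotations <- parse_csq_info(variants, info)
  }
  variants <- attach_annotations(variants, annotations)
  variant_set(variants, geno)
}

empty_variant_set <- function(sample_ids) {
  variant_set(
    tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      gene = character(), consequence = character(), gnomad_af = double(),
      cadd_phred = double(), filter = character()
    ),
    matrix(integer(), 0, length(sample_ids), dimnames = list(NULL, sample_ids))
  )
}

# CSQ=gene|consequence|gnomad_af|cadd_phred (comma-separated entries; the
# first, i.e. canonical-transcript, entry is kept)
parse_csq_info <- function(variants, info) {
  csq <- vapply(strsplit(ifelse(is.na(info), "", info), ";", fixed = TRUE),
                function(kv) {
                  hit <- kv[startsWith(kv, "CSQ=")]
                  if (length(hit)) sub("^CSQ=", "", hit[1]) else NA_character_
                }, character(1))
  first <- sub(",.*$", "", csq)
  parts <- strsplit(first, "|", fixed = TRUE)
  field <- function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, character(1))
  }
  tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene = field(1),
    consequence = field(2),
    gnomad_af = suppressWarnings(as.numeric(field(3))),
    cadd_phred = suppressWarnings(as.numeric(field(4)))
  )
}

attach_annotations <- function(variants, annotations) {
  ann <- as_tibble(annotations)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "gnomad_af", "cadd_phred")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    abort(paste0("annotation table lacks column(s): ", toString(missing_cols)))
  }
  # several symbols per record (e.g. "A;B"): keep the first, note the discard
  multi <- grepl("[;,]", ann$gene %||% "")
  if (any(multi, na.rm = TRUE)) {
    inform(sprintf(
      "%d annotation record(s) listed several gene symbols; first kept",
      sum(multi, na.rm = TRUE)
    ))
    ann$gene <- sub("[;,].*$", "", ann$gene)
  }
  out <- left_join(
    variants,
    mutate(ann, pos = as.integer(.data$pos)),
    by = c("chrom", "pos", "ref", "alt")
  )
  no_gene <- is.na(out$gene) | out$gene == ""
  out$gene[no_gene] <- NA_character_
  out$consequence[no_gene] <- "other"
  out$consequence[is.na(out$consequence)] <- "other"
  out$consequence[!out$consequence %in% CONSEQUENCES] <- "other"
  select(out, "chrom", "pos", "ref", "alt", "gene", "consequence",
         "gnomad_af", "cadd_phred", "filter")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read / write the sidecar annotation TSV
#'
#' The sidecar table (header `chrom,pos,ref,alt,gene,consequence,gnomad_af,
#' cadd_phred`, tab-separated) is the canonical transport for annotations that
#' originate from several upstream sources. An empty `gnomad_af` field means
#' the variant is absent from the population resource.
#'
#' @param path Path to the TSV file.
#' @return `read_annotations()`: a tibble with the eight annotation columns.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), consequence = readr::col_character(),
    gnomad_af = readr::col_double(), cadd_phred = readr::col_double()
  ))
}

#' @rdname read_annotations
#' @param variants Variant annotation tibble (e.g. `vs$variants`).
#' @export
write_annotations <- function(variants, path) {
  out <- select(as_tibble(variants), "chrom", "pos", "ref", "alt", "gene",
                "consequence", "gnomad_af", "cadd_phred")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One gene set per line: term identifier, description, then member symbols,
#' tab-separated. The set's category (used for per-category multiple-testing
#' correction) is parsed from the description field when non-empty, else
#' `"uncategorized"`. Duplicate member symbols within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term_id`, `term_name`, `category`, and a
#'   list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  category = character(), members = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(sprintf("GMT line(s) %s have fewer than 3 fields", toString(head(short, 5))))
  }
  tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = vapply(parts, `[`, character(1), 1),
    category = vapply(parts, function(p) {
      d <- trimws(p[2])
      if (nzchar(d)) d else "uncategorized"
    }, character(1)),
    members = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
}

#' Write a GMT gene-set collection
#' @param sets Gene-set tibble as from [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$category[i], sets$members[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a curated gene list
#'
#' Plain text, one symbol per line; symbols are uppercased and de-duplicated.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x <- unique(toupper(x[nzchar(x)]))
  if (length(x) == 0) abort("curated gene list is empty")
  x
}
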