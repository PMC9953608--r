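# Local gene-set over-representation analysis. Each term is tested with the
# upper-tail hypergeometric against an explicit universe; Benjamini-Hochberg
# adjustment is applied independently within each gene-set category. The
# three-way exclusivity comparison asks whether a term's enrichment is seen
# for case protein-altering variants only (not in controls, not in the
# synonymous comparator stream).

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-controlling adjustment: the i-th smallest p-value becomes
#' `min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every gene set for over-representation of the query list within an
#' explicit universe. Query symbols outside the universe are dropped (and
#' counted in a message); terms with no member in the universe are skipped.
#' Nominal p-values are upper-tail hypergeometric probabilities; adjustment
#' is Benjamini-Hochberg within each category.
#'
#' @param query Character vector of gene symbols.
#' @param sets Gene-set tibble ([read_gmt()]).
#' @param universe Character vector of universe gene symbols (typically the
#'   analyzable genes from coverage harmonization), or `"annotation"` to use
#'   the union of all set members.
#' @param alpha Significance level on the adjusted p-value; default 0.05.
#' @return A tibble `term_id, term_name, category, set_size_in_universe,
#'   query_size_in_universe, universe_size, overlap_size, overlap_genes
#'   (list-column), nominal_p, adjusted_p, significant`, sorted by
#'   `adjusted_p` then `nominal_p`.
#' @export
enrich <- function(query, sets, universe, alpha = 0.05) {
  if (identical(universe, "annotation")) {
    universe <- unique(unlist(sets$members))
  }
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query_in <- intersect(unique(query), universe)
  n_dropped <- length(setdiff(unique(query), universe))
  if (n_dropped > 0) {
    inform(sprintf("%d query gene(s) outside the universe dropped", n_dropped))
  }

  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    members_in <- intersect(sets$members[[i]], universe)
    if (length(members_in) == 0) return(NULL)
    overlap <- intersect(query_in, members_in)
    p <- hypergeom_upper_tail(
      N = length(universe), K = length(members_in),
      n = length(query_in), k = length(overlap)
    )
    tibble(
      term_id = sets$term_id[i], term_name = sets$term_name[i],
      category = sets$category[i],
      set_size_in_universe = length(members_in),
      query_size_in_universe = length(query_in),
      universe_size = length(universe),
      overlap_size = length(overlap),
      overlap_genes = list(sort(overlap)),
      nominal_p = p
    )
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("%d term(s) with no member in the universe skipped", skipped))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(mutate(out, adjusted_p = numeric(), significant = logical()))
  }
  out <- out %>%
    group_by(.data$category) %>%
    mutate(adjusted_p = bh_adjust(.data$nominal_p)) %>%
    ungroup() %>%
    mutate(significant = .data$adjusted_p < alpha) %>%
    arrange(.data$adjusted_p, .data$nominal_p, .data$term_id)
  out
}

#' Three-way exclusivity of enrichment
#'
#' For every term in the case results, records whether it is significantly
#' enriched (adjusted p below `alpha`) in cases, in controls, and in the
#' case-synonymous comparator; a term absent from a comparison collection
#' counts as not enriched there. A term is *exclusive* when enriched in cases
#' and in neither comparison stream.
#'
#' @param case_results,control_results,synonymous_results Tibbles from
#'   [enrich()] over the same gene-set collection.
#' @param alpha Significance level on adjusted p-values; default 0.05.
#' @return A tibble `term_id, term_name, category, enriched_in_cases,
#'   enriched_in_controls, enriched_in_synonymous, exclusive`.
#' @export
exclusivity <- function(case_results, control_results, synonymous_results,
                        alpha = 0.05) {
  sig_terms <- function(res) {
    if (is.null(res) || nrow(res) == 0) return(character())
    res$term_id[res$adjusted_p < alpha]
  }
  ctrl_sig <- sig_terms(control_results)
  syn_sig <- sig_terms(synonymous_results)
  case_results %>%
    mutate(
      enriched_in_cases = .data$adjusted_p < alpha,
      enriched_in_controls = .data$term_id %in% ctrl_sig,
      enriched_in_synonymous = .data$term_id %in% syn_sig,
      exclusive = .data$enriched_in_cases & !.data$enriched_in_controls &
        !.data$enriched_in_synonymous
    ) %>%
    select("term_id", "term_name", "category", "enriched_in_cases",
           "enriched_in_controls", "enriched_in_synonymous", "exclusive")
}
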