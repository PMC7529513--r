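#' Confirmation scan in the independent validation population
#'
#' Fits the null mixed model in the validation population (GRM from the array
#' panel) and scans the supplied variants — typically the candidate variants
#' plus the polymorphic array SNPs — with the variance components fixed, as in
#' the discovery stage. The validation population must be disjoint from the
#' discovery population: any shared individual id is an error, because the
#' two stages are required to be statistically independent.
#'
#' @param phenotypes Validation phenotype table.
#' @param genotypes Dosage matrix restricted to the variants to test
#'   (candidates plus array panel).
#' @param G `"grm"` object computed from the validation population's array
#'   panel genotypes.
#' @param maf_min MAF filter for the validation scan (default 0.01).
#' @param discovery_ids Individual ids used in the discovery stage (enforces
#'   the independence check when supplied).
#' @param variants Optional variant table merged into the results.
#' @return An association result table (see [assoc_scan()]) with the fitted
#'   `"mlma_vc"` attached as attribute `"vc"`.
#' @export
validation_scan <- function(phenotypes, genotypes, G, maf_min = 0.01,
                            discovery_ids = NULL, variants = NULL) {
  if (!is.null(discovery_ids)) {
    shared <- intersect(phenotypes$individual_id, discovery_ids)
    if (length(shared) > 0) {
      stop_dq("validation and discovery populations overlap (",
              length(shared), " shared individuals, e.g. ", shared[1],
              "); the two stages must be statistically independent")
    }
  }
  vc <- fit_null(phenotypes, G)
  res <- assoc_scan(phenotypes, genotypes, G, vc, maf_min = maf_min,
                    variants = variants)
  attr(res, "vc") <- vc
  res
}

#' Build the confirmation record for one QTL
#'
#' Restricts the validation results to tested variants inside the QTL's
#' EXT-CI, ranks them by `-log10(P)` (ties broken by position), and reports
#' how the candidate variants fared against the array SNPs: counts of
#' significant variants in each group, candidates among the `top_k`
#' best-ranked variants, the best candidate rank, the region's top variant,
#' and the confirmed flag (any tested variant reaching the validation
#' threshold).
#'
#' @param qtl One row of a `"qtl_table"`.
#' @param candidates Candidate set for this QTL (data frame with `id`), or
#'   `NULL`/empty when no candidate was carried to validation.
#' @param results Validation association results covering the region (with
#'   `chrom`, `pos`).
#' @param top_k Size of the head of the ranking in which candidates are
#'   counted.
#' @param threshold Validation significance threshold as a p-value; the
#'   confirmed flag requires `neglog10p >= -log10(threshold)`.
#' @return One-row data frame: `trait_id`, `chrom`, `ext_start`, `ext_end`,
#'   `n_candidates_tested`, `n_candidates_significant`, `n_array_tested`,
#'   `n_array_significant`, `n_candidates_in_topk`,
#'   `best_rank_of_candidate`, `top_id`, `top_pos`, `top_neglog10p`,
#'   `top_is_candidate`, `confirmed`, `status`.
#' @export
confirm_qtl <- function(qtl, candidates, results, top_k = 10,
                        threshold = significance_threshold("validation")) {
  t_nlp <- -log10(threshold)
  cand_ids <- if (is.null(candidates) || nrow(candidates) == 0) {
    character(0)
  } else {
    candidates$id
  }
  inside <- results$chrom == qtl$chrom &
    results$pos >= qtl$ext_start & results$pos <= qtl$ext_end &
    results$status == "tested"
  reg <- results[inside, , drop = FALSE]

  base <- data.frame(
    trait_id = qtl$trait_id, chrom = qtl$chrom,
    ext_start = qtl$ext_start, ext_end = qtl$ext_end,
    stringsAsFactors = FALSE
  )
  if (nrow(reg) == 0) {
    return(cbind(base, data.frame(
      n_candidates_tested = 0L, n_candidates_significant = 0L,
      n_array_tested = 0L, n_array_significant = 0L,
      n_candidates_in_topk = 0L, best_rank_of_candidate = NA_integer_,
      top_id = NA_character_, top_pos = NA_real_, top_neglog10p = NA_real_,
      top_is_candidate = NA, confirmed = FALSE, status = "untested",
      stringsAsFactors = FALSE
    )))
  }
  reg <- reg[order(-reg$neglog10p, reg$pos), , drop = FALSE]
  reg$rank <- seq_len(nrow(reg))
  is_cand <- reg$id %in% cand_ids
  sig <- reg$neglog10p >= t_nlp

  cbind(base, data.frame(
    n_candidates_tested = sum(is_cand),
    n_candidates_significant = sum(is_cand & sig),
    n_array_tested = sum(!is_cand),
    n_array_significant = sum(!is_cand & sig),
    n_candidates_in_topk = sum(is_cand & reg$rank <= top_k),
    best_rank_of_candidate = if (any(is_cand)) min(reg$rank[is_cand]) else NA_integer_,
    top_id = reg$id[1], top_pos = reg$pos[1], top_neglog10p = reg$neglog10p[1],
    top_is_candidate = is_cand[1],
    confirmed = any(sig),
    status = "tested",
    stringsAsFactors = FALSE
  ))
}

#' Summarize confirmation records across QTL
#'
#' @param records Data frame of rows from [confirm_qtl()].
#' @return A list: `n_qtl`, `n_confirmed`, `confirmation_rate`,
#'   `mean_best_rank_all` (over QTL with at least one tested candidate),
#'   `mean_best_rank_confirmed`, `frac_top_is_candidate` (among confirmed
#'   QTL), and `by_trait` (per-trait confirmed/unconfirmed counts).
#' @export
summarize_confirmations <- function(records) {
  assert_that(nrow(records) >= 1, "need at least one confirmation record")
  with_cand <- !is.na(records$best_rank_of_candidate)
  confirmed <- records$confirmed
  list(
    n_qtl = nrow(records),
    n_confirmed = sum(confirmed),
    confirmation_rate = mean(confirmed),
    mean_best_rank_all = if (any(with_cand)) {
      mean(records$best_rank_of_candidate[with_cand])
    } else NA_real_,
    mean_best_rank_confirmed = if (any(with_cand & confirmed)) {
      mean(records$best_rank_of_candidate[with_cand & confirmed])
    } else NA_real_,
    frac_top_is_candidate = if (any(confirmed)) {
      mean(records$top_is_candidate[confirmed], na.rm = TRUE)
    } else NA_real_,
    by_trait = as.data.frame(table(trait = records$trait_id,
                                   confirmed = records$confirmed))
  )
}
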