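#' Allocate a chip budget across QTL
#'
#' Each QTL receives `floor(total_budget / n_qtl)` slots; the remainder is
#' distributed one slot at a time to QTL in decreasing order of peak
#' significance.
#'
#' @param n_qtl Number of QTL.
#' @param total_budget Total custom-chip slots available.
#' @param peak_neglog10p Optional per-QTL peak `-log10(P)` used to order the
#'   remainder; defaults to input order.
#' @return Integer vector of per-QTL quotas summing to
#'   `min(total_budget, ...)`.
#' @export
#' @examples
#' allocate_budget(90, 900)  # 10 slots each
allocate_budget <- function(n_qtl, total_budget = 900, peak_neglog10p = NULL) {
  assert_that(n_qtl >= 1, "n_qtl must be >= 1")
  base <- total_budget %/% n_qtl
  rem <- total_budget %% n_qtl
  quotas <- rep.int(base, n_qtl)
  if (rem > 0) {
    ord <- if (is.null(peak_neglog10p)) {
      seq_len(n_qtl)
    } else {
      order(-peak_neglog10p, seq_len(n_qtl))
    }
    quotas[ord[seq_len(rem)]] <- quotas[ord[seq_len(rem)]] + 1L
  }
  as.integer(quotas)
}

#' Rank candidate variants within one QTL
#'
#' Variants with MAF at or below `maf_min_select` are removed; the remainder
#' are ordered primarily by significance. Within any run of variants whose
#' `-log10(P)` lies within `similarity_window` of the local leader, the order
#' is refined by functional-annotation tier — tier 1: coding (missense,
#' loss-of-function); tier 2: putative regulatory (splicing region, 5'/3'
#' UTR, upstream, downstream); tier 3: other genic (synonymous, intronic,
#' non-coding transcript exon); tier 4: intergenic — then by significance,
#' then by position.
#'
#' @param results Association results restricted to one QTL's confidence
#'   interval, with an `annotation` column (or supplied separately via
#'   `annotations`, a named vector keyed by variant id).
#' @param annotations Optional named annotation vector overriding/completing
#'   the `annotation` column.
#' @param maf_min_select MAF bound; only variants with MAF strictly greater
#'   are eligible.
#' @param similarity_window Width, on the `-log10(P)` scale, within which
#'   significance counts as "similar" and annotation breaks the tie.
#' @return The eligible rows, ordered, with `selection_rank` and
#'   `annotation_tier` columns added; zero rows if nothing is eligible.
#' @export
rank_candidates <- function(results, annotations = NULL,
                            maf_min_select = 0.02, similarity_window = 1.0) {
  res <- results[!is.na(results$neglog10p) & results$status == "tested", ,
                 drop = FALSE]
  if (!is.null(annotations)) {
    res$annotation <- unname(annotations[res$id])
  }
  if (is.null(res$annotation)) res$annotation <- NA_character_
  res <- res[res$maf > maf_min_select, , drop = FALSE]
  if (nrow(res) == 0) {
    message("no eligible candidate variants (all below MAF ",
            maf_min_select, " or untested)")
    res$selection_rank <- integer(0)
    res$annotation_tier <- integer(0)
    return(res)
  }
  tier <- ANNOTATION_TIER[res$annotation]
  tier[is.na(tier)] <- max(ANNOTATION_TIER)  # unannotated treated as lowest
  res$annotation_tier <- as.integer(tier)

  res <- res[order(-res$neglog10p, res$pos %||% seq_len(nrow(res))), ,
             drop = FALSE]
  # greedy tie-groups: each group is led by the most significant variant not
  # yet grouped and absorbs everything within similarity_window of it
  grp <- integer(nrow(res))
  g <- 0L
  i <- 1L
  while (i <= nrow(res)) {
    g <- g + 1L
    leader <- res$neglog10p[i]
    in_grp <- which(grp == 0L & res$neglog10p >= leader - similarity_window)
    grp[in_grp] <- g
    i <- max(in_grp) + 1L
  }
  o <- order(grp, res$annotation_tier, -res$neglog10p,
             res$pos %||% seq_len(nrow(res)))
  res <- res[o, , drop = FALSE]
  res$selection_rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Select candidate variants for every QTL under a chip budget
#'
#' Runs [allocate_budget()] and [rank_candidates()] per QTL (within its
#' EXT-CI by default) and returns the per-QTL candidate sets together with
#' the deduplicated chip union: a variant serving two overlapping QTL counts
#' once toward the chip total while both sets reference it.
#'
#' @param qtl_regions A `"qtl_table"` from [merge_to_qtl()].
#' @param results The discovery association result table (genome-wide, with
#'   `chrom` and `pos`).
#' @param annotations Optional named annotation vector keyed by variant id.
#' @param total_budget Total chip slots.
#' @param maf_min_select,similarity_window Passed to [rank_candidates()].
#' @param use_ci Which confidence interval bounds candidates: `"ext"`
#'   (default, keeps merged sub-peaks represented) or `"top"`.
#' @param dropout Optional fraction of selected variants randomly removed
#'   (emulating assay-design losses); `0` disables.
#' @param seed Seed for the dropout draw.
#' @return A list with `sets` (one data frame per QTL, each with
#'   `selection_rank`) and `chip` (deduplicated data frame of selected
#'   variant ids with the QTL indices each serves).
#' @export
select_candidates <- function(qtl_regions, results, annotations = NULL,
                              total_budget = 900, maf_min_select = 0.02,
                              similarity_window = 1.0,
                              use_ci = c("ext", "top"),
                              dropout = 0, seed = 1L) {
  use_ci <- match.arg(use_ci)
  n_qtl <- nrow(qtl_regions)
  if (n_qtl == 0) return(list(sets = list(), chip = data.frame(id = character(0))))
  quotas <- allocate_budget(n_qtl, total_budget,
                            peak_neglog10p = qtl_regions$neglog10p_ms)
  sets <- vector("list", n_qtl)
  for (k in seq_len(n_qtl)) {
    lo <- if (use_ci == "ext") qtl_regions$ext_start[k] else qtl_regions$top_start[k]
    hi <- if (use_ci == "ext") qtl_regions$ext_end[k] else qtl_regions$top_end[k]
    inside <- results$chrom == qtl_regions$chrom[k] &
      results$pos >= lo & results$pos <= hi
    ranked <- rank_candidates(results[inside, , drop = FALSE], annotations,
                              maf_min_select, similarity_window)
    take <- min(quotas[k], nrow(ranked))
    sets[[k]] <- ranked[seq_len(take), , drop = FALSE]
  }
  chip_ids <- unique(unlist(lapply(sets, function(s) s$id), use.names = FALSE))
  if (dropout > 0 && length(chip_ids) > 0) {
    keep <- with_seed(seed, runif(length(chip_ids)) >= dropout)
    dropped <- chip_ids[!keep]
    chip_ids <- chip_ids[keep]
    sets <- lapply(sets, function(s) s[!(s$id %in% dropped), , drop = FALSE])
  }
  chip <- data.frame(id = chip_ids, stringsAsFactors = FALSE)
  chip$serves_qtl <- lapply(chip$id, function(v) {
    which(vapply(sets, function(s) v %in% s$id, logical(1)))
  })
  list(sets = sets, chip = chip, quotas = quotas)
}
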