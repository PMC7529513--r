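#' Cluster significant variants into peaks
#'
#' Significant variants (`neglog10p >= -log10(threshold)`) on the same
#' chromosome are chained into a cluster wherever the distance between
#' consecutive significant variants is strictly less than `gap_bp`. Each
#' cluster receives its individual confidence interval via the
#' upper-third-of-peak rule (see [individual_ci()]).
#'
#' @param results Association result table (one trait x population) carrying
#'   `chrom`, `pos`, `neglog10p`, `beta`, `id`, `status`.
#' @param threshold Significance threshold as a p-value (e.g.
#'   [significance_threshold()]).
#' @param gap_bp Grouping distance in bp (strict: gaps `>= gap_bp` split).
#' @param ci_rule Upper-third rule variant, see [individual_ci()].
#' @return A list of peak clusters; each is a list with `chrom`, `members`
#'   (data frame sorted by position), `max_neglog10p`, `peak_pos`, and
#'   `individual_ci` (`c(start, end)`, 1-based inclusive).
#' @export
cluster_significant <- function(results, threshold, gap_bp = 1e6,
                                ci_rule = c("threshold_anchored", "max_fraction")) {
  ci_rule <- match.arg(ci_rule)
  t_nlp <- -log10(threshold)
  sig <- results[!is.na(results$neglog10p) & results$status == "tested" &
                   results$neglog10p >= t_nlp, , drop = FALSE]
  if (nrow(sig) == 0) return(list())
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]

  clusters <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    breaks <- which(diff(s$pos) >= gap_bp)
    grp <- cumsum(c(1L, seq_len(nrow(s) - 1) %in% breaks))
    for (g in unique(grp)) {
      members <- s[grp == g, , drop = FALSE]
      rownames(members) <- NULL
      cl <- list(
        chrom = ch,
        members = members,
        max_neglog10p = max(members$neglog10p),
        peak_pos = peak_position(members)
      )
      cl$individual_ci <- individual_ci(cl, threshold, rule = ci_rule)
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  clusters
}

# deterministic most-significant member: highest neglog10p, ties broken by
# larger |beta|, then lower position
peak_index <- function(members) {
  o <- order(-members$neglog10p, -abs(members$beta), members$pos)
  o[1]
}

peak_position <- function(members) members$pos[peak_index(members)]

#' Individual confidence interval of a peak (upper third)
#'
#' With `M` the peak's maximum `-log10(P)` and `T` the `-log10` significance
#' threshold, the default (`"threshold_anchored"`) rule keeps members with
#' `neglog10p >= M - (M - T) / 3` — the upper third of the peak measured
#' between the threshold and the maximum — and spans their positions. The
#' alternative `"max_fraction"` rule keeps members with
#' `neglog10p >= (2/3) M`.
#'
#' @param cluster A peak cluster (see [cluster_significant()]).
#' @param threshold Significance threshold as a p-value.
#' @param rule Which reading of "upper third of the peak" to apply.
#' @return `c(start, end)` in bp, 1-based inclusive; bounds are member
#'   positions.
#' @export
individual_ci <- function(cluster, threshold,
                          rule = c("threshold_anchored", "max_fraction")) {
  rule <- match.arg(rule)
  members <- cluster$members
  assert_that(nrow(members) >= 1, "cluster has no members")
  M <- max(members$neglog10p)
  cutoff <- if (rule == "threshold_anchored") {
    M - (M - (-log10(threshold))) / 3
  } else {
    (2 / 3) * M
  }
  keep <- members$neglog10p >= cutoff - 1e-12
  range(members$pos[keep])
}

#' Merge peak clusters into QTL regions
#'
#' Individual confidence intervals (one trait x population) that overlap or
#' lie strictly less than `gap_bp` apart are chained into a QTL region. Each
#' region reports a TOP-CI (the individual CI of the cluster containing the
#' region's most significant variant), an EXT-CI (outermost bounds over the
#' merged CIs), the most significant variant with its frequency `p_ms` and
#' effect `b_ms`, and the proportion of genetic variance explained,
#' `2 p_ms (1 - p_ms) b_ms^2`.
#'
#' @param clusters List of peak clusters from [cluster_significant()].
#' @param trait_id,population_id Labels stored on the regions.
#' @param gap_bp Merging distance in bp (strict).
#' @return A data frame of class `"qtl_table"`, one row per QTL region:
#'   `trait_id`, `population_id`, `chrom`, `top_start`, `top_end`,
#'   `ext_start`, `ext_end`, `ms_id`, `ms_pos`, `ms_annotation`, `p_ms`,
#'   `b_ms`, `neglog10p_ms`, `var_explained`, `n_clusters`. The member
#'   clusters of each region are attached as attribute `"clusters"`.
#' @export
merge_to_qtl <- function(clusters, trait_id = "trait1",
                         population_id = "discovery", gap_bp = 1e6) {
  if (length(clusters) == 0) {
    out <- empty_qtl_table()
    attr(out, "clusters") <- list()
    return(out)
  }
  ci <- data.frame(
    chrom = vapply(clusters, function(cl) cl$chrom[[1]], clusters[[1]]$chrom[[1]]),
    start = vapply(clusters, function(cl) cl$individual_ci[1], numeric(1)),
    end = vapply(clusters, function(cl) cl$individual_ci[2], numeric(1)),
    idx = seq_along(clusters)
  )
  comp <- interval_components(ci, gap_bp)

  rows <- lapply(split(ci$idx, comp), function(members_idx) {
    cls <- clusters[members_idx]
    all_members <- do.call(rbind, lapply(cls, `[[`, "members"))
    ms <- all_members[peak_index(all_members), , drop = FALSE]
    # cluster containing the globally most significant variant
    holder <- which(vapply(cls, function(cl) ms$id %in% cl$members$id, logical(1)))[1]
    top_ci <- cls[[holder]]$individual_ci
    ext_ci <- c(min(vapply(cls, function(cl) cl$individual_ci[1], numeric(1))),
                max(vapply(cls, function(cl) cl$individual_ci[2], numeric(1))))
    p_ms <- ms$maf
    b_ms <- ms$beta
    data.frame(
      trait_id = trait_id, population_id = population_id,
      chrom = cls[[1]]$chrom,
      top_start = top_ci[1], top_end = top_ci[2],
      ext_start = ext_ci[1], ext_end = ext_ci[2],
      ms_id = ms$id, ms_pos = ms$pos,
      ms_annotation = if ("annotation" %in% names(ms)) ms$annotation else NA_character_,
      p_ms = p_ms, b_ms = b_ms,
      neglog10p_ms = ms$neglog10p,
      var_explained = qtl_variance_explained(p_ms, b_ms),
      n_clusters = length(cls),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$ext_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_table", class(out))
  attr(out, "clusters") <- clusters
  out
}

empty_qtl_table <- function() {
  out <- data.frame(
    trait_id = character(0), population_id = character(0), chrom = integer(0),
    top_start = numeric(0), top_end = numeric(0),
    ext_start = numeric(0), ext_end = numeric(0),
    ms_id = character(0), ms_pos = numeric(0), ms_annotation = character(0),
    p_ms = numeric(0), b_ms = numeric(0), neglog10p_ms = numeric(0),
    var_explained = numeric(0), n_clusters = integer(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("qtl_table", class(out))
  out
}

# connected components of intervals under "overlap or distance < gap_bp",
# computed by chaining sorted intervals with a running maximum end; the
# relation is transitive along the sorted order, so chaining equals the full
# transitive closure.
interval_components <- function(ci, gap_bp) {
  comp <- integer(nrow(ci))
  nxt <- 0L
  for (ch in unique(ci$chrom)) {
    rows <- which(ci$chrom == ch)
    o <- rows[order(ci$start[rows], ci$end[rows])]
    run_end <- -Inf
    for (r in o) {
      gap <- max(0, ci$start[r] - run_end)
      if (!is.finite(run_end) || gap >= gap_bp) nxt <- nxt + 1L
      comp[r] <- nxt
      run_end <- max(run_end, ci$end[r])
    }
  }
  comp
}

#' Proportion of genetic variance explained by a QTL
#'
#' `2 p (1 - p) b^2`, with `p` the frequency and `b` the allelic substitution
#' effect (in genetic-SD units) of the QTL's most significant variant. Using
#' either allele's frequency gives the same value.
#'
#' @param p Allele frequency of the most significant variant.
#' @param b Its substitution effect in genetic-SD units.
#' @return Proportion of genetic variance (0-1 scale).
#' @export
#' @examples
#' qtl_variance_explained(0.203, 0.5803) # 0.109
qtl_variance_explained <- function(p, b) {
  2 * p * (1 - p) * b^2
}

#' Group QTL regions across traits and populations
#'
#' Regions (possibly from different traits and populations) whose EXT-CIs
#' overlap or whose bounds are strictly less than `gap_bp` apart are given a
#' shared integer `region_id`; ids are assigned in genome order (chromosome,
#' then leftmost bound of the group).
#'
#' @param regions A `"qtl_table"` (rows from any number of scans).
#' @param gap_bp Grouping distance in bp (strict).
#' @return The table with a `region_id` column added.
#' @export
group_regions_across <- function(regions, gap_bp = 1e6) {
  if (nrow(regions) == 0) {
    regions$region_id <- integer(0)
    return(regions)
  }
  ci <- data.frame(chrom = regions$chrom, start = regions$ext_start,
                   end = regions$ext_end)
  comp <- interval_components(ci, gap_bp)
  # renumber components in genome order
  first <- tapply(seq_len(nrow(ci)), comp, function(ix) {
    c(min(ci$chrom[ix]), min(ci$start[ix]))
  })
  ord <- order(vapply(first, `[`, numeric(1), 1), vapply(first, `[`, numeric(1), 2))
  remap <- setNames(seq_along(ord), names(first)[ord])
  regions$region_id <- as.integer(remap[as.character(comp)])
  regions
}

#' Tabulate functional annotations
#'
#' Counts and percentages of each annotation category over a set of variants
#' (typically those inside QTL confidence intervals).
#'
#' @param annotations Character vector of per-variant annotation labels.
#' @return Data frame with `annotation`, `n`, `pct` (percent of total),
#'   ordered by the canonical category list; a `Total` row is appended.
#' @export
summarize_annotations <- function(annotations) {
  annotations <- annotations[!is.na(annotations)]
  unknown <- setdiff(unique(annotations), ANNOTATION_CATEGORIES)
  if (length(unknown) > 0) {
    stop_dq("unknown annotation categories: ", paste(unknown, collapse = ", "))
  }
  cats <- ANNOTATION_CATEGORIES
  n <- vapply(cats, function(a) sum(annotations == a), integer(1))
  total <- length(annotations)
  out <- data.frame(
    annotation = c(cats, "total"),
    n = c(n, total),
    pct = if (total > 0) 100 * c(n, total) / total else c(n, total) * NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
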