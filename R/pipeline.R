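#' Run the full two-stage workflow on a synthetic dataset
#'
#' Generates a dataset under `config`, runs the discovery mixed-model scan
#' (GRM from the array panel), defines QTL regions, selects candidate
#' variants under the chip budget, scans candidates plus array SNPs in the
#' independent validation population and builds per-QTL confirmation
#' records.
#'
#' @param config A [sim_config()].
#' @param discovery_n_tests Effective number of independent discovery tests
#'   for the Bonferroni threshold.
#' @param maf_min_discovery,maf_min_validation,maf_min_select MAF filters for
#'   the discovery scan, validation scan and candidate selection.
#' @param gap_bp Clustering/merging distance.
#' @param total_budget Chip budget for candidate selection.
#' @param similarity_window Significance-similarity window for the
#'   annotation tie-break.
#' @param top_k Head size for candidate counting in confirmation records.
#' @param ci_rule Upper-third rule variant (see [individual_ci()]).
#' @param lazy_validation Keep validation genotypes lazy (recommended for
#'   large populations); only the columns actually scanned are materialized.
#' @return A list with the dataset pieces plus `vc_discovery`,
#'   `discovery_results` (array + dense scan), `qtl` (grouped regions),
#'   `selection`, `validation_results`, `records` (confirmations) and
#'   `summary`.
#' @export
run_two_stage <- function(config = sim_config(),
                          discovery_n_tests = 8e6,
                          maf_min_discovery = 0.001,
                          maf_min_validation = 0.01,
                          maf_min_select = 0.02,
                          gap_bp = 1e6,
                          total_budget = 900,
                          similarity_window = 1.0,
                          top_k = 10,
                          ci_rule = "threshold_anchored",
                          lazy_validation = TRUE) {
  ds <- simulate_dataset(config, lazy_validation = lazy_validation)
  variants <- ds$variants
  array_idx <- which(variants$is_array)

  # ---- Part I: discovery scan on the dense panel -------------------------
  G_d <- compute_grm(ds$discovery[, array_idx, drop = FALSE])
  vc_d <- fit_null(ds$pheno_discovery, G_d)
  res_d <- assoc_scan(ds$pheno_discovery, ds$discovery, G_d, vc_d,
                      maf_min = maf_min_discovery, variants = variants)

  thr_d <- significance_threshold("discovery", discovery_n_tests)
  clusters <- cluster_significant(res_d, thr_d, gap_bp = gap_bp,
                                  ci_rule = ci_rule)
  qtl <- merge_to_qtl(clusters, trait_id = ds$pheno_discovery$trait_id[1],
                      population_id = "discovery", gap_bp = gap_bp)
  qtl <- group_regions_across(qtl, gap_bp = gap_bp)

  # ---- candidate selection ----------------------------------------------
  selection <- select_candidates(
    qtl, res_d, total_budget = total_budget,
    maf_min_select = maf_min_select, similarity_window = similarity_window
  )

  # ---- Part II: validation scan on candidates + array panel --------------
  cand_ids <- selection$chip$id
  test_idx <- sort(unique(c(array_idx, match(cand_ids, variants$id))))
  Xv <- if (inherits(ds$validation, "lazy_dosage")) {
    materialize_dosages(ds$validation, test_idx)
  } else {
    ds$validation[, test_idx, drop = FALSE]
  }
  Xv_array <- Xv[, variants$id[intersect(test_idx, array_idx)], drop = FALSE]
  G_v <- compute_grm(Xv_array)
  res_v <- validation_scan(
    ds$pheno_validation, Xv, G_v, maf_min = maf_min_validation,
    discovery_ids = rownames(ds$discovery),
    variants = variants[test_idx, , drop = FALSE]
  )

  thr_v <- significance_threshold("validation")
  records <- do.call(rbind, lapply(seq_len(nrow(qtl)), function(k) {
    confirm_qtl(qtl[k, , drop = FALSE], selection$sets[[k]], res_v,
                top_k = top_k, threshold = thr_v)
  }))

  summary <- if (!is.null(records) && nrow(records) > 0) {
    summarize_confirmations(records)
  } else {
    NULL
  }

  list(
    config = config, variants = variants, truths = ds$truths,
    pheno_discovery = ds$pheno_discovery,
    pheno_validation = ds$pheno_validation,
    vc_discovery = vc_d, discovery_results = res_d,
    qtl = qtl, selection = selection,
    validation_results = res_v, records = records, summary = summary
  )
}

#' Replicate study of the full pipeline on planted QTL
#'
#' Repeats [run_two_stage()] on freshly seeded datasets and scores, per
#' planted QTL and replicate: whether a QTL region was detected near the
#' causal variant, whether the region's EXT-CI covers it, whether it was
#' selected as a candidate, its discovery-scan effect estimate, and the
#' confirmation outcome with the best candidate rank.
#'
#' A planted QTL counts as detected when some region on its chromosome lies
#' within `match_bp` of the causal position; coverage additionally requires
#' the causal position inside the region's EXT-CI.
#'
#' @param n_reps Number of replicates.
#' @param config Base [sim_config()]; each replicate r runs with seed
#'   `config$seed + r`.
#' @param match_bp Maximum causal-to-region distance for a detection match.
#' @param ... Passed on to [run_two_stage()].
#' @return A list with `records` (one row per planted QTL per replicate) and
#'   `rates` (detection, coverage among detected, candidate selection among
#'   covered-and-detected, confirmation among detected, mean best candidate
#'   rank, causal-is-top fraction among confirmed).
#' @export
replicate_study <- function(n_reps = 50, config = sim_config(),
                            match_bp = 2e6, ...) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    run <- run_two_stage(cfg, ...)
    rows[[r]] <- score_replicate(run, r, match_bp)
  }
  records <- do.call(rbind, rows)
  det <- records$detected
  cov <- records$covered
  sel <- records$selected
  conf <- records$confirmed
  rates <- list(
    n_reps = n_reps,
    n_qtl_records = nrow(records),
    detection_rate = mean(det),
    coverage_given_detected = if (any(det)) mean(cov[det]) else NA_real_,
    selection_given_detected = if (any(det)) mean(sel[det]) else NA_real_,
    # a causal variant outside the reported EXT-CI cannot be selected by
    # construction, so this conditions on the interval covering it
    selection_given_covered = if (any(det & cov)) mean(sel[det & cov]) else NA_real_,
    confirmation_given_detected = if (any(det)) mean(conf[det]) else NA_real_,
    mean_best_rank = mean(records$best_rank[det & !is.na(records$best_rank)]),
    causal_top_given_confirmed = if (any(conf & det)) {
      mean(records$causal_is_top[conf & det], na.rm = TRUE)
    } else NA_real_,
    mean_var_explained_detected = if (any(cov & det)) {
      mean(records$var_explained[cov & det], na.rm = TRUE)
    } else NA_real_,
    mean_true_var = mean(records$true_var)
  )
  list(records = records, rates = rates)
}

score_replicate <- function(run, rep_id, match_bp) {
  truths <- run$truths
  qtl <- run$qtl
  out <- lapply(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    hit <- NA_integer_
    if (nrow(qtl) > 0) {
      same <- which(qtl$chrom == tr$chrom)
      if (length(same) > 0) {
        d <- pmax(0, pmax(qtl$ext_start[same] - tr$pos,
                          tr$pos - qtl$ext_end[same]))
        if (min(d) <= match_bp) hit <- same[which.min(d)]
      }
    }
    detected <- !is.na(hit)
    covered <- detected && tr$pos >= qtl$ext_start[hit] &&
      tr$pos <= qtl$ext_end[hit]
    selected <- detected &&
      tr$variant_id %in% run$selection$sets[[hit]]$id
    confirmed <- detected && isTRUE(run$records$confirmed[hit])
    best_rank <- if (detected) run$records$best_rank_of_candidate[hit] else NA
    causal_is_top <- if (confirmed) {
      identical(run$records$top_id[hit], tr$variant_id)
    } else NA
    scan_row <- run$discovery_results[
      run$discovery_results$id == tr$variant_id, , drop = FALSE]
    data.frame(
      rep = rep_id, qtl = i, effect = tr$effect,
      allele_freq = tr$allele_freq,
      true_var = qtl_variance_explained(tr$allele_freq, tr$effect),
      causal_beta = if (nrow(scan_row)) scan_row$beta else NA_real_,
      causal_se = if (nrow(scan_row)) scan_row$se else NA_real_,
      causal_neglog10p = if (nrow(scan_row)) scan_row$neglog10p else NA_real_,
      detected = detected, covered = covered, selected = selected,
      confirmed = confirmed,
      best_rank = as.numeric(best_rank),
      causal_is_top = causal_is_top,
      var_explained = if (detected) qtl$var_explained[hit] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Render a human-readable report of a pipeline run
#'
#' Produces a per-trait QTL summary (count and total / lowest / largest
#' percentage of genetic variance explained) and, when confirmation records
#' exist, a validation table with candidate vs. array significance counts and
#' best candidate ranks.
#'
#' @param run Result of [run_two_stage()].
#' @return Character vector of report lines (also printed invisibly usable
#'   with `writeLines()`).
#' @export
format_report <- function(run) {
  lines <- c("== QTL discovery summary ==")
  qtl <- run$qtl
  if (nrow(qtl) == 0) {
    lines <- c(lines, "no QTL detected")
  } else {
    for (tr in unique(qtl$trait_id)) {
      q <- qtl[qtl$trait_id == tr, ]
      ve <- 100 * q$var_explained
      lines <- c(lines, sprintf(
        "trait %s: %d QTL, TOT %.1f%%, Min %.1f%%, Max %.1f%%",
        tr, nrow(q), sum(ve), min(ve), max(ve)
      ))
      lines <- c(lines, sprintf(
        "  region %d chr%s %d-%d bp: top %s at %d, -log10P %.1f, MAF %.3f, b %.3f (%.1f%%)",
        q$region_id, q$chrom, q$ext_start, q$ext_end, q$ms_id, q$ms_pos,
        q$neglog10p_ms, q$p_ms, q$b_ms, 100 * q$var_explained
      ))
    }
  }
  if (!is.null(run$records) && nrow(run$records) > 0) {
    s <- run$summary
    lines <- c(lines, "", "== Validation summary ==",
               sprintf("confirmed %d of %d QTL (%.0f%%)", s$n_confirmed,
                       s$n_qtl, 100 * s$confirmation_rate),
               sprintf("mean best candidate rank: %.2f (all), %.2f (confirmed)",
                       s$mean_best_rank_all, s$mean_best_rank_confirmed),
               sprintf("top variant is a candidate in %.0f%% of confirmed QTL",
                       100 * s$frac_top_is_candidate))
    r <- run$records
    lines <- c(lines, sprintf(
      "  region chr%s %d-%d: cand %d/%d sig, array %d/%d sig, best rank %s, %s",
      r$chrom, r$ext_start, r$ext_end,
      r$n_candidates_significant, r$n_candidates_tested,
      r$n_array_significant, r$n_array_tested,
      ifelse(is.na(r$best_rank_of_candidate), "-", r$best_rank_of_candidate),
      ifelse(r$confirmed, "confirmed", "not confirmed")
    ))
  }
  lines
}

# ---------------------------------------------------------------------------
# Command-line interface: thin wrapper over the stage functions. Stages read
# their inputs from --out-dir (written by earlier stages) and append to the
# run manifest, so `define-qtl` before `gwas` fails naming the missing stage.
# ---------------------------------------------------------------------------

cli_usage <- function() {
  c("usage: dairyqtl <subcommand> --config <yaml> --out-dir <dir> [--seed <int>]",
    "subcommands: simulate | gwas | define-qtl | select-candidates | validate | report | all")
}

cli_parse <- function(args) {
  if (length(args) < 1) stop_dq(paste(cli_usage(), collapse = "\n"))
  cmd <- args[[1]]
  opts <- list(config = NULL, out_dir = "dairyqtl_run", seed = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- args[[i]]
    val <- if (i + 1 <= length(args)) args[[i + 1]] else NULL
    switch(key,
           "--config" = { opts$config <- val; i <- i + 2 },
           "--out-dir" = { opts$out_dir <- val; i <- i + 2 },
           "--seed" = { opts$seed <- as.integer(val); i <- i + 2 },
           stop_dq("unknown option: ", key))
  }
  list(cmd = cmd, opts = opts)
}

cli_config <- function(opts) {
  cfg <- if (is.null(opts$config)) sim_config() else read_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  cfg
}

cli_require <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop_dq("missing ", file, ": run the '", stage, "' stage first")
  }
  path
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `gwas`, `define-qtl`,
#' `select-candidates`, `validate`, `report`, `all`) used by the
#' `inst/cli/dairyqtl` script. Stage outputs and a manifest are written under
#' `--out-dir`; each stage requires its upstream outputs and fails naming the
#' missing stage otherwise.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the paths written by the stage.
#' @keywords internal
cli_main <- function(args) {
  parsed <- cli_parse(args)
  cmd <- parsed$cmd
  opts <- parsed$opts
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- opts$out_dir
  paths <- list(
    config = file.path(od, "config.yaml"),
    dosages = file.path(od, "genotypes_discovery.tsv"),
    dosages_val = file.path(od, "genotypes_validation.tsv"),
    pheno = file.path(od, "phenotypes_discovery.tsv"),
    pheno_val = file.path(od, "phenotypes_validation.tsv"),
    truths = file.path(od, "qtl_truths.tsv"),
    variants = file.path(od, "variants.tsv"),
    stats = file.path(od, "summary_stats_discovery.tsv"),
    regions_tsv = file.path(od, "qtl_regions.tsv"),
    regions_bed = file.path(od, "qtl_regions.bed"),
    candidates = file.path(od, "candidates.tsv"),
    stats_val = file.path(od, "summary_stats_validation.tsv"),
    records = file.path(od, "confirmations.tsv"),
    report = file.path(od, "report.txt"),
    manifest = file.path(od, "manifest.json")
  )

  if (cmd %in% c("simulate", "all")) {
    cfg <- cli_config(opts)
    ds <- simulate_dataset(cfg)
    write_config(cfg, paths$config)
    write_dosage_tsv(ds$discovery, ds$variants, paths$dosages)
    write_dosage_tsv(ds$validation, ds$variants, paths$dosages_val)
    write_phenotypes(ds$pheno_discovery, paths$pheno)
    write_phenotypes(ds$pheno_validation, paths$pheno_val)
    write.table(ds$truths, paths$truths, sep = "\t", quote = FALSE,
                row.names = FALSE)
    vt <- ds$variants
    write.table(vt, paths$variants, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (cmd == "simulate") {
      write_manifest(build_manifest(cfg, cfg$seed, c(
        simulate = paths$dosages, variants = paths$variants,
        phenotypes = paths$pheno
      ), relative_to = od), paths$manifest)
      return(invisible(paths))
    }
  }

  # in-memory pipeline for the remaining stages: rebuild from files
  cfg <- if (file.exists(paths$config)) read_config(paths$config) else cli_config(opts)

  if (cmd %in% c("gwas", "define-qtl", "select-candidates", "validate",
                 "report", "all")) {
    if (cmd != "all") {
      cli_require(od, "genotypes_discovery.tsv", "simulate")
    }
    gd <- read_genotypes(paths$dosages, "dosage_tsv")
    variants <- read.table(paths$variants, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    pheno <- read_phenotypes(paths$pheno)
    if (cmd %in% c("gwas", "all")) {
      G <- compute_grm(gd$genotypes[, variants$is_array, drop = FALSE])
      vc <- fit_null(pheno, G)
      res <- assoc_scan(pheno, gd$genotypes, G, vc, maf_min = 0.001,
                        variants = variants)
      write_summary_stats(res, paths$stats, variants = variants)
      if (cmd == "gwas") return(invisible(paths))
    }
    if (cmd %in% c("define-qtl", "all")) {
      cli_require(od, "summary_stats_discovery.tsv", "gwas")
      res <- read_summary_stats(paths$stats)
      res$annotation <- variants$annotation[match(res$id, variants$id)]
      thr <- significance_threshold("discovery")
      qtl <- merge_to_qtl(cluster_significant(res, thr),
                          trait_id = pheno$trait_id[1])
      qtl <- group_regions_across(qtl)
      write_regions(qtl, paths$regions_bed, paths$regions_tsv)
      if (cmd == "define-qtl") return(invisible(paths))
    }
    if (cmd %in% c("select-candidates", "all")) {
      cli_require(od, "qtl_regions.tsv", "define-qtl")
      qtl <- read_regions(paths$regions_tsv)
      res <- read_summary_stats(paths$stats)
      res$annotation <- variants$annotation[match(res$id, variants$id)]
      sel <- select_candidates(qtl, res)
      cand <- do.call(rbind, lapply(seq_along(sel$sets), function(k) {
        s <- sel$sets[[k]]
        if (nrow(s) == 0) return(NULL)
        cbind(qtl_index = k, s[, c("id", "neglog10p", "maf", "annotation",
                                   "selection_rank")])
      }))
      if (is.null(cand)) cand <- data.frame(qtl_index = integer(0), id = character(0))
      write.table(cand, paths$candidates, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (cmd == "select-candidates") return(invisible(paths))
    }
    if (cmd %in% c("validate", "all")) {
      cli_require(od, "candidates.tsv", "select-candidates")
      cand <- read.table(paths$candidates, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
      gv <- read_genotypes(paths$dosages_val, "dosage_tsv")
      pheno_v <- read_phenotypes(paths$pheno_val)
      qtl <- read_regions(paths$regions_tsv)
      test_ids <- union(variants$id[variants$is_array], cand$id)
      Xv <- gv$genotypes[, test_ids, drop = FALSE]
      Gv <- compute_grm(gv$genotypes[, variants$id[variants$is_array],
                                     drop = FALSE])
      res_v <- validation_scan(pheno_v, Xv, Gv,
                               discovery_ids = pheno$individual_id,
                               variants = variants)
      write_summary_stats(res_v, paths$stats_val, variants = variants)
      if (nrow(qtl) > 0) {
        records <- do.call(rbind, lapply(seq_len(nrow(qtl)), function(k) {
          confirm_qtl(qtl[k, , drop = FALSE],
                      cand[cand$qtl_index == k, , drop = FALSE], res_v)
        }))
      } else {
        records <- NULL
      }
      if (!is.null(records)) {
        write.table(records, paths$records, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      if (cmd == "validate") return(invisible(paths))
    }
    if (cmd %in% c("report", "all")) {
      cli_require(od, "qtl_regions.tsv", "define-qtl")
      qtl <- read_regions(paths$regions_tsv)
      run <- list(qtl = qtl, records = NULL, summary = NULL)
      if (file.exists(paths$records)) {
        run$records <- read.table(paths$records, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
        if (nrow(run$records) > 0) run$summary <- summarize_confirmations(run$records)
      }
      writeLines(format_report(run), paths$report)
      write_manifest(build_manifest(cfg, cfg$seed, c(
        report = paths$report, regions = paths$regions_tsv
      ), relative_to = od), paths$manifest)
      return(invisible(paths))
    }
  }
  invisible(paths)
}
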