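thr82 <- significance_threshold("discovery")  # -log10 = 8.204

test_that("clustering chains variants separated by less than the gap", {
  res <- fake_results(chrom = c(1, 1, 1), pos = c(100, 5e5, 1.6e6),
                      neglog10p = c(9, 10, 12))
  cl <- cluster_significant(res, thr82, gap_bp = 1e6)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$members$pos, c(100, 5e5))
  expect_equal(cl[[2]]$members$pos, 1.6e6)

  expect_length(cluster_significant(fake_results(1, 100, 3), thr82), 0)

  single <- cluster_significant(fake_results(1, 42, 9), thr82)
  expect_length(single, 1)
  expect_equal(single[[1]]$individual_ci, c(42, 42))
})

test_that("clustering agrees with brute-force transitive closure", {
  for (r in 1:20) {
    set.seed(500 + r)
    n <- sample(20:200, 1)
    chrom <- sample(1:2, n, replace = TRUE)
    pos <- sample.int(2e7, n)
    nlp <- runif(n, 0, 20)
    res <- fake_results(chrom, pos, nlp)
    res <- res[order(res$chrom, res$pos), ]
    cl <- cluster_significant(res, thr82, gap_bp = 1e6)

    sig <- res[res$neglog10p >= -log10(thr82), ]
    comp <- brute_force_clusters(sig$chrom, sig$pos, 1e6)
    expect_identical(length(cl), length(unique(comp)))
    # memberships coincide: each brute-force component equals one cluster
    got <- lapply(cl, function(c) sort(c$members$id))
    want <- lapply(split(sig$id, comp), sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # every significant variant in exactly one cluster
    all_members <- unlist(lapply(cl, function(c) c$members$id))
    expect_identical(sort(all_members), sort(sig$id))
  }
})

test_that("the upper-third CI follows the threshold-anchored rule", {
  cl <- list(members = data.frame(
    id = c("a", "b", "c"), pos = c(1e6, 1.2e6, 1.5e6),
    neglog10p = c(20, 17, 9), beta = c(0.5, 0.4, 0.2)
  ))
  # M = 20, T = 8.2 (one decimal in reports); cutoff = 20 - 11.8/3 = 16.07
  ci <- individual_ci(cl, threshold = 10^-8.2)
  expect_equal(ci, c(1e6, 1.2e6))

  # all members at the same height span everything
  cl_eq <- list(members = data.frame(
    id = letters[1:3], pos = c(1, 5, 9) * 1e5,
    neglog10p = rep(12, 3), beta = rep(0.3, 3)
  ))
  expect_equal(individual_ci(cl_eq, thr82), c(1e5, 9e5))

  # alternative rule: two thirds of the maximum
  ci_alt <- individual_ci(cl, threshold = 10^-8.2, rule = "max_fraction")
  expect_equal(ci_alt, c(1e6, 1.2e6))  # cutoff 13.33 keeps a and b
})

test_that("merging yields TOP-CI inside EXT-CI with the peak in TOP-CI", {
  res <- fake_results(
    chrom = rep(1, 5),
    pos = c(1e6, 1.2e6, 1.9e6, 2.0e6, 9e6),
    neglog10p = c(12, 11.8, 30, 14, 9),
    beta = c(0.2, 0.2, 0.6, 0.3, 0.1),
    maf = rep(0.3, 5)
  )
  # sub-peaks resolved at 0.5 Mbp, then merged into regions at 1 Mbp: the
  # two left clusters (CIs [1, 1.2] and [1.9, 1.9] Mbp) fall in one region
  cl <- cluster_significant(res, thr82, gap_bp = 5e5)
  expect_length(cl, 3)
  qtl <- merge_to_qtl(cl, gap_bp = 1e6)
  expect_identical(nrow(qtl), 2L)
  top <- qtl[1, ]
  expect_identical(top$ms_pos, 1.9e6)
  expect_equal(c(top$top_start, top$top_end), c(1.9e6, 1.9e6))
  expect_equal(c(top$ext_start, top$ext_end), c(1e6, 1.9e6))
  expect_true(top$top_start >= top$ext_start && top$top_end <= top$ext_end)
  expect_true(top$ms_pos >= top$top_start && top$ms_pos <= top$top_end)
  expect_identical(top$n_clusters, 2L)

  # single cluster: TOP-CI and EXT-CI identical
  single <- merge_to_qtl(cluster_significant(
    fake_results(1, c(1e6, 1.1e6), c(10, 9)), thr82))
  expect_identical(single$top_start, single$ext_start)
  expect_identical(single$top_end, single$ext_end)
  expect_identical(single$n_clusters, 1L)
})

test_that("variance explained matches 2p(1-p)b^2 worked cases", {
  expect_equal(round(qtl_variance_explained(0.203, 0.5803), 3), 0.109)
  expect_equal(qtl_variance_explained(0.5, 0), 0)
  # frequency of either allele gives the same answer
  expect_equal(qtl_variance_explained(0.203, 0.58),
               qtl_variance_explained(0.797, 0.58))
})

test_that("cross-analysis grouping respects the 1-Mbp rule", {
  mk <- function(chrom, s, e, trait) {
    data.frame(trait_id = trait, population_id = "d", chrom = chrom,
               top_start = s, top_end = e, ext_start = s, ext_end = e,
               ms_id = "v", ms_pos = s, ms_annotation = "intergenic",
               p_ms = 0.3, b_ms = 0.3, neglog10p_ms = 10, n_clusters = 1L,
               var_explained = 0.02, stringsAsFactors = FALSE)
  }
  # identical CIs, different traits -> same id
  r1 <- rbind(mk(1, 5e6, 5.5e6, "A"), mk(1, 5e6, 5.5e6, "B"))
  g1 <- group_regions_across(r1)
  expect_identical(g1$region_id[1], g1$region_id[2])

  # bounds 0.9 Mbp apart -> same id; 1.1 Mbp apart -> different
  r2 <- rbind(mk(1, 1e6, 2e6, "A"), mk(1, 2.9e6, 3.4e6, "B"))
  expect_identical(length(unique(group_regions_across(r2)$region_id)), 1L)
  r3 <- rbind(mk(1, 1e6, 2e6, "A"), mk(1, 3.1e6, 3.6e6, "B"))
  expect_identical(length(unique(group_regions_across(r3)$region_id)), 2L)

  # singleton gets id 1
  expect_identical(group_regions_across(mk(2, 1e6, 2e6, "A"))$region_id, 1L)
})

test_that("region grouping agrees with brute-force interval closure", {
  for (r in 1:15) {
    set.seed(700 + r)
    n <- sample(3:30, 1)
    chrom <- sample(1:3, n, replace = TRUE)
    start <- sample.int(3e7, n)
    end <- start + sample.int(2e6, n)
    ci <- data.frame(chrom = chrom, start = start, end = end)
    comp <- dairyqtl:::interval_components(ci, 1e6)
    want <- brute_force_interval_components(chrom, start, end, 1e6)
    # same partition (labels may differ)
    expect_identical(length(unique(comp)), length(unique(want)))
    expect_true(all(tapply(want, comp, function(w) length(unique(w))) == 1))
  }
})

test_that("annotation summaries count and percentage correctly", {
  x <- c(rep("intergenic", 60), rep("intronic", 30), rep("missense", 10))
  s <- summarize_annotations(x)
  expect_equal(s$n[s$annotation == "intergenic"], 60)
  expect_equal(s$pct[s$annotation == "intergenic"], 60)
  expect_equal(s$pct[s$annotation == "missense"], 10)
  expect_equal(s$n[s$annotation == "total"], 100)
  expect_error(summarize_annotations(c("exonic")), "unknown")
})
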