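test_that("config validation rejects degenerate inputs", {
  expect_error(tiny_config(n_variants = 0), "counts")
  expect_error(tiny_config(maf_min = 0.6), "maf_min")
  expect_error(tiny_config(array_fraction = 0), "array_fraction")
  expect_error(tiny_config(reliability_discovery = 1.2), "reliability")
  expect_error(tiny_config(n_qtl = 3), "qtl_effects")
  probs <- default_annotation_probs()
  probs[1] <- probs[1] + 0.1
  expect_error(tiny_config(annotation_probs = probs), "sum to 1")
  expect_error(tiny_config(annotation_probs = c(exonic = 1)), "unknown")
})

test_that("a single block copied from two founders gives r2 = 1 everywhere", {
  cfg <- tiny_config(
    n_haplotypes = 2, n_prototypes = 2, mutation_rate = 0,
    ld_block_bp = 1e9, chrom_length_bp = 1e6, n_variants = 40,
    n_discovery = 80, n_validation = 50, maf_min = 0.2, n_qtl = 0,
    qtl_effects = numeric(0)
  )
  geno <- simulate_genotypes(cfg)
  X <- geno$discovery
  poly <- apply(X, 2, sd) > 0
  r2 <- cor(X[, poly])^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("within-block LD exceeds between-block LD", {
  cfg <- tiny_config(n_variants = 300, n_discovery = 400, n_qtl = 0,
                     qtl_effects = numeric(0), chrom_length_bp = 1e7,
                     ld_block_bp = 5e5, seed = 3L)
  geno <- simulate_genotypes(cfg)
  X <- geno$discovery
  blk <- geno$variants$block
  poly <- apply(X, 2, sd) > 0
  r2 <- cor(X[, poly])^2
  same <- outer(blk[poly], blk[poly], "==")
  diag(same) <- NA
  within <- mean(r2[same & upper.tri(r2)], na.rm = TRUE)
  between <- mean(r2[!same & upper.tri(r2)], na.rm = TRUE)
  expect_gt(within, 5 * between)  # block structure dominates
  expect_gt(within, 0.2)          # copying from few lineages is strong LD
  expect_lt(between, 0.05)        # blocks recombine freely
})

test_that("genotype output respects positions, dosages and the MAF floor", {
  cfg <- tiny_config(seed = 5L)
  geno <- simulate_genotypes(cfg)
  expect_true(all(geno$discovery %in% 0:2))
  v <- geno$variants
  expect_true(all(diff(v$pos[v$chrom == 1]) > 0))
  expect_true(all(v$pos >= 1))
  expect_true(all(v$freq > 0 & v$freq < 1))
  expect_error(
    simulate_genotypes(tiny_config(n_haplotypes = 3, maf_min = 0.4)),
    "unattainable"
  )
})

test_that("identical configs reproduce byte-identical datasets", {
  a <- simulate_dataset(tiny_config(seed = 9L))
  b <- simulate_dataset(tiny_config(seed = 9L))
  expect_identical(a$discovery, b$discovery)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truths, b$truths)
  expect_identical(a$pheno_discovery, b$pheno_discovery)
  expect_identical(a$pheno_validation, b$pheno_validation)
})

test_that("discovery and validation frequencies agree (shared founders)", {
  cfg <- tiny_config(n_variants = 1500, n_haplotypes = 250,
                     n_discovery = 400, n_validation = 600, n_qtl = 0,
                     qtl_effects = numeric(0), seed = 13L)
  geno <- simulate_genotypes(cfg)
  f_d <- colMeans(geno$discovery) / 2
  f_v <- colMeans(geno$validation) / 2
  ks <- suppressWarnings(stats::ks.test(f_d, f_v))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(abs(f_d - f_v)), 0.05)
})

test_that("lazy validation dosages match the materialized matrix", {
  cfg <- tiny_config(seed = 21L)
  full <- simulate_genotypes(cfg, lazy_validation = FALSE)
  lazy <- simulate_genotypes(cfg, lazy_validation = TRUE)
  idx <- c(1L, 5L, 100L, 599L)
  expect_equal(materialize_dosages(lazy$validation, idx),
               full$validation[, idx])
})

test_that("annotation assignment follows the requested distribution", {
  v1 <- data.frame(id = "x", chrom = 1, pos = 1)
  one <- assign_annotations(v1, c(intergenic = 1), seed = 1)
  expect_identical(one$annotation, "intergenic")

  n <- 1e5
  vn <- data.frame(id = seq_len(n), chrom = 1, pos = seq_len(n))
  probs <- default_annotation_probs()
  out <- assign_annotations(vn, probs, seed = 2)
  emp <- mean(out$annotation == "intergenic")
  expect_lt(abs(emp - probs[["intergenic"]]), 0.01)

  expect_error(assign_annotations(vn, c(garbage = 1), seed = 1), "unknown")
})

test_that("plant_qtl honors spacing and frequency constraints", {
  cfg0 <- tiny_config(n_qtl = 0, qtl_effects = numeric(0))
  geno <- simulate_genotypes(cfg0)
  empty <- plant_qtl(geno$variants, cfg0)
  expect_identical(nrow(empty$truths), 0L)

  cfg2 <- tiny_config(n_qtl = 2, qtl_effects = c(0.4, 0.5),
                      chrom_length_bp = 1e7, qtl_spacing_bp = 5e6)
  geno2 <- simulate_genotypes(cfg2)
  planted <- plant_qtl(geno2$variants, cfg2)
  expect_identical(nrow(planted$truths), 2L)
  expect_gte(abs(diff(planted$truths$pos)), 5e6)
  expect_true(all(planted$variants$is_causal[planted$truths$variant_index]))
  expect_identical(unique(planted$variants$annotation[planted$truths$variant_index]),
                   "missense")

  cfg_bad <- tiny_config(n_qtl = 1, qtl_effects = 0.5,
                         qtl_maf_range = c(0.49, 0.5))
  geno_bad <- simulate_genotypes(cfg_bad)
  if (!any(pmin(geno_bad$variants$freq, 1 - geno_bad$variants$freq) >= 0.49)) {
    expect_error(plant_qtl(geno_bad$variants, cfg_bad), "frequency-window")
  } else {
    succeed("eligible variant happened to exist in the narrow window")
  }
})

test_that("reliability controls the genetic share of phenotype variance", {
  cfg <- tiny_config(seed = 31L)
  ds <- simulate_genotypes(cfg)
  planted <- plant_qtl(ds$variants, cfg)

  ph1 <- simulate_phenotypes(ds$discovery, planted$truths, h2_poly = 0.3,
                             reliability = 1, seed = 1)
  expect_equal(ph1$value, attr(ph1, "genetic_value"))

  big <- tiny_config(n_discovery = 5000, n_variants = 400, seed = 32L)
  dsb <- simulate_genotypes(big)
  pb <- plant_qtl(dsb$variants, big)
  ph <- simulate_phenotypes(dsb$discovery, pb$truths, h2_poly = 0.3,
                            reliability = 0.5, seed = 2)
  ratio <- var(attr(ph, "genetic_value")) / var(ph$value)
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)

  expect_error(simulate_phenotypes(ds$discovery, pb$truths, reliability = 0),
               "reliability")
  expect_error(simulate_phenotypes(ds$discovery, pb$truths, reliability = 1.1),
               "reliability")
})

test_that("mean Var(g)/Var(y) is calibrated at r = 0.9 over 100 replicates", {
  cfg <- tiny_config(n_discovery = 800, n_variants = 250, n_qtl = 0,
                     qtl_effects = numeric(0), seed = 40L)
  ds <- simulate_genotypes(cfg)
  truths <- plant_qtl(ds$variants, cfg)$truths
  ratios <- vapply(1:100, function(r) {
    ph <- simulate_phenotypes(ds$discovery, truths, h2_poly = 0.3,
                              reliability = 0.9, seed = 1000 + r)
    var(attr(ph, "genetic_value")) / var(ph$value)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.9), 0.02)
})

test_that("somatic cell score transform matches its definition", {
  expect_equal(scs_from_scc(1e5), 3)
  expect_equal(scs_from_scc(8e5), 6)
  expect_equal(scs_from_scc(5e4), 2)
  expect_error(scs_from_scc(0), "positive")
  expect_error(scs_from_scc(-1), "positive")
})

test_that("array panel sampling is sized, spread and causal-free", {
  cfg <- tiny_config(n_variants = 2000, n_haplotypes = 200, seed = 51L)
  ds <- simulate_genotypes(cfg)
  planted <- plant_qtl(ds$variants, cfg)
  v <- select_array_panel(planted$variants, array_fraction = 0.05, seed = 1)
  expect_identical(sum(v$is_array), as.integer(ceiling(0.05 * 2000)))
  expect_false(any(v$is_array & v$is_causal))

  v_all <- select_array_panel(planted$variants, array_fraction = 1, seed = 1,
                              exclude_causal = FALSE)
  expect_true(all(v_all$is_array))

  v_one <- select_array_panel(planted$variants, array_fraction = 1 / 4000,
                              seed = 1)
  expect_identical(sum(v_one$is_array), 1L)
})
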