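test_that("scan equals the dense GLS oracle on small instances", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- tiny_config(n_discovery = 45, n_validation = 10, n_variants = 18,
                       n_haplotypes = 40, chrom_length_bp = 5e6,
                       n_qtl = 0, qtl_effects = numeric(0), seed = seed)
    ds <- simulate_genotypes(cfg)
    truths <- plant_qtl(ds$variants, cfg)$truths
    ph <- simulate_phenotypes(ds$discovery, truths, h2_poly = 0.5,
                              reliability = 0.8, seed = seed)
    g <- compute_grm(ds$discovery)
    vc <- fit_null(ph, g)
    res <- assoc_scan(ph, ds$discovery, g, vc, maf_min = 0)

    oracle <- dense_gls_oracle(ph$value, ds$discovery, as.matrix(g),
                               vc$sigma2_u, vc$sigma2_e)
    tested <- res$status == "tested"
    expect_lt(max(abs(res$beta[tested] - oracle[tested, "beta"])), 1e-8)
    expect_lt(max(abs(res$se[tested] - oracle[tested, "se"])), 1e-8)
    expect_lt(max(abs(res$p_value[tested] - oracle[tested, "p"])), 1e-8)
  }
})

test_that("with sigma2_u = 0 the scan reduces to ordinary least squares", {
  set.seed(5)
  n <- 60
  X <- matrix(rbinom(n * 8, 2L, 0.4), n, 8,
              dimnames = list(sprintf("i%02d", 1:n), paste0("v", 1:8)))
  y <- setNames(rnorm(n), rownames(X))
  g <- compute_grm(X)
  vc <- fit_null(y, g)
  vc$lambda <- 0
  vc$sigma2_u <- 0
  vc$sigma2_e <- 1.3  # any fixed residual variance
  res <- assoc_scan(y, X, g, vc, maf_min = 0)
  for (j in 1:8) {
    fit <- lm(y ~ X[, j])
    expect_lt(abs(res$beta[j] - coef(fit)[2]), 1e-8)
    # Wald p with the same fixed variance
    xc <- X[, j] - mean(X[, j])
    se_or <- sqrt(1.3 / sum(xc^2))
    p_or <- pchisq((coef(fit)[2] / se_or)^2, 1, lower.tail = FALSE)
    expect_lt(abs(res$p_value[j] - p_or), 1e-8)
  }
})

test_that("null model fitting flags degenerate inputs", {
  cfg <- tiny_config(n_discovery = 50, n_variants = 40, seed = 7L)
  ds <- simulate_genotypes(cfg)
  g <- compute_grm(ds$discovery)
  y_const <- setNames(rep(1, 50), rownames(ds$discovery))
  expect_error(fit_null(y_const, g), "constant")
  y_bad <- setNames(rnorm(50), paste0("other", 1:50))
  expect_error(fit_null(y_bad, g), "misaligned")
  y_na <- setNames(c(NA, rnorm(49)), rownames(ds$discovery))
  expect_error(fit_null(y_na, g), "non-finite")
  expect_error(fit_null(setNames(rnorm(5), rownames(ds$discovery)[1:5]),
                        compute_grm(ds$discovery[1:5, ])), "at least 10")
})

test_that("permuting phenotypes against the GRM drives h2 to zero", {
  cfg <- tiny_config(n_discovery = 800, n_variants = 500, n_qtl = 0,
                     qtl_effects = numeric(0), h2_poly = 0.5, seed = 17L)
  ds <- simulate_genotypes(cfg)
  truths <- plant_qtl(ds$variants, cfg)$truths
  ph <- simulate_phenotypes(ds$discovery, truths, h2_poly = 0.5,
                            reliability = 1, seed = 17L)
  g <- compute_grm(ds$discovery)
  set.seed(18)
  ph$value <- sample(ph$value)  # break the genotype-phenotype link
  vc <- fit_null(ph, g)
  expect_lt(vc$h2, 0.05)
})

test_that("shifting phenotypes by a constant changes only the intercept", {
  cfg <- tiny_config(n_discovery = 120, n_variants = 60, seed = 23L)
  ds <- simulate_genotypes(cfg)
  truths <- plant_qtl(ds$variants, cfg)$truths
  ph <- simulate_phenotypes(ds$discovery, truths, reliability = 0.9, seed = 23L)
  g <- compute_grm(ds$discovery)
  vc <- fit_null(ph, g)
  res1 <- assoc_scan(ph, ds$discovery, g, vc, maf_min = 0)

  ph2 <- ph
  ph2$value <- ph$value + 5
  vc2 <- fit_null(ph2, g)
  expect_lt(abs((vc2$mu - vc$mu) - 5), 1e-6)
  # variance components held fixed: the GLS solution is exactly
  # shift-equivariant in the intercept and invariant in the slope
  res2 <- assoc_scan(ph2, ds$discovery, g, vc, maf_min = 0)
  tested <- res1$status == "tested"
  expect_lt(max(abs(res1$beta[tested] - res2$beta[tested])), 1e-10)
  expect_lt(max(abs(res1$se[tested] - res2$se[tested])), 1e-10)
  expect_lt(max(abs(res1$neglog10p[tested] - res2$neglog10p[tested])), 1e-7)
})

test_that("monomorphic and rare variants are filtered, never dropped", {
  cfg <- tiny_config(n_discovery = 80, n_variants = 50, seed = 29L)
  ds <- simulate_genotypes(cfg)
  X <- ds$discovery
  X[, 1] <- 2L  # force monomorphic
  ph <- simulate_phenotypes(X, plant_qtl(ds$variants, cfg)$truths,
                            reliability = 0.9, seed = 29L)
  g <- compute_grm(X[, -1])
  vc <- fit_null(ph, g)
  res_strict <- assoc_scan(ph, X, g, vc, maf_min = 0.05)
  expect_identical(nrow(res_strict), ncol(X))
  expect_identical(res_strict$status[1], "filtered")
  expect_true(is.na(res_strict$p_value[1]))

  res_loose <- assoc_scan(ph, X, g, vc, maf_min = 0.01)
  was_tested <- res_strict$status == "tested"
  expect_true(all(res_loose$status[was_tested] == "tested"))
  expect_gte(sum(res_loose$status == "tested"), sum(was_tested))
  tested_both <- was_tested & res_loose$status == "tested"
  expect_equal(res_loose$beta[tested_both], res_strict$beta[tested_both])
})

test_that("neglog10p stays consistent with the p-value", {
  cfg <- tiny_config(seed = 37L)
  ds <- simulate_genotypes(cfg)
  planted <- plant_qtl(ds$variants, cfg)
  ph <- simulate_phenotypes(ds$discovery, planted$truths, reliability = 0.9,
                            seed = 37L)
  g <- compute_grm(ds$discovery[, ds$variants$is_array |
                                  seq_len(600) %% 3 == 0])
  vc <- fit_null(ph, g)
  res <- assoc_scan(ph, ds$discovery, g, vc)
  tested <- res$status == "tested"
  expect_true(all(res$p_value[tested] > 0 & res$p_value[tested] <= 1))
  expect_lt(max(abs(res$neglog10p[tested] + log10(res$p_value[tested]))), 1e-9)
  expect_true(all(res$se[tested] > 0))
})

test_that("a scan refuses unconverged variance components", {
  cfg <- tiny_config(n_discovery = 40, n_variants = 30, seed = 41L)
  ds <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(ds$discovery, plant_qtl(ds$variants, cfg)$truths,
                            reliability = 0.9, seed = 41L)
  g <- compute_grm(ds$discovery)
  vc <- fit_null(ph, g)
  vc$converged <- FALSE
  expect_error(assoc_scan(ph, ds$discovery, g, vc), "converge")
})

test_that("significance thresholds match the two-stage design", {
  expect_equal(round(-log10(significance_threshold("discovery")), 1), 8.2)
  expect_equal(significance_threshold("discovery", 1), 0.05)
  expect_equal(significance_threshold("validation"), 1e-6)
})

test_that("a 0.5-SD QTL at MAF 0.2 is found with near-certain power", {
  hits <- 0L
  cover <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    # panel shaped so that no single variant direction dominates the GRM
    # (array size of the order of n, many blocks), as with a real array
    cfg <- sim_config(
      n_discovery = 2000, n_validation = 10, n_variants = 2000,
      n_haplotypes = 200, chrom_length_bp = 1e8, ld_block_bp = 2.5e5,
      n_qtl = 1, qtl_effects = 0.5, qtl_maf_range = c(0.15, 0.25),
      array_fraction = 0.5, reliability_discovery = 0.9, seed = 300L + r
    )
    ds <- simulate_genotypes(cfg)
    planted <- plant_qtl(ds$variants, cfg)
    variants <- select_array_panel(planted$variants, cfg$array_fraction,
                                   seed = 300L + r)
    ph <- simulate_phenotypes(ds$discovery, planted$truths,
                              h2_poly = cfg$h2_poly, reliability = 0.9,
                              seed = 300L + r)
    g <- compute_grm(ds$discovery[, variants$is_array])
    vc <- fit_null(ph, g)
    res <- assoc_scan(ph, ds$discovery, g, vc)
    row <- res[res$id == planted$truths$variant_id, ]
    if (row$neglog10p > 8.2) hits <- hits + 1L
    if (abs(row$beta - 0.5) < 3 * row$se) cover <- cover + 1L
  }
  # empirical rates over the replicates (recorded for the suite log)
  cat(sprintf("\n[power] neglog10p>8.2: %d/%d, beta within 3 se: %d/%d\n",
              hits, n_rep, cover, n_rep))
  expect_gte(hits / n_rep, 0.95)
  expect_gte(cover / n_rep, 0.95)
})
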