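# Independent oracles and shared fixtures for the test suite.

# Small, fast simulation settings used by most unit tests.
tiny_config <- function(...) {
  defaults <- list(
    n_discovery = 200, n_validation = 300, n_variants = 600,
    n_haplotypes = 100, chrom_length_bp = 2e7, ld_block_bp = 2.5e5,
    n_qtl = 2, qtl_effects = c(0.5, 0.6), array_fraction = 0.1,
    seed = 42L
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

# Dense generalized-least-squares oracle: explicit V inverse, per variant.
dense_gls_oracle <- function(y, X, G_mat, sigma2_u, sigma2_e) {
  n <- length(y)
  V <- sigma2_u * G_mat + sigma2_e * diag(n)
  Vi <- solve(V)
  t(vapply(seq_len(ncol(X)), function(j) {
    D <- cbind(1, X[, j])
    A <- solve(t(D) %*% Vi %*% D)
    est <- A %*% t(D) %*% Vi %*% y
    b <- est[2, 1]
    se <- sqrt(A[2, 2])
    chi <- (b / se)^2
    c(beta = b, se = se, p = pchisq(chi, 1, lower.tail = FALSE))
  }, numeric(3)))
}

# Brute-force connected components of significant variants under
# "same chromosome and distance < gap_bp", via full transitive closure.
brute_force_clusters <- function(chrom, pos, gap_bp) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  adj <- outer(chrom, chrom, "==") & abs(outer(pos, pos, "-")) < gap_bp
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  }
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# Brute-force components of intervals under "overlap or gap < gap_bp".
brute_force_interval_components <- function(chrom, start, end, gap_bp) {
  n <- length(start)
  gap <- function(i, j) {
    if (chrom[i] != chrom[j]) return(Inf)
    max(0, max(start[i], start[j]) - min(end[i], end[j]))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) adj[i, j] <- gap(i, j) < gap_bp
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# Fabricate an association-result table for the clustering/selection logic.
fake_results <- function(chrom, pos, neglog10p, beta = NULL, maf = NULL,
                         annotation = NULL, status = "tested") {
  n <- length(pos)
  data.frame(
    id = sprintf("v%03d", seq_len(n)), chrom = chrom, pos = pos,
    maf = maf %||% rep(0.25, n),
    beta = beta %||% rep(0.3, n), se = 0.05,
    p_value = 10^(-neglog10p), neglog10p = neglog10p,
    n_used = 100L, status = rep(status, length.out = n),
    annotation = annotation %||% rep("intergenic", n),
    stringsAsFactors = FALSE
  )
}

# The end-to-end replicate study at the study-design scale is expensive, so
# it is run once per test session and memoized for every consumer.
.study_cache <- new.env(parent = emptyenv())
e2e_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- replicate_study(n_reps = 50, config = sim_config(seed = 100L))
  }
  .study_cache$study
}
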