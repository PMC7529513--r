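#' REML fit of the null polygenic model
#'
#' Fits `y = 1*mu + u + e` with `u ~ N(0, G sigma2_u)` and
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood. The GRM is
#' eigendecomposed once; the restricted log-likelihood is profiled over the
#' variance ratio `lambda = sigma2_u / sigma2_e` on a log-spaced grid and the
#' bracket around the grid optimum is then refined with a derivative-free
#' (golden-section) search. Convergence is declared when successive
#' log-likelihoods differ by less than 1e-8 or the lambda bracket width falls
#' below 1e-6.
#'
#' @param y Phenotype table (`individual_id`, `value`, ...) or a named
#'   numeric vector; ids must match the GRM's individuals (any order).
#' @param G A `"grm"` object from [compute_grm()].
#' @param lambda_grid Log10-spaced grid of variance ratios to profile.
#' @return An object of class `"mlma_vc"`: `sigma2_u`, `sigma2_e`, `lambda`,
#'   `h2` (= sigma2_u / (sigma2_u + sigma2_e)), `loglik` (restricted
#'   log-likelihood at the optimum), `converged`, `n_iter`, `mu`, and the
#'   cached GRM eigensystem used by [assoc_scan()].
#' @export
fit_null <- function(y, G, lambda_grid = 10^seq(-3, 3, by = 0.25)) {
  al <- align_phenotypes(y, G)
  yv <- al$values
  n <- length(yv)
  assert_that(n >= 10, "need at least 10 individuals to fit the null model")
  if (any(!is.finite(yv))) stop_dq("non-finite phenotype values")
  if (sd(yv) == 0) stop_dq("phenotype is constant (zero variance)")

  eg <- grm_eigen(G)
  ty <- as.numeric(crossprod(eg$U, yv))
  t1 <- as.numeric(crossprod(eg$U, rep(1, n)))
  sums <- list(yy = sum(yv^2), y1 = sum(yv), n = n)

  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  ll <- function(lambda) {
    counter$n <- counter$n + 1L
    reml_loglik(lambda, eg$d, ty, t1, sums)
  }

  grid <- c(0, lambda_grid)
  ll_grid <- vapply(grid, ll, numeric(1))
  i <- which.max(ll_grid)

  if (i == 1L) {
    # boundary: sigma2_u = 0 unless the first interior point competes
    bracket <- c(0, grid[2])
  } else if (i == length(grid)) {
    bracket <- c(grid[i - 1], grid[i] * 10)
  } else {
    bracket <- c(grid[i - 1], grid[i + 1])
  }
  opt <- optimize(ll, interval = bracket, maximum = TRUE, tol = 1e-9)
  cand <- rbind(c(grid[i], ll_grid[i]), c(opt$maximum, opt$objective))
  best <- cand[which.max(cand[, 2]), ]
  lambda <- best[1]
  loglik <- best[2]

  # the golden-section refinement stops on a bracket narrower than its tol,
  # satisfying the lambda-bracket stopping rule; flag non-convergence only
  # when the optimum is degenerate
  converged <- is.finite(loglik)

  prof <- reml_profile(lambda, eg$d, ty, t1, sums)
  vc <- structure(
    list(
      sigma2_u = lambda * prof$sigma2_e,
      sigma2_e = prof$sigma2_e,
      lambda = lambda,
      h2 = lambda / (1 + lambda),
      mu = prof$mu,
      loglik = loglik,
      converged = converged,
      n_iter = counter$n,
      eigen = eg,
      individual_ids = al$ids
    ),
    class = "mlma_vc"
  )
  vc
}

# Profiled REML quantities at a given variance ratio. Works in the rotated
# basis: K components carry eigenvalue d_i, the (n - K)-dimensional null space
# of G carries eigenvalue 0 and is handled through totals.
reml_profile <- function(lambda, d, ty, t1, sums) {
  w <- 1 / (lambda * d + 1)
  n <- sums$n
  A11 <- (n - sum(t1^2)) + sum(w * t1^2)
  A1y <- (sums$y1 - sum(t1 * ty)) + sum(w * t1 * ty)
  Ayy <- (sums$yy - sum(ty^2)) + sum(w * ty^2)
  mu <- A1y / A11
  Q <- Ayy - mu * A1y
  sigma2_e <- Q / (n - 1)
  list(mu = mu, sigma2_e = sigma2_e, A11 = A11, Q = Q)
}

reml_loglik <- function(lambda, d, ty, t1, sums) {
  prof <- reml_profile(lambda, d, ty, t1, sums)
  if (!is.finite(prof$sigma2_e) || prof$sigma2_e <= 0) return(-Inf)
  n <- sums$n
  logdetM <- sum(log(lambda * d + 1))
  -0.5 * ((n - 1) * log(2 * pi * prof$sigma2_e) + logdetM +
            log(prof$A11) + (n - 1))
}

#' @export
print.mlma_vc <- function(x, ...) {
  cat("Null mixed model (REML):\n")
  cat(sprintf("  sigma2_u = %.4f, sigma2_e = %.4f, h2 = %.3f\n",
              x$sigma2_u, x$sigma2_e, x$h2))
  cat(sprintf("  restricted logLik = %.3f (%s, %d evaluations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

align_phenotypes <- function(y, G) {
  if (is.data.frame(y)) {
    ids <- y$individual_id
    values <- y$value
  } else {
    values <- as.numeric(y)
    ids <- names(y)
  }
  if (is.null(ids)) stop_dq("phenotypes must carry individual ids")
  if (anyDuplicated(ids)) stop_dq("duplicated individual ids in phenotypes")
  pos <- match(G$individual_ids, ids)
  if (anyNA(pos)) {
    stop_dq("phenotype and GRM individual ids are misaligned (",
            sum(is.na(pos)), " GRM individuals lack phenotypes)")
  }
  list(values = values[pos], ids = G$individual_ids)
}

#' Mixed-model association scan with fixed variance components
#'
#' Tests every variant with the model `y = 1*mu + x*b + u + e`, holding the
#' variance components at the null-model REML estimates so that
#' `V = G sigma2_u + I sigma2_e` is fixed. For each variant, `b` and its
#' standard error are the generalized-least-squares solution for the fixed
#' effects `(mu, b)` and the p-value comes from the Wald statistic
#' `(b/se)^2` against chi-square(1). Because the phenotypes are standardized
#' to unit genetic variance, effects are expressed in genetic-standard-
#' deviation units.
#'
#' @param y Phenotype table or named vector (see [fit_null()]).
#' @param genotypes Dosage matrix (individuals x variants) with variant ids as
#'   colnames; rows must cover the GRM individuals.
#' @param G A `"grm"` object (defines V together with `vc`).
#' @param vc Converged `"mlma_vc"` from [fit_null()]. Its cached eigensystem
#'   is reused when it matches `G`'s individuals.
#' @param maf_min Variants with minor-allele frequency below this (or
#'   monomorphic) are marked `"filtered"` and carry no test.
#' @param variants Optional variant table; when given, `chrom`, `pos` and
#'   `annotation` are merged into the result by variant id.
#' @return An association result table: one row per input variant with `id`,
#'   `maf`, `beta`, `se`, `p_value`, `neglog10p`, `n_used`, `status`
#'   (`"tested"`/`"filtered"`), plus coordinates when `variants` is supplied.
#' @export
assoc_scan <- function(y, genotypes, G, vc, maf_min = 0.001, variants = NULL) {
  stopifnot(inherits(vc, "mlma_vc"))
  if (!isTRUE(vc$converged)) {
    stop_dq("refusing to scan: null-model variance components did not converge")
  }
  al <- align_phenotypes(y, G)
  yv <- al$values
  n <- length(yv)
  ridx <- match(G$individual_ids, rownames(genotypes))
  if (anyNA(ridx)) stop_dq("genotype rows do not cover the GRM individuals")
  X <- genotypes[ridx, , drop = FALSE]

  eg <- if (!is.null(vc$eigen) && identical(vc$individual_ids, G$individual_ids)) {
    vc$eigen
  } else {
    grm_eigen(G)
  }
  lambda <- vc$lambda
  gam <- lambda * eg$d / (lambda * eg$d + 1)
  s2e <- vc$sigma2_e

  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  tested <- maf > 0 & maf >= maf_min

  m <- ncol(X)
  beta <- se <- pval <- nlp <- rep(NA_real_, m)

  if (any(tested)) {
    Xt <- X[, tested, drop = FALSE]
    TX <- crossprod(eg$U, Xt)                       # K x m_t
    ty <- as.numeric(crossprod(eg$U, yv))
    t1 <- as.numeric(crossprod(eg$U, rep(1, n)))

    cs1 <- colSums(Xt)
    xx <- colSums(Xt * Xt)
    xVx <- (xx - colSums(gam * TX^2)) / s2e
    xV1 <- (cs1 - as.numeric(crossprod(TX, gam * t1))) / s2e
    xVy <- (as.numeric(crossprod(Xt, yv)) -
              as.numeric(crossprod(TX, gam * ty))) / s2e
    oV1 <- (n - sum(gam * t1^2)) / s2e
    oVy <- (sum(yv) - sum(gam * t1 * ty)) / s2e

    det <- xVx * oV1 - xV1^2
    b <- (xVy * oV1 - xV1 * oVy) / det
    vb <- oV1 / det
    s <- sqrt(vb)
    chi <- (b / s)^2
    logp <- pchisq(chi, df = 1, lower.tail = FALSE, log.p = TRUE)
    pv <- exp(logp)
    pv[pv == 0] <- .Machine$double.xmin

    beta[tested] <- b
    se[tested] <- s
    pval[tested] <- pv
    nlp[tested] <- -log10(pv)
  }

  out <- data.frame(
    id = colnames(X) %||% sprintf("var_%06d", seq_len(m)),
    maf = maf,
    beta = beta,
    se = se,
    p_value = pval,
    neglog10p = nlp,
    n_used = ifelse(tested, n, 0L),
    status = ifelse(tested, "tested", "filtered"),
    stringsAsFactors = FALSE
  )
  if (!is.null(variants)) {
    keep <- c("id", intersect(c("chrom", "pos", "annotation", "is_array",
                                "is_causal"), names(variants)))
    out <- merge(out, variants[, keep, drop = FALSE], by = "id", sort = FALSE)
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
  }
  class(out) <- c("assoc_result", class(out))
  out
}

#' Genome-wide significance threshold
#'
#' Discovery scans use a Bonferroni correction of the 5% genome-wide error
#' rate over the effective number of independent tests (8 million by default
#' for a sequence-level panel after LD pruning), giving a nominal p-value of
#' 6.25e-9 (-log10 = 8.2 at one decimal). Validation scans on an array-sized
#' panel use the fixed cutoff 1e-6 (-log10 = 6).
#'
#' @param mode `"discovery"` or `"validation"`.
#' @param n_tests_effective Effective number of independent tests (discovery
#'   mode only).
#' @return The p-value cutoff.
#' @export
#' @examples
#' -log10(significance_threshold("discovery")) # 8.204
#' significance_threshold("validation")        # 1e-6
significance_threshold <- function(mode = c("discovery", "validation"),
                                   n_tests_effective = 8e6) {
  mode <- match.arg(mode)
  if (mode == "validation") return(1e-6)
  assert_that(n_tests_effective >= 1, "n_tests_effective must be >= 1")
  0.05 / n_tests_effective
}
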