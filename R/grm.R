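#' Genomic relationship matrix from marker dosages
#'
#' Computes the allele-frequency-weighted cross-product GRM
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))`, where `Z` is the dosage matrix with
#' each column centered by twice its observed alternate-allele frequency
#' `p_j`. Monomorphic variants and variants with MAF below `maf_min` are
#' excluded and recorded in the variant mask; missing dosages are mean-imputed
#' per variant before centering.
#'
#' The result is kept in factored form (`G = tcrossprod(Z) / denom`), which is
#' what the mixed-model machinery consumes; use [as.matrix()] to materialize
#' the dense matrix.
#'
#' @param genotypes Numeric/integer dosage matrix, individuals x variants
#'   (`NA` allowed; rownames are individual ids).
#' @param maf_min Minimum minor-allele frequency for a variant to enter the
#'   GRM (monomorphic variants are always excluded).
#' @return An object of class `"grm"` with elements `Z` (centered dosages),
#'   `denom`, `individual_ids`, `n_variants_used`, `variant_mask` (logical
#'   over input columns; `TRUE` = used) and `n_imputed` (count of mean-imputed
#'   missing dosages).
#' @export
compute_grm <- function(genotypes, maf_min = 0) {
  assert_that(nrow(genotypes) >= 2, "need at least 2 individuals for a GRM")
  n_imputed <- 0L
  if (anyNA(genotypes)) {
    n_imputed <- sum(is.na(genotypes))
    mu <- colMeans(genotypes, na.rm = TRUE)
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(genotypes) / 2
  maf <- pmin(p, 1 - p)
  mask <- maf > 0 & maf >= maf_min
  if (!any(mask)) {
    stop_dq("no variant passed the GRM filter (monomorphic or MAF < ",
            maf_min, ")")
  }
  Z <- sweep(genotypes[, mask, drop = FALSE], 2, 2 * p[mask])
  denom <- 2 * sum(p[mask] * (1 - p[mask]))
  structure(
    list(
      Z = Z,
      denom = denom,
      individual_ids = rownames(genotypes) %||%
        sprintf("ind_%05d", seq_len(nrow(genotypes))),
      n_variants_used = sum(mask),
      variant_mask = mask,
      n_imputed = n_imputed
    ),
    class = "grm"
  )
}

#' @export
as.matrix.grm <- function(x, ...) {
  G <- tcrossprod(x$Z) / x$denom
  dimnames(G) <- list(x$individual_ids, x$individual_ids)
  G
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", length(x$individual_ids), "individuals,",
      x$n_variants_used, "variants used\n")
  if (x$n_imputed > 0) cat("  (", x$n_imputed, "missing dosages mean-imputed )\n")
  invisible(x)
}

#' Eigendecomposition of a GRM through its factored form
#'
#' For `G = Z Z' / d` the non-null spectrum is obtained from the smaller of
#' `Z'Z` (m x m) and `Z Z'` (n x n), so a GRM built from a sparse array panel
#' on a large population never requires an n x n decomposition. Eigenpairs
#' with eigenvalues numerically at zero are dropped; the null space is handled
#' implicitly by the mixed-model code.
#'
#' @param g A `"grm"` object.
#' @param tol Relative eigenvalue threshold below which components are
#'   treated as null.
#' @return A list with `U` (n x K eigenvectors) and `d` (K positive
#'   eigenvalues).
#' @keywords internal
grm_eigen <- function(g, tol = 1e-10) {
  Zs <- g$Z / sqrt(g$denom)
  n <- nrow(Zs)
  m <- ncol(Zs)
  if (m < n) {
    e <- eigen(crossprod(Zs), symmetric = TRUE)
    keep <- e$values > tol * max(e$values, 0)
    d <- e$values[keep]
    U <- Zs %*% sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(d), "/")
  } else {
    e <- eigen(tcrossprod(Zs), symmetric = TRUE)
    keep <- e$values > tol * max(e$values, 0)
    d <- e$values[keep]
    U <- e$vectors[, keep, drop = FALSE]
  }
  list(U = U, d = d)
}
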