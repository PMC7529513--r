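#' Simulation configuration for a two-population GWAS dataset
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()], [plant_qtl()], [simulate_phenotypes()] and
#' [simulate_dataset()]. Defaults describe the study design the package
#' emulates: a discovery population of a few thousand sires with
#' high-reliability pseudo-phenotypes (deregressed-proof style), a larger
#' validation population of cows with single-record-heritability phenotypes,
#' a dense variant panel with LD blocks, a sparse array-like subset, and a
#' handful of planted QTL with effects expressed in genetic-standard-deviation
#' units.
#'
#' @param n_discovery Number of discovery individuals.
#' @param n_validation Number of validation individuals.
#' @param n_variants Number of dense-panel variants.
#' @param n_haplotypes Founder haplotype pool size shared by both populations.
#' @param chrom_length_bp Chromosome lengths in bp (one entry per chromosome).
#' @param ld_block_bp Mean LD-block length in bp; blocks are drawn with
#'   exponentially distributed lengths around this mean.
#' @param maf_min Lower bound enforced on the founder-pool minor allele
#'   frequency of every simulated variant.
#' @param array_fraction Fraction of variants flagged as members of the sparse
#'   array panel (the "50K"-like panel used for the GRM and validation scans).
#' @param n_qtl Number of planted causal variants per trait.
#' @param qtl_effects Allelic substitution effects, in genetic-SD units; length
#'   must equal `n_qtl`.
#' @param qtl_maf_range Frequency window from which causal variants are drawn.
#' @param qtl_spacing_bp Minimum distance between planted QTL on a chromosome.
#' @param causal_annotation Annotation label given to planted causal variants
#'   (`NA` to leave their sampled label untouched). The default `"missense"`
#'   mirrors a design in which causal candidates are expected in coding
#'   sequence and lets annotation-aware selection be exercised.
#' @param h2_poly Proportion of the latent genetic value that is
#'   marker-structured (captured by a GRM); the remainder is an i.i.d.
#'   Mendelian-sampling-like component.
#' @param reliability_discovery,reliability_validation Phenotype reliability
#'   r = Var(g)/Var(y) for each population; scalar or per-individual vector.
#' @param annotation_probs Named probability vector over the annotation
#'   vocabulary (see [assign_annotations()]); must sum to 1.
#' @param n_prototypes Number of distinct haplotype prototypes per LD block in
#'   the founder pool; fewer prototypes mean stronger within-block LD.
#' @param mutation_rate Per-allele copying-error rate applied when founder
#'   haplotypes are copied from block prototypes.
#' @param seed Integer seed; all downstream randomness derives from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_discovery = 2000,
                       n_validation = 10000,
                       n_variants = 20000,
                       n_haplotypes = 400,
                       chrom_length_bp = 1e8,
                       ld_block_bp = 2.5e5,
                       maf_min = 0.01,
                       array_fraction = 0.025,
                       n_qtl = 5,
                       qtl_effects = c(0.3, 0.4, 0.5, 0.55, 0.6),
                       qtl_maf_range = c(0.05, 0.45),
                       qtl_spacing_bp = 5e6,
                       causal_annotation = "missense",
                       h2_poly = 0.3,
                       reliability_discovery = 0.9,
                       reliability_validation = 0.35,
                       annotation_probs = default_annotation_probs(),
                       n_prototypes = 4,
                       mutation_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_discovery = as.integer(n_discovery),
    n_validation = as.integer(n_validation),
    n_variants = as.integer(n_variants),
    n_haplotypes = as.integer(n_haplotypes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    ld_block_bp = as.numeric(ld_block_bp),
    maf_min = maf_min,
    array_fraction = array_fraction,
    n_qtl = as.integer(n_qtl),
    qtl_effects = as.numeric(qtl_effects),
    qtl_maf_range = as.numeric(qtl_maf_range),
    qtl_spacing_bp = as.numeric(qtl_spacing_bp),
    causal_annotation = causal_annotation,
    h2_poly = h2_poly,
    reliability_discovery = reliability_discovery,
    reliability_validation = reliability_validation,
    annotation_probs = annotation_probs,
    n_prototypes = as.integer(n_prototypes),
    mutation_rate = mutation_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_discovery, cfg$n_validation, cfg$n_variants,
              cfg$n_haplotypes, cfg$n_prototypes)
  assert_that(all(is.finite(counts)) && all(counts >= 1L),
              "all population/panel counts must be >= 1")
  assert_that(cfg$maf_min > 0 && cfg$maf_min < 0.5,
              "maf_min must lie in (0, 0.5)")
  assert_that(cfg$array_fraction > 0 && cfg$array_fraction <= 1,
              "array_fraction must lie in (0, 1]")
  assert_that(all(cfg$reliability_discovery > 0) &&
                all(cfg$reliability_discovery <= 1),
              "reliability_discovery must lie in (0, 1]")
  assert_that(all(cfg$reliability_validation > 0) &&
                all(cfg$reliability_validation <= 1),
              "reliability_validation must lie in (0, 1]")
  assert_that(cfg$n_qtl >= 0L, "n_qtl must be >= 0")
  assert_that(length(cfg$qtl_effects) == cfg$n_qtl,
              "length(qtl_effects) must equal n_qtl")
  assert_that(all(is.finite(cfg$qtl_effects)), "qtl_effects must be finite")
  assert_that(cfg$h2_poly >= 0 && cfg$h2_poly <= 1, "h2_poly must lie in [0, 1]")
  assert_that(all(cfg$chrom_length_bp >= 1), "chromosome lengths must be >= 1 bp")
  assert_that(length(cfg$qtl_maf_range) == 2 &&
                cfg$qtl_maf_range[1] <= cfg$qtl_maf_range[2],
              "qtl_maf_range must be an increasing pair")
  validate_annotation_probs(cfg$annotation_probs)
  invisible(cfg)
}

#' Default annotation-category probabilities
#'
#' Category frequencies of variants inside QTL confidence intervals in dense
#' cattle panels, expressed as exact fractions of published tallies (dominated
#' by intergenic and intronic variants, with missense around 0.4%). Sums to 1
#' exactly.
#'
#' @return Named numeric vector over the annotation vocabulary.
#' @export
default_annotation_probs <- function() {
  counts <- c(
    intergenic = 6642, upstream = 764, downstream = 773,
    `3_prime_utr` = 41, `5_prime_utr` = 14, intronic = 3286,
    synonymous = 105, non_coding_transcript_exon = 4,
    splicing_region = 17, missense = 50
  )
  counts / sum(counts)
}

validate_annotation_probs <- function(probs) {
  assert_that(!is.null(names(probs)) && all(nzchar(names(probs))),
              "annotation_probs must be a named vector")
  unknown <- setdiff(names(probs), ANNOTATION_CATEGORIES)
  if (length(unknown) > 0) {
    stop_dq("unknown annotation categories: ", paste(unknown, collapse = ", "))
  }
  assert_that(all(probs >= 0), "annotation probabilities must be >= 0")
  assert_that(abs(sum(probs) - 1) <= 1e-9,
              "annotation probabilities must sum to 1 (within 1e-9)")
  invisible(probs)
}

#' Simulate LD-structured genotypes for two populations sharing founders
#'
#' Builds a founder haplotype pool organised in LD blocks: within each block a
#' small set of haplotype prototypes is drawn and every founder haplotype
#' copies one prototype with a low per-allele error rate, which creates strong
#' within-block LD; blocks recombine freely. Each individual then samples two
#' founder haplotypes independently per block, and both populations draw from
#' the same pool so that causal variants segregate (at similar frequencies) in
#' both.
#'
#' @param config A [sim_config()] object.
#' @param lazy_validation If `TRUE`, the validation population is returned as a
#'   compact haplotype-assignment object (class `"lazy_dosage"`) from which
#'   dosage columns can be materialized on demand with
#'   [materialize_dosages()] — useful when only a subset of variants (e.g.
#'   candidates and the array panel) will ever be scanned.
#'
#' @return A list with elements `discovery` (integer dosage matrix,
#'   individuals x variants, entries 0/1/2), `validation` (matrix or
#'   `lazy_dosage`), and `variants` (a variant table with `chrom`, `pos`,
#'   `id`, `ref`, `alt`, `freq` — realized alternate-allele frequency over
#'   both populations — plus `block`, `is_array`, `is_causal`, `annotation`).
#' @export
simulate_genotypes <- function(config, lazy_validation = FALSE) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n_chrom <- length(config$chrom_length_bp)
    # the pool must admit a minor-allele count k with maf_min <= k/n_hap <= 1/2
    if (ceiling(config$maf_min * config$n_haplotypes) > config$n_haplotypes / 2) {
      stop_dq("maf_min = ", config$maf_min, " is unattainable with a pool of ",
              config$n_haplotypes, " haplotypes")
    }

    # variants per chromosome, proportional to length
    alloc <- chrom_allocation(config$n_variants, config$chrom_length_bp)
    chrom <- rep.int(seq_len(n_chrom), alloc)
    pos <- unlist(lapply(seq_len(n_chrom), function(k) {
      if (alloc[k] == 0) return(integer(0))
      sort(sample.int(config$chrom_length_bp[k], alloc[k], replace = FALSE))
    }), use.names = FALSE)

    # exponential block lengths with the configured mean, per chromosome
    block <- integer(config$n_variants)
    offset <- 0L
    n_blocks_total <- 0L
    for (k in seq_len(n_chrom)) {
      idx <- which(chrom == k)
      if (length(idx) == 0) next
      bounds <- cumsum(stats::rexp(
        ceiling(config$chrom_length_bp[k] / config$ld_block_bp) * 3 + 5,
        rate = 1 / config$ld_block_bp
      ))
      bounds <- bounds[bounds < config$chrom_length_bp[k]]
      blk <- findInterval(pos[idx], bounds) + 1L
      block[idx] <- blk + n_blocks_total
      n_blocks_total <- n_blocks_total + max(blk)
    }

    proto_assign <- draw_proto_assign(config, block)
    pool <- founder_pool(config, block, proto_assign)

    n_blocks <- max(block)
    # per-block founder haplotype assignment (free recombination across blocks)
    draw_assign <- function(n_ind) {
      list(
        h1 = matrix(sample.int(config$n_haplotypes, n_ind * n_blocks, replace = TRUE),
                    n_ind, n_blocks),
        h2 = matrix(sample.int(config$n_haplotypes, n_ind * n_blocks, replace = TRUE),
                    n_ind, n_blocks)
      )
    }
    asg_d <- draw_assign(config$n_discovery)
    asg_v <- draw_assign(config$n_validation)

    lazy_v <- structure(
      list(pool = pool, h1 = asg_v$h1, h2 = asg_v$h2, block = block,
           n_ind = config$n_validation,
           ids = sprintf("val_%05d", seq_len(config$n_validation))),
      class = "lazy_dosage"
    )
    disc <- dosage_from_assignment(pool, asg_d$h1, asg_d$h2, block)
    rownames(disc) <- sprintf("disc_%05d", seq_len(config$n_discovery))

    # resample variants monomorphic across both populations (pool MAF floor is
    # already enforced; sampling can still fix an allele in small samples)
    for (attempt in 1:10) {
      freq_d <- colMeans(disc) / 2
      freq_v <- lazy_freq(lazy_v)
      freq_all <- (freq_d * config$n_discovery + freq_v * config$n_validation) /
        (config$n_discovery + config$n_validation)
      mono <- freq_all <= 0 | freq_all >= 1
      if (!any(mono)) break
      pool[, mono] <- founder_pool(config, block, proto_assign,
                                   cols = which(mono))
      lazy_v$pool <- pool
      disc[, mono] <- dosage_from_assignment(pool, asg_d$h1, asg_d$h2,
                                             block, cols = which(mono))
    }
    if (any(mono)) {
      stop_dq("could not obtain polymorphic samples for ", sum(mono),
              " variant(s); increase n_haplotypes or maf_min")
    }

    ids <- sprintf("var_%06d", seq_len(config$n_variants))
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, config$n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    variants <- data.frame(
      chrom = chrom, pos = as.integer(pos), id = ids, ref = ref, alt = alt,
      freq = freq_all, block = block,
      is_array = FALSE, is_causal = FALSE,
      annotation = NA_character_,
      stringsAsFactors = FALSE
    )
    colnames(disc) <- ids

    validation <- if (lazy_validation) {
      lazy_v$variant_ids <- ids
      lazy_v
    } else {
      v <- dosage_from_assignment(pool, asg_v$h1, asg_v$h2, block)
      dimnames(v) <- list(lazy_v$ids, ids)
      v
    }

    list(discovery = disc, validation = validation, variants = variants)
  })
}

chrom_allocation <- function(n_variants, lengths) {
  if (n_variants < 1) stop_dq("n_variants must be >= 1")
  alloc <- floor(n_variants * lengths / sum(lengths))
  short <- n_variants - sum(alloc)
  if (short > 0) {
    extra <- order(lengths, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1L
  }
  as.integer(alloc)
}

# Founder haplotype pool: per block, n_prototypes prototype haplotypes with
# per-variant allele frequencies drawn from a U-shaped spectrum truncated at
# the configured floor; each founder copies one prototype with a small
# per-allele error rate. The prototype assignment is shared by all variants
# of a block (that sharing IS the within-block LD) and is therefore drawn
# once, outside this function, and reused when columns are re-drawn to
# satisfy the pool MAF floor.
founder_pool <- function(config, block, proto_assign, cols = NULL) {
  cols <- cols %||% seq_along(block)
  H <- matrix(0, config$n_haplotypes, length(cols))
  blocks <- block[cols]
  for (b in unique(blocks)) {
    sel <- which(blocks == b)
    H[, sel] <- draw_pool_block(config, proto_assign[[as.character(b)]],
                                length(sel))
  }
  # enforce the pool MAF floor column-wise
  for (attempt in 1:25) {
    p <- colMeans(H)
    bad <- pmin(p, 1 - p) < config$maf_min
    if (!any(bad)) break
    for (b in unique(blocks[bad])) {
      sel <- which(blocks == b & bad)
      H[, sel] <- draw_pool_block(config, proto_assign[[as.character(b)]],
                                  length(sel))
    }
  }
  p <- colMeans(H)
  if (any(pmin(p, 1 - p) < config$maf_min)) {
    stop_dq("could not satisfy maf_min = ", config$maf_min,
            " for all variants with ", config$n_haplotypes,
            " founder haplotypes; lower maf_min or enlarge the pool")
  }
  H
}

draw_pool_block <- function(config, assign, nv) {
  # each variant marks a random clade of the block's prototype genealogy, so
  # variants arising on the same branch are in complete LD and nested or
  # disjoint branches give the graded r2 structure of a haplotype block
  K <- config$n_prototypes
  clades <- assign$clades
  pick <- sample.int(length(clades), nv, replace = TRUE)
  P <- vapply(pick, function(k) as.integer(seq_len(K) %in% clades[[k]]),
              integer(K))
  flip_pol <- rbinom(nv, 1L, 0.5) == 1L
  P[, flip_pol] <- 1L - P[, flip_pol, drop = FALSE]
  Hb <- P[assign$proto, , drop = FALSE]
  flips <- matrix(rbinom(length(Hb), 1L, config$mutation_rate), nrow(Hb))
  (Hb + flips) %% 2
}

# Per-block genealogy: prototype weights (Dirichlet-like, giving a spread of
# haplotype-lineage frequencies and hence a continuous allele-frequency
# spectrum), a founder-to-prototype assignment drawn from those weights, and
# the clades of a random binary merge tree over the prototypes.
draw_proto_assign <- function(config, block) {
  K <- config$n_prototypes
  out <- lapply(unique(block), function(b) {
    w <- stats::rgamma(K, 0.7)
    w <- w / sum(w)
    proto <- sample.int(K, config$n_haplotypes, replace = TRUE, prob = w)
    sets <- as.list(seq_len(K))
    clades <- as.list(seq_len(K))
    while (length(sets) > 2) {
      pair <- sample.int(length(sets), 2)
      merged <- sort(unlist(sets[pair]))
      sets <- c(sets[-pair], list(merged))
      clades <- c(clades, list(merged))
    }
    list(proto = proto, clades = clades)
  })
  names(out) <- as.character(unique(block))
  out
}

dosage_from_assignment <- function(pool, h1, h2, block, cols = NULL) {
  cols <- cols %||% seq_along(block)
  out <- matrix(0, nrow(h1), length(cols))
  blocks <- block[cols]
  for (b in unique(blocks)) {
    sel <- which(blocks == b)
    pc <- pool[, cols[sel], drop = FALSE]
    out[, sel] <- pc[h1[, b], , drop = FALSE] + pc[h2[, b], , drop = FALSE]
  }
  out
}

lazy_freq <- function(lazy) {
  # realized alternate-allele frequency without materializing dosages:
  # average the pool frequencies of the sampled haplotypes per block
  n_var <- length(lazy$block)
  freq <- numeric(n_var)
  for (b in unique(lazy$block)) {
    sel <- which(lazy$block == b)
    pc <- lazy$pool[, sel, drop = FALSE]
    cnt <- tabulate(c(lazy$h1[, b], lazy$h2[, b]), nbins = nrow(lazy$pool))
    freq[sel] <- as.numeric(crossprod(pc, cnt)) / (2 * lazy$n_ind)
  }
  freq
}

#' Materialize dosage columns from a lazy validation population
#'
#' @param lazy A `"lazy_dosage"` object from [simulate_genotypes()].
#' @param variant_idx Column indices (into the variant table) to materialize.
#' @return Integer dosage matrix (individuals x selected variants) with
#'   individual ids as rownames and variant ids as colnames.
#' @export
materialize_dosages <- function(lazy, variant_idx) {
  stopifnot(inherits(lazy, "lazy_dosage"))
  out <- dosage_from_assignment(lazy$pool, lazy$h1, lazy$h2, lazy$block,
                                cols = variant_idx)
  dimnames(out) <- list(lazy$ids, lazy$variant_ids[variant_idx])
  out
}

#' Assign a functional-annotation label to every variant
#'
#' Labels are drawn independently from the supplied category distribution, so
#' empirical proportions converge to `annotation_probs` as the panel grows.
#'
#' @param variants A variant table (from [simulate_genotypes()]).
#' @param annotation_probs Named probabilities over the annotation vocabulary
#'   (missense, loss_of_function, splicing_region, 5_prime_utr, 3_prime_utr,
#'   upstream, downstream, synonymous, intronic, non_coding_transcript_exon,
#'   intergenic); must sum to 1.
#' @param seed Integer seed.
#' @return The variant table with its `annotation` column filled.
#' @export
assign_annotations <- function(variants,
                               annotation_probs = default_annotation_probs(),
                               seed = 1L) {
  validate_annotation_probs(annotation_probs)
  with_seed(seed, {
    variants$annotation <- sample(
      names(annotation_probs), nrow(variants),
      replace = TRUE, prob = annotation_probs
    )
  })
  variants
}

#' Plant causal variants (QTL) into a variant panel
#'
#' Samples `n_qtl` variants from the configured frequency window, at least
#' `qtl_spacing_bp` apart on a chromosome, assigns them the configured
#' substitution effects (genetic-SD units) and flags them in the variant
#' table.
#'
#' @param variants Variant table.
#' @param config A [sim_config()].
#' @param trait_id Trait label attached to the truths.
#' @return A list with `truths` — a data frame of planted QTL
#'   (`variant_index`, `variant_id`, `chrom`, `pos`, `effect`, `allele_freq`,
#'   `trait_id`) — and `variants`, the updated table with `is_causal` flags
#'   (and, unless `causal_annotation` is `NA`, relabelled causal variants).
#' @export
plant_qtl <- function(variants, config, trait_id = "trait1") {
  validate_sim_config(config)
  if (config$n_qtl == 0L) {
    return(list(
      truths = data.frame(variant_index = integer(0), variant_id = character(0),
                          chrom = integer(0), pos = integer(0),
                          effect = numeric(0), allele_freq = numeric(0),
                          trait_id = character(0), stringsAsFactors = FALSE),
      variants = variants
    ))
  }
  maf <- pmin(variants$freq, 1 - variants$freq)
  eligible <- which(maf >= config$qtl_maf_range[1] &
                      maf <= config$qtl_maf_range[2])
  if (length(eligible) < config$n_qtl) {
    stop_dq("only ", length(eligible), " variants have MAF in [",
            config$qtl_maf_range[1], ", ", config$qtl_maf_range[2],
            "] but n_qtl = ", config$n_qtl,
            " were requested (frequency-window constraint)")
  }
  with_seed(config$seed + 1L, {
    cand <- sample(eligible)
    chosen <- integer(0)
    for (j in cand) {
      ok <- all(variants$chrom[chosen] != variants$chrom[j] |
                  abs(variants$pos[chosen] - variants$pos[j]) >= config$qtl_spacing_bp)
      if (ok) chosen <- c(chosen, j)
      if (length(chosen) == config$n_qtl) break
    }
    if (length(chosen) < config$n_qtl) {
      stop_dq("could not place ", config$n_qtl, " QTL at least ",
              config$qtl_spacing_bp, " bp apart within the eligible set ",
              "(spacing constraint)")
    }
    chosen <- chosen[order(variants$chrom[chosen], variants$pos[chosen])]
    truths <- data.frame(
      variant_index = chosen,
      variant_id = variants$id[chosen],
      chrom = variants$chrom[chosen],
      pos = variants$pos[chosen],
      effect = config$qtl_effects,
      allele_freq = variants$freq[chosen],
      trait_id = trait_id,
      stringsAsFactors = FALSE
    )
    variants$is_causal[chosen] <- TRUE
    if (!is.na(config$causal_annotation)) {
      variants$annotation[chosen] <- config$causal_annotation
    }
    list(truths = truths, variants = variants)
  })
}

#' Simulate reliability-controlled pseudo-phenotypes
#'
#' The latent genetic value is
#' `g = sum_QTL (x - 2p) b + sqrt(v_poly) u + sqrt(v_iid) delta`, where `u` is
#' a marker-structured polygenic draw with covariance proportional to a GRM
#' built from the non-causal columns of `genotypes`, `delta` is i.i.d.
#' standard normal (Mendelian-sampling-like variation the marker panel does
#' not capture), and the polygenic variances are scaled so that the
#' theoretical variance of `g` is 1 with a fraction `h2_poly` of the
#' non-QTL part marker-structured. The observed pseudo-phenotype is
#' `y = g + e` with `Var(e) = (1 - r) / r`, so `Var(g)/Var(y) = r`
#' (the reliability), matching deregressed proofs standardized by the genetic
#' standard deviation. Residuals are homoscedastic within a population unless
#' a per-individual reliability vector is supplied.
#'
#' @param genotypes Dosage matrix (individuals x variants) whose colnames are
#'   variant ids; causal columns are located by id from `truths` and all other
#'   columns form the polygenic basis.
#' @param truths Planted-QTL data frame from [plant_qtl()] (may be empty).
#' @param h2_poly Marker-structured share of the non-QTL genetic variance.
#' @param reliability Scalar or per-individual reliability in (0, 1].
#' @param seed Integer seed.
#' @param trait_id Trait label for the output table.
#' @param poly_basis Optional character vector of variant ids forming the
#'   polygenic basis; default uses every non-causal column of `genotypes`.
#' @return A phenotype table (`individual_id`, `trait_id`, `value`,
#'   `reliability`) with the simulated genetic values attached as attribute
#'   `"genetic_value"`.
#' @export
simulate_phenotypes <- function(genotypes, truths, h2_poly = 0.3,
                                reliability = 0.9, seed = 1L,
                                trait_id = "trait1", poly_basis = NULL) {
  assert_that(all(reliability > 0) && all(reliability <= 1),
              "reliability must lie in (0, 1]")
  n <- nrow(genotypes)
  causal_ids <- if (nrow(truths) > 0) truths$variant_id else character(0)
  miss <- setdiff(causal_ids, colnames(genotypes))
  if (length(miss) > 0) {
    stop_dq("causal variants absent from genotype matrix: ",
            paste(miss, collapse = ", "))
  }
  with_seed(seed, {
    g_qtl <- numeric(n)
    v_qtl <- 0
    if (length(causal_ids) > 0) {
      X <- genotypes[, causal_ids, drop = FALSE]
      p <- colMeans(X) / 2
      # (X - 2p) b computed without materializing the centered matrix
      g_qtl <- as.numeric(X %*% truths$effect) - sum(2 * p * truths$effect)
      v_qtl <- sum(2 * p * (1 - p) * truths$effect^2)
    }
    if (v_qtl > 1) {
      stop_dq("planted QTL variance 2p(1-p)b^2 sums to ", round(v_qtl, 3),
              " > 1: effects exceed one genetic SD in total")
    }
    v_rest <- 1 - v_qtl
    v_poly <- h2_poly * v_rest
    v_iid <- (1 - h2_poly) * v_rest

    u <- numeric(n)
    if (v_poly > 0) {
      keep <- setdiff(poly_basis %||% colnames(genotypes), causal_ids)
      Xp <- genotypes[, keep, drop = FALSE]
      p <- colMeans(Xp) / 2
      poly_ok <- p > 0 & p < 1
      Xp <- Xp[, poly_ok, drop = FALSE]
      p <- p[poly_ok]
      if (ncol(Xp) == 0) stop_dq("no polymorphic non-causal variants for the polygenic term")
      a <- rnorm(ncol(Xp))
      u <- (as.numeric(Xp %*% a) - sum(2 * p * a)) / sqrt(2 * sum(p * (1 - p)))
    }
    g <- g_qtl + sqrt(v_poly) * u + sqrt(v_iid) * rnorm(n)
    e_sd <- sqrt((1 - reliability) / reliability)
    y <- g + rnorm(n) * e_sd

    out <- data.frame(
      individual_id = rownames(genotypes) %||% sprintf("ind_%05d", seq_len(n)),
      trait_id = trait_id,
      value = y,
      reliability = if (length(reliability) == 1) rep(reliability, n) else reliability,
      stringsAsFactors = FALSE
    )
    attr(out, "genetic_value") <- g
    out
  })
}

#' Somatic cell score from somatic cell count
#'
#' `SCS = 3 + log2(SCC / 100000)` with SCC in cells per ml.
#'
#' @param scc Somatic cell count(s), cells per ml; must be > 0.
#' @return Somatic cell score(s).
#' @export
#' @examples
#' scs_from_scc(100000) # 3
#' scs_from_scc(800000) # 6
scs_from_scc <- function(scc) {
  if (any(!is.finite(scc)) || any(scc <= 0)) {
    stop_dq("scc must be a positive cell count per ml")
  }
  3 + log2(scc / 1e5)
}

#' Flag a sparse array-like panel within the dense variant set
#'
#' Samples `ceiling(array_fraction * n)` variants approximately uniformly
#' along the genome (one per equal-width positional stratum where possible),
#' preferring common variants (frequency >= `prefer_maf`) within a stratum.
#' Planted causal variants are excluded by default so that comparisons of
#' candidate vs. array ranks remain meaningful.
#'
#' @param variants Variant table.
#' @param array_fraction Fraction of variants to flag, in (0, 1].
#' @param seed Integer seed.
#' @param exclude_causal Exclude `is_causal` variants from the panel.
#' @param prefer_maf MAF above which a variant counts as "common".
#' @return The variant table with its `is_array` column set.
#' @export
select_array_panel <- function(variants, array_fraction = 0.05, seed = 1L,
                               exclude_causal = TRUE, prefer_maf = 0.05) {
  assert_that(array_fraction > 0 && array_fraction <= 1,
              "array_fraction must lie in (0, 1]")
  n <- nrow(variants)
  n_pick <- ceiling(array_fraction * n)
  eligible <- if (exclude_causal) which(!variants$is_causal) else seq_len(n)
  n_pick <- min(n_pick, length(eligible))
  maf <- pmin(variants$freq, 1 - variants$freq)

  with_seed(seed, {
    # stratify the genome into n_pick equal slices of the concatenated map
    offs <- c(0, cumsum(tapply(variants$pos, variants$chrom, max)))
    gpos <- variants$pos + offs[match(variants$chrom, sort(unique(variants$chrom)))]
    strat <- if (n_pick > 1) {
      cut(gpos[eligible], breaks = n_pick, labels = FALSE)
    } else {
      rep(1L, length(eligible))
    }
    picked <- integer(0)
    for (s in unique(strat)) {
      in_s <- eligible[strat == s]
      common <- in_s[maf[in_s] >= prefer_maf]
      pool <- if (length(common) > 0) common else in_s
      picked <- c(picked, pool[sample.int(length(pool), 1)])
    }
    if (length(picked) < n_pick) {
      left <- setdiff(eligible, picked)
      extra <- left[order(-maf[left])][seq_len(min(n_pick - length(picked), length(left)))]
      picked <- c(picked, extra)
    }
    variants$is_array <- FALSE
    variants$is_array[picked] <- TRUE
  })
  variants
}

#' Generate a complete two-population dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [assign_annotations()], [plant_qtl()], [select_array_panel()] and
#' [simulate_phenotypes()] for both populations under a single seed.
#'
#' @param config A [sim_config()].
#' @param lazy_validation Keep the validation genotypes in lazy form (see
#'   [simulate_genotypes()]); phenotypes are then simulated from the causal
#'   columns plus a random polygenic basis of `poly_basis_size` non-causal
#'   variants.
#' @param poly_basis_size Number of non-causal variants used for the lazy
#'   validation polygenic term.
#' @return A list: `config`, `variants`, `truths`, `discovery` (genotypes),
#'   `validation` (genotypes or lazy object), `pheno_discovery`,
#'   `pheno_validation`.
#' @export
simulate_dataset <- function(config = sim_config(), lazy_validation = FALSE,
                             poly_basis_size = 2000L) {
  geno <- simulate_genotypes(config, lazy_validation = lazy_validation)
  variants <- assign_annotations(geno$variants, config$annotation_probs,
                                 seed = config$seed + 2L)
  planted <- plant_qtl(variants, config)
  variants <- select_array_panel(planted$variants, config$array_fraction,
                                 seed = config$seed + 3L)
  truths <- planted$truths

  non_causal <- setdiff(seq_len(nrow(variants)), truths$variant_index)
  basis_idx <- with_seed(config$seed + 5L,
                         sort(sample(non_causal,
                                     min(poly_basis_size, length(non_causal)))))
  basis_ids <- variants$id[basis_idx]

  pheno_d <- simulate_phenotypes(
    geno$discovery, truths, h2_poly = config$h2_poly,
    reliability = config$reliability_discovery, seed = config$seed + 4L,
    poly_basis = basis_ids
  )

  if (lazy_validation) {
    cols <- sort(unique(c(truths$variant_index, basis_idx)))
    Xv <- materialize_dosages(geno$validation, cols)
    pheno_v <- simulate_phenotypes(
      Xv, truths, h2_poly = config$h2_poly,
      reliability = config$reliability_validation, seed = config$seed + 6L,
      poly_basis = basis_ids
    )
  } else {
    pheno_v <- simulate_phenotypes(
      geno$validation, truths, h2_poly = config$h2_poly,
      reliability = config$reliability_validation, seed = config$seed + 6L,
      poly_basis = basis_ids
    )
  }

  list(config = config, variants = variants, truths = truths,
       discovery = geno$discovery, validation = geno$validation,
       pheno_discovery = pheno_d, pheno_validation = pheno_v)
}
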