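#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input is parsed with `vcfR`; only biallelic records are kept (skipped
#' multi-allelic records are counted in a message), GT fields are converted
#' to 0/1/2 dosages and missing genotypes to `NA`. The dosage TSV format has
#' one variant per row: `chrom`, `pos`, `id`, `ref`, `alt`, then one integer
#' dosage column per individual. Positions are 1-based in both formats.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A list with `genotypes` (individuals x variants dosage matrix) and
#'   `variants` (data frame `chrom`, `pos`, `id`, `ref`, `alt`, `freq`).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("skipped ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  check_variant_frame(fix$ID, fix$CHROM, as.integer(fix$POS))
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix$ID))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[clean == "0/0"] <- 0L
  code[clean == "0/1" | clean == "1/0"] <- 1L
  code[clean == "1/1"] <- 2L
  dos[] <- t(code)
  variants <- data.frame(
    chrom = type.convert(fix$CHROM, as.is = TRUE),
    pos = as.integer(fix$POS),
    id = fix$ID, ref = fix$REF, alt = fix$ALT,
    freq = colMeans(dos, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE
  )
  list(genotypes = dos, variants = variants)
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(tab)[1:5])) {
    stop_dq("malformed dosage header: expected columns ",
            paste(need, collapse = ", "))
  }
  check_variant_frame(tab$id, tab$chrom, tab$pos)
  dcols <- setdiff(names(tab), need)
  dos <- as.matrix(tab[, dcols, drop = FALSE])
  bad <- which(!is.na(dos) & (dos != round(dos) | dos < 0 | dos > 2),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_dq("non-integer or out-of-range dosage at line ", bad[1, 1] + 1L,
            " (variant ", tab$id[bad[1, 1]], ", individual ",
            dcols[bad[1, 2]], ")")
  }
  storage.mode(dos) <- "integer"
  dos <- t(dos)
  colnames(dos) <- tab$id
  variants <- data.frame(
    chrom = tab$chrom, pos = as.integer(tab$pos), id = tab$id,
    ref = tab$ref, alt = tab$alt,
    freq = colMeans(dos, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE
  )
  list(genotypes = dos, variants = variants)
}

check_variant_frame <- function(id, chrom, pos) {
  if (anyDuplicated(id)) {
    stop_dq("duplicated variant ids (e.g. ", id[duplicated(id)][1], ")")
  }
  o <- order(chrom, pos)
  if (!identical(o, seq_along(pos))) {
    stop_dq("variants are not sorted by chromosome and position")
  }
  invisible(TRUE)
}

#' Write genotypes as a dosage TSV
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param variants Variant table aligned with the matrix columns.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  tab <- cbind(
    variants[, c("chrom", "pos", "id", "ref", "alt")],
    as.data.frame(t(genotypes), check.names = FALSE)
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' @inheritParams write_dosage_tsv
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=dairyqtl_", as.character(packageVersion("dairyqtl"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  gt <- matrix(gt_code[as.character(genotypes)], nrow(genotypes),
               ncol(genotypes))
  gt[is.na(gt)] <- "./."
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write per-individual phenotypes as TSV
#' @param phenotypes Phenotype table.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes[, c("individual_id", "trait_id", "value", "reliability")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV written by [write_phenotypes()]
#' @param path File path.
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write association summary statistics
#'
#' TSV with columns `chrom`, `pos`, `id`, `ref`, `alt`, `maf`, `beta`, `se`,
#' `p`, `neglog10p`, `status`, ordered by (chrom, pos), floats at 6
#' significant digits.
#'
#' @param results Association result table (with coordinates merged).
#' @param path Output path.
#' @param variants Optional variant table supplying `ref`/`alt` when the
#'   results lack them.
#' @export
write_summary_stats <- function(results, path, variants = NULL) {
  res <- results
  if (!is.null(variants)) {
    res <- merge(res, variants[, c("id", "ref", "alt")], by = "id",
                 sort = FALSE)
  }
  for (col in c("ref", "alt", "chrom", "pos")) {
    if (is.null(res[[col]])) res[[col]] <- rep(NA, nrow(res))
  }
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  out <- data.frame(
    chrom = res$chrom, pos = res$pos, id = res$id, ref = res$ref,
    alt = res$alt,
    maf = signif(res$maf, 6), beta = signif(res$beta, 6),
    se = signif(res$se, 6), p = signif(res$p_value, 6),
    neglog10p = signif(res$neglog10p, 6), status = res$status,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_summary_stats()]
#' @param path File path.
#' @return An association result table.
#' @export
read_summary_stats <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[names(tab) == "p"] <- "p_value"
  class(tab) <- c("assoc_result", class(tab))
  tab
}

#' Write QTL regions as BED and TSV
#'
#' The BED file holds the EXT-CIs converted from the internal 1-based
#' inclusive convention to BED's 0-based half-open convention
#' (`start-1`, `end`). The companion TSV mirrors the per-QTL report: trait,
#' population, TOP-CI bounds, most-significant variant (id, position,
#' annotation, MAF, -log10 P, effect), EXT-CI bounds, variance explained and
#' cross-analysis region id.
#'
#' @param regions A `"qtl_table"` (ideally after [group_regions_across()]).
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = regions$chrom,
      start = as.integer(regions$ext_start - 1),
      end = as.integer(regions$ext_end),
      name = if (nrow(regions) > 0) {
        paste0(regions$trait_id, "_", regions$ms_id)
      } else {
        character(0)
      }
    )
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    cols <- c("region_id", "trait_id", "population_id", "chrom",
              "top_start", "top_end", "ms_id", "ms_pos", "ms_annotation",
              "p_ms", "neglog10p_ms", "b_ms", "ext_start", "ext_end",
              "var_explained")
    cols <- intersect(cols, names(regions))
    write.table(regions[, cols, drop = FALSE], tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Read a QTL region TSV written by [write_regions()]
#' @param path File path.
#' @export
read_regions <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("top_start", "top_end", "ext_start", "ext_end") %in% names(tab))) {
    bad <- tab$top_start < tab$ext_start | tab$top_end > tab$ext_end
    if (any(bad)) {
      stop_dq("invalid region file: TOP-CI outside EXT-CI in ", sum(bad),
              " row(s)")
    }
  }
  class(tab) <- c("qtl_table", class(tab))
  tab
}

#' Build a run manifest
#'
#' Records the configuration snapshot, seeds, stage output paths with their
#' md5 digests, and the package version, so a run can be audited and
#' reproduced.
#'
#' @param config The `"sim_config"` (or any serializable config list).
#' @param seed Run seed.
#' @param outputs Named character vector of stage output paths.
#' @param relative_to Optional directory; stored paths are made relative to
#'   it, so runs of the same configuration in different directories produce
#'   byte-identical manifests.
#' @return Manifest list (class `"run_manifest"`).
#' @export
build_manifest <- function(config, seed, outputs = character(0),
                           relative_to = NULL) {
  digests <- if (length(outputs) > 0) {
    unname(tools::md5sum(outputs))
  } else {
    character(0)
  }
  paths <- unname(outputs)
  if (!is.null(relative_to)) {
    prefix <- paste0(sub("/+$", "", relative_to), "/")
    paths <- sub(prefix, "", paths, fixed = TRUE)
  }
  structure(
    list(
      package = "dairyqtl",
      version = as.character(packageVersion("dairyqtl")),
      seed = seed,
      config = unclass(config),
      outputs = if (length(outputs) > 0) {
        data.frame(stage = names(outputs), path = paths,
                   md5 = digests, stringsAsFactors = FALSE)
      } else {
        data.frame(stage = character(0), path = character(0),
                   md5 = character(0))
      }
    ),
    class = "run_manifest"
  )
}

#' Write / read / verify a run manifest
#'
#' `verify_manifest()` recomputes the digest of every listed output and
#' errors on any mismatch.
#'
#' @param manifest A `"run_manifest"`.
#' @param path JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(m) <- "run_manifest"
  m
}

#' @param base_dir Directory against which relative manifest paths are
#'   resolved.
#' @rdname write_manifest
#' @export
verify_manifest <- function(manifest, base_dir = ".") {
  if (nrow(manifest$outputs) == 0) return(invisible(TRUE))
  paths <- ifelse(startsWith(manifest$outputs$path, "/"),
                  manifest$outputs$path,
                  file.path(base_dir, manifest$outputs$path))
  now <- unname(tools::md5sum(paths))
  bad <- which(now != manifest$outputs$md5 | is.na(now))
  if (length(bad) > 0) {
    stop_dq("manifest digest mismatch for: ",
            paste(manifest$outputs$path[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write / read a simulation config as YAML
#' @param config A `"sim_config"`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  # a named list round-trips as a YAML map; a named vector loses its names
  vals$annotation_probs <- as.list(vals$annotation_probs)
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  if (!is.null(vals$annotation_probs)) {
    probs <- unlist(vals$annotation_probs)
    # absorb serialization round-off only; real mis-specification still errors
    if (abs(sum(probs) - 1) < 1e-6) probs <- probs / sum(probs)
    vals$annotation_probs <- probs
  }
  do.call(sim_config, vals)
}
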