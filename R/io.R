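#' Read a genotype dosage matrix from VCF or a dosage TSV
#'
#' Reads sample-by-variant risk-allele dosages. For VCF input the `DS`
#' FORMAT field is used when present, otherwise dosages are counted from
#' `GT`; columns are oriented so that each counts copies of the requested
#' effect allele. For a dosage TSV (samples as rows, first column
#' `sample_id`, one column per variant) values are taken as already
#' oriented to the effect allele.
#'
#' @param path Path to a VCF 4.x file (possibly gzipped) or a tab-separated
#'   dosage file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"dosage"`.
#' @param effect_alleles Optional named character vector `rsid -> allele`
#'   giving the allele each column must count (VCF only). Columns whose ALT
#'   differs from the effect allele are flipped (`dosage -> 2 - dosage`).
#'   An rsid absent from the file, or an allele that is neither REF nor
#'   ALT, is a hard error.
#' @return A tibble with column `sample_id` followed by one numeric dosage
#'   column per variant (values in \[0, 2\], `NA` for missing genotypes).
#'   The attribute `"variants"` holds a tibble of per-variant metadata
#'   (`rsid`, `chrom`, `pos`, `ref`, `alt`, `effect_allele`, `flipped`)
#'   when read from VCF.
#' @seealso [flip_dosage()], [read_phenotypes()], [cohort_bundle()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           effect_alleles = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- switch(format,
    vcf = read_genotypes_vcf(path, effect_alleles),
    dosage = read_genotypes_dosage(path, effect_alleles)
  )
  check_dosage_range(out)
  out
}

read_genotypes_vcf <- function(path, effect_alleles) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  rsid <- fix$ID
  if (anyNA(rsid) || anyDuplicated(rsid)) {
    abort("VCF records must carry unique, non-missing IDs")
  }
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), gt_to_dosage)
  } else {
    abort("VCF has neither GT nor DS in FORMAT")
  }
  # variants x samples -> samples x variants
  ds <- t(ds)
  colnames(ds) <- rsid
  variants <- tibble::tibble(
    rsid = rsid, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    effect_allele = fix$ALT, flipped = FALSE
  )
  if (!is.null(effect_alleles)) {
    unknown <- setdiff(names(effect_alleles), rsid)
    if (length(unknown)) {
      abort(sprintf("effect_alleles names unknown variant(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    idx <- match(names(effect_alleles), rsid)
    for (k in seq_along(idx)) {
      i <- idx[k]
      eff <- unname(effect_alleles[k])
      if (eff == variants$alt[i]) next
      if (eff == variants$ref[i]) {
        ds[, i] <- 2 - ds[, i]
        variants$effect_allele[i] <- eff
        variants$flipped[i] <- TRUE
      } else {
        abort(sprintf(
          "effect allele %s for %s is neither REF (%s) nor ALT (%s)",
          eff, rsid[i], variants$ref[i], variants$alt[i]))
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame(ds, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(ds)), out)
  attr(out, "variants") <- variants
  out
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

read_genotypes_dosage <- function(path, effect_alleles) {
  if (!is.null(effect_alleles)) {
    abort("effect_alleles reorientation requires allele metadata; dosage TSV input is assumed to be effect-allele oriented already")
  }
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(d) || ncol(d) < 2) abort("dosage file is empty or has no variant columns")
  names(d)[1] <- "sample_id"
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id)) abort("duplicate sample_id in dosage file")
  tibble::as_tibble(d)
}

check_dosage_range <- function(genotypes) {
  m <- dosage_matrix(genotypes)
  bad <- which(!is.na(m) & (m < 0 | m > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("dosage outside [0, 2] at sample %s, variant %s",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(genotypes)
}

#' Flip a dosage vector to the opposite allele
#'
#' @param dosage Numeric dosages in \[0, 2\].
#' @return `2 - dosage` (an involution: flipping twice restores the input).
#' @export
flip_dosage <- function(dosage) 2 - dosage

#' Write genotypes to a VCF file
#'
#' Serializes a genotype tibble (hard-called dosages) as VCF 4.2 with `GT`
#' genotypes, using the `"variants"` attribute (or a supplied variant
#' table) for coordinates and alleles.
#'
#' @param genotypes Genotype tibble as returned by [read_genotypes()] or
#'   [simulate_genotypes()].
#' @param path Output path; a `.gz` suffix is added by the writer if absent.
#' @param variants Optional variant metadata tibble with `rsid`, `chrom`,
#'   `pos` (and optionally `ref`/`alt` alleles).
#' @return The path written, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, variants = NULL) {
  variants <- variants %||% attr(genotypes, "variants")
  ids <- variant_ids(genotypes)
  if (is.null(variants)) {
    variants <- tibble::tibble(rsid = ids, chrom = "1",
                               pos = seq_along(ids), ref = "A", alt = "B")
  }
  variants <- variants[match(ids, variants$rsid), ]
  if (anyNA(variants$rsid)) abort("variant metadata missing for some genotype columns")
  ref <- variants$ref %||% rep("A", length(ids))
  alt <- variants$alt %||% variants$effect_allele %||% rep("B", length(ids))
  m <- round(t(dosage_matrix(genotypes)))
  gtstr <- matrix(c("0/0", "0/1", "1/1")[m + 1], nrow = nrow(m))
  gtstr[is.na(m)] <- "./."
  fix <- cbind(CHROM = as.character(variants$chrom), POS = as.character(variants$pos),
               ID = variants$rsid, REF = ref, ALT = alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = "GT", gtstr)
  colnames(gt) <- c("FORMAT", genotypes$sample_id)
  v <- methods::new("vcfR",
    meta = c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `sample_id`, `status` (1 = case,
#'   0 = control), optional `smoking` (1 = ever, 0 = never) and any further
#'   numeric covariate columns.
#' @return A tibble with `sample_id` as character and `status` as integer.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "status")
  miss <- setdiff(req, names(d))
  if (length(miss)) abort(sprintf("phenotype file missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  d$sample_id <- as.character(d$sample_id)
  d$status <- as.integer(d$status)
  if (!all(d$status %in% c(0L, 1L))) abort("status must be 0/1")
  if (anyDuplicated(d$sample_id)) abort("duplicate sample_id in phenotype file")
  tibble::as_tibble(d)
}

#' Bundle genotypes, phenotypes and variant metadata into one cohort
#'
#' Checks the one-to-one sample join and aligns phenotype rows to genotype
#' row order.
#'
#' @param genotypes Genotype tibble (`sample_id` + dosage columns).
#' @param phenotypes Phenotype tibble (`sample_id`, `status`, ...).
#' @param variants Optional variant metadata tibble; defaults to the
#'   genotype tibble's `"variants"` attribute.
#' @param label Cohort label, e.g. `"training"` or `"testing"`.
#' @return An object of class `cohort_bundle`: a list with elements
#'   `genotypes`, `phenotypes`, `variants`, `label`.
#' @export
cohort_bundle <- function(genotypes, phenotypes, variants = NULL,
                          label = "cohort") {
  variants <- variants %||% attr(genotypes, "variants")
  if (anyDuplicated(genotypes$sample_id)) abort("duplicate sample_id in genotypes")
  if (!setequal(genotypes$sample_id, phenotypes$sample_id) ||
      nrow(genotypes) != nrow(phenotypes)) {
    abort("genotypes and phenotypes must contain exactly the same sample_ids")
  }
  phenotypes <- phenotypes[match(genotypes$sample_id, phenotypes$sample_id), ]
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 variants = variants, label = label),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle '%s': %d samples (%d cases / %d controls), %d variants>\n",
              x$label, nrow(x$genotypes), sum(x$phenotypes$status == 1),
              sum(x$phenotypes$status == 0), length(variant_ids(x$genotypes))))
  invisible(x)
}

#' Impute missing dosages
#'
#' Default missingness policy for scoring: per-variant mean imputation with
#' `2 * f`, where `f` is the effect-allele frequency in controls (or in all
#' samples when no phenotypes are given). The `"drop_sample"` policy
#' removes samples with any missing dosage instead.
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Optional phenotype tibble used to restrict the
#'   frequency estimate to controls.
#' @param policy `"mean_control"` or `"drop_sample"`.
#' @return A genotype tibble with no missing values.
#' @export
impute_genotypes <- function(genotypes, phenotypes = NULL,
                             policy = c("mean_control", "drop_sample")) {
  policy <- match.arg(policy)
  m <- dosage_matrix(genotypes)
  if (!anyNA(m)) return(genotypes)
  if (policy == "drop_sample") {
    keep <- !apply(is.na(m), 1, any)
    out <- genotypes[keep, ]
    attr(out, "variants") <- attr(genotypes, "variants")
    return(out)
  }
  rows <- if (!is.null(phenotypes)) {
    genotypes$sample_id %in% phenotypes$sample_id[phenotypes$status == 0]
  } else rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (!any(nas)) next
    f <- mean(m[rows, j], na.rm = TRUE) / 2
    if (is.nan(f)) f <- mean(m[, j], na.rm = TRUE) / 2
    m[nas, j] <- 2 * f
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = genotypes$sample_id),
                          tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
  attr(out, "variants") <- attr(genotypes, "variants")
  out
}
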