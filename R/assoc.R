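#' Per-variant additive logistic association scan
#'
#' Fits, for every variant, the per-allele (additive) logistic regression
#' `status ~ dosage (+ covariates)` on per-variant complete cases and
#' reports Wald statistics: the log-odds per effect allele, its standard
#' error, the odds ratio with 95% CI (`exp(beta +/- 1.96 se)`), and the
#' two-sided Wald p-value.
#'
#' Monomorphic variants are flagged (`note = "monomorphic"`) with missing
#' statistics, and quasi-separated fits are flagged
#' (`note = "separation"`) with an infinite OR marker rather than
#' crashing.
#'
#' @param genotypes Genotype tibble (effect-allele dosages).
#' @param phenotypes Phenotype tibble with `status` and any covariate
#'   columns.
#' @param covariates Optional character vector of phenotype columns to
#'   adjust for.
#' @return A tibble with one row per variant: `rsid`, `n`, `beta`, `se`,
#'   `or`, `or_low`, `or_high`, `p_value`, `note`.
#' @export
assoc_scan <- function(genotypes, phenotypes, covariates = NULL) {
  ids <- variant_ids(genotypes)
  ph <- phenotypes[match(genotypes$sample_id, phenotypes$sample_id), ]
  assert_binary_status(ph$status)
  m <- dosage_matrix(genotypes)
  covm <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(ph))
    if (length(miss)) abort(sprintf("covariate(s) not in phenotypes: %s",
                                    paste(miss, collapse = ", ")))
    covm <- as.matrix(ph[covariates])
  }
  rows <- purrr::map(seq_along(ids), function(j) {
    univariate_assoc_one(m[, j], ph$status, covm, ids[j])
  })
  dplyr::bind_rows(rows)
}

univariate_assoc_one <- function(dosage, status, covm, rsid) {
  ok <- !is.na(dosage)
  if (!is.null(covm)) ok <- ok & complete.cases(covm)
  g <- dosage[ok]; y <- status[ok]
  out <- tibble::tibble(rsid = rsid, n = sum(ok), beta = NA_real_,
                        se = NA_real_, or = NA_real_, or_low = NA_real_,
                        or_high = NA_real_, p_value = NA_real_,
                        note = NA_character_)
  if (length(unique(g)) < 2) {
    out$note <- "monomorphic"
    return(out)
  }
  X <- if (is.null(covm)) data.frame(g = g) else
    data.frame(g = g, covm[ok, , drop = FALSE])
  fit <- suppressWarnings(glm(y ~ ., data = X, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-10)))
  b <- coef(fit)[["g"]]
  se <- sqrt(vcov(fit)["g", "g"])
  if (!fit$converged || abs(b) > 15 || se > 100) {
    out$note <- "separation"
    out$or <- if (b > 0) Inf else 0
    return(out)
  }
  out$beta <- b
  out$se <- se
  out$or <- exp(b)
  out$or_low <- exp(b - 1.96 * se)
  out$or_high <- exp(b + 1.96 * se)
  out$p_value <- 2 * pnorm(-abs(b / se))
  out
}

#' Single-variant association
#'
#' Convenience wrapper around [assoc_scan()] for one variant column.
#'
#' @param cohort A [cohort_bundle()].
#' @param rsid Variant to test.
#' @param covariates Optional covariate column names.
#' @return One-row association tibble.
#' @export
univariate_assoc <- function(cohort, rsid, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (!rsid %in% variant_ids(cohort$genotypes)) {
    abort(sprintf("unknown variant: %s", rsid))
  }
  assoc_scan(cohort$genotypes[c("sample_id", rsid)], cohort$phenotypes,
             covariates)
}

#' Retain significant variants from an association scan
#'
#' Keeps exactly the variants with `p_value < alpha` (strict inequality),
#' in their original order. Flagged variants (monomorphic, separation)
#' have no p-value and are never retained. No multiple-testing correction
#' is applied: this mirrors the plain per-SNP screen used in
#' replication-based risk-panel construction, and is a deliberate design
#' choice of that screening step, not a general recommendation.
#'
#' @param results Tibble from [assoc_scan()].
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of retained rsids.
#' @export
screen_assoc <- function(results, alpha = 0.05) {
  if (!nrow(results)) abort("empty association results")
  results$rsid[!is.na(results$p_value) & results$p_value < alpha]
}
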