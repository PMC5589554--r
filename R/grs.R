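#' Compute per-sample genetic risk scores
#'
#' The weighted-sum score of sample `s` is `sum_i beta_i * g_si`, where
#' `g_si` counts risk alleles (0-2) at SNP `i`. The
#' `"allele_count_rescaled"` mode multiplies the weighted sum by
#' `k / sum(beta_i)` so that one score point corresponds to roughly one
#' risk allele; the two modes differ only by a positive scale factor, so
#' sample rankings are identical.
#'
#' Orientation: genotype columns are assumed to count each weight's effect
#' allele. When both the genotype metadata and the weight table carry an
#' `effect_allele`, mismatching columns are flipped (`2 - dosage`)
#' automatically; a logical `count_complement` column in the weight table
#' forces a flip for fits produced on opposite-oriented columns (see
#' [as_weight_table()]).
#'
#' @param genotypes Genotype tibble.
#' @param weights Weight tibble with `rsid` and `beta` (e.g.
#'   [grs_weights()] or [as_weight_table()]).
#' @param mode `"weighted_sum"` (default) or `"allele_count_rescaled"`.
#' @param allow_missing_variants If `TRUE`, weight rows whose rsid is
#'   absent from the genotypes are dropped with a warning and `k` is
#'   decremented; otherwise this is an error.
#' @param missing Missing-dosage policy: `"impute_mean"` fills missing
#'   dosages with `2 * effect_freq` from the weight table when available,
#'   otherwise the column mean; `"fail"` errors on any missing dosage.
#' @return A tibble of class `score_vector` with `sample_id` and `grs`.
#'   Attributes: `k` (number of SNPs scored), `mode`, `weight_source`.
#' @export
compute_grs <- function(genotypes, weights,
                        mode = c("weighted_sum", "allele_count_rescaled"),
                        allow_missing_variants = FALSE,
                        missing = c("impute_mean", "fail")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  ids <- variant_ids(genotypes)
  absent <- setdiff(weights$rsid, ids)
  if (length(absent)) {
    if (!allow_missing_variants) {
      abort(sprintf("weight table variant(s) absent from genotypes: %s",
                    paste(absent, collapse = ", ")))
    }
    warn(sprintf("dropping %d weight(s) absent from genotypes (k reduced)",
                 length(absent)))
    weights <- weights[!weights$rsid %in% absent, ]
  }
  if (!nrow(weights)) abort("no weights left to score")
  m <- dosage_matrix(genotypes)[, weights$rsid, drop = FALSE]

  flip <- rep(FALSE, nrow(weights))
  gv <- attr(genotypes, "variants")
  if (!is.null(gv) && "effect_allele" %in% names(gv) &&
      "effect_allele" %in% names(weights)) {
    geno_eff <- gv$effect_allele[match(weights$rsid, gv$rsid)]
    known <- !is.na(geno_eff) & !is.na(weights$effect_allele)
    flip[known] <- geno_eff[known] != weights$effect_allele[known]
  }
  if ("count_complement" %in% names(weights)) {
    flip <- flip | (weights$count_complement %in% TRUE)
  }
  if (any(flip)) m[, flip] <- 2 - m[, flip]

  if (anyNA(m)) {
    if (missing == "fail") abort("missing dosages; impute first or use missing = 'impute_mean'")
    for (j in which(colSums(is.na(m)) > 0)) {
      fill <- if ("effect_freq" %in% names(weights) &&
                  !is.na(weights$effect_freq[j])) 2 * weights$effect_freq[j]
              else mean(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- fill
    }
  }
  score <- drop(m %*% weights$beta)
  if (mode == "allele_count_rescaled") {
    score <- score * nrow(weights) / sum(weights$beta)
  }
  out <- tibble::tibble(sample_id = genotypes$sample_id, grs = unname(score))
  attr(out, "k") <- nrow(weights)
  attr(out, "mode") <- mode
  attr(out, "weight_source") <- attr(weights, "weight_source") %||% "weights"
  class(out) <- c("score_vector", class(out))
  out
}

#' Combined smoking + GRS risk score
#'
#' The combined score is the logistic linear predictor
#' `beta_smoke * smoking + beta_grs * grs` from a `status ~ smoking + grs`
#' fit (the intercept is omitted: it shifts every score equally, so all
#' rankings and quantile strata are unchanged).
#'
#' @param scores A `score_vector` from [compute_grs()].
#' @param phenotypes Phenotype tibble with `status` and `smoking`.
#' @param model Optional prefitted `glm` with terms `smoking` and `grs`;
#'   by default the model is fitted on the supplied cohort.
#' @return A tibble with `sample_id`, `grs`, `combined`.
#' @export
combined_score <- function(scores, phenotypes, model = NULL) {
  d <- dplyr::inner_join(scores, phenotypes, by = "sample_id")
  if (nrow(d) != nrow(scores)) abort("phenotypes missing for some scored samples")
  if (!"smoking" %in% names(d) || anyNA(d$smoking)) {
    abort("smoking status missing and no imputation policy is defined")
  }
  if (is.null(model)) {
    assert_binary_status(d$status)
    model <- glm(status ~ smoking + grs, data = d, family = binomial())
  }
  cf <- coef(model)
  if (!all(c("smoking", "grs") %in% names(cf))) {
    abort("model must contain terms `smoking` and `grs`")
  }
  tibble::tibble(sample_id = d$sample_id, grs = d$grs,
                 combined = cf[["smoking"]] * d$smoking + cf[["grs"]] * d$grs)
}
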