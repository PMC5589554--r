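#' Run the two-stage GRS risk-model pipeline
#'
#' End-to-end orchestration on a training cohort, with optional external
#' validation on a testing cohort:
#'
#' 1. per-variant additive logistic association scan ([assoc_scan()]);
#' 2. variant QC — INFO, control MAF, control HWE, windowed LD pruning
#'    ordered by the in-sample association p-values ([apply_qc()]);
#' 3. univariate screen at `alpha` ([screen_assoc()]);
#' 4. L1-penalized logistic selection over the screened SNPs with
#'    cross-validated penalty choice ([select_lambda()]);
#' 5. GRS and combined smoking + GRS scores ([compute_grs()],
#'    [combined_score()]);
#' 6. quartile risk stratification with ORs and trend tests
#'    ([stratify_risk()]) and model evaluation ([evaluate_models()]).
#'
#' The weight table fitted on the training cohort is frozen before the
#' testing stage: the testing cohort is only scored and evaluated, never
#' refitted.
#'
#' @param training A [cohort_bundle()] used to fit weights.
#' @param testing Optional [cohort_bundle()] scored with the frozen
#'   training weights.
#' @param thresholds [qc_thresholds()].
#' @param alpha Univariate screening threshold (default 0.05).
#' @param lambda_rule `"cv_1se"` (default) or `"cv_min"`.
#' @param folds,seed Cross-validation folds and seed for
#'   [select_lambda()].
#' @param probs Quantile cut points for stratification.
#' @param mode GRS mode, `"weighted_sum"` or `"allele_count_rescaled"`.
#' @param covariates Optional covariate names for the association scan.
#' @return A list of class `grs_pipeline`: `weights` (frozen weight
#'   table), `qc`, `assoc`, `screened`, `lasso` (the `lasso_path`), and
#'   per-cohort results under `cohorts[[label]]` (`scores`,
#'   `strata_grs`, `strata_combined`, `evaluation`).
#' @export
run_grs_pipeline <- function(training, testing = NULL,
                             thresholds = qc_thresholds(), alpha = 0.05,
                             lambda_rule = "cv_1se", folds = 10, seed = 1,
                             probs = c(0.25, 0.5, 0.75),
                             mode = "weighted_sum", covariates = NULL) {
  stopifnot(inherits(training, "cohort_bundle"))
  assoc <- assoc_scan(training$genotypes, training$phenotypes, covariates)
  qc <- apply_qc(training, thresholds,
                 assoc_p = setNames(assoc$p_value, assoc$rsid))
  post_qc <- assoc[assoc$rsid %in% qc_keep(qc), ]
  screened <- screen_assoc(post_qc, alpha = alpha)
  if (!length(screened)) abort("no variants survive screening")
  g <- impute_genotypes(training$genotypes, training$phenotypes)
  lasso <- select_lambda(g[screened], training$phenotypes$status,
                         folds = folds, rule = lambda_rule, seed = seed)
  weights <- as_weight_table(lasso, variants = training$variants)
  if (!nrow(weights)) abort("penalized selection kept no variants")

  score_cohort <- function(cohort) {
    gi <- impute_genotypes(cohort$genotypes, cohort$phenotypes)
    attr(gi, "variants") <- cohort$variants
    scores <- compute_grs(gi, weights, mode = mode,
                          allow_missing_variants = TRUE)
    comb <- combined_score(scores, cohort$phenotypes)
    strata_grs <- stratify_risk(scores, cohort$phenotypes, probs = probs)
    comb_scores <- tibble::tibble(sample_id = comb$sample_id,
                                  grs = comb$combined)
    strata_comb <- stratify_risk(comb_scores, cohort$phenotypes,
                                 probs = probs)
    evaluation <- evaluate_models(cohort$phenotypes, scores)
    list(scores = dplyr::mutate(scores, combined = comb$combined),
         strata_grs = strata_grs, strata_combined = strata_comb,
         evaluation = evaluation)
  }
  cohorts <- list()
  cohorts[[training$label]] <- score_cohort(training)
  if (!is.null(testing)) {
    stopifnot(inherits(testing, "cohort_bundle"))
    cohorts[[testing$label]] <- score_cohort(testing)
  }
  structure(list(weights = weights, qc = qc, assoc = assoc,
                 screened = screened, lasso = lasso, cohorts = cohorts),
            class = "grs_pipeline")
}

#' @export
print.grs_pipeline <- function(x, ...) {
  cat(sprintf("<grs_pipeline: %d screened -> %d weighted SNPs; cohorts: %s>\n",
              length(x$screened), nrow(x$weights),
              paste(names(x$cohorts), collapse = ", ")))
  for (nm in names(x$cohorts)) {
    ev <- x$cohorts[[nm]]$evaluation
    cat(sprintf("  %s AUC: %s\n", nm,
                paste(sprintf("%s %.3f", ev$model, ev$auc), collapse = ", ")))
  }
  invisible(x)
}
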