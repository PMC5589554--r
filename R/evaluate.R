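# Model evaluation: C-statistics with structural-component (DeLong)
# variances, paired nonparametric AUC comparison, Hosmer-Lemeshow
# calibration, and the three standard risk models.

#' Fit the epidemiologic, genetic and extended risk models
#'
#' Three logistic regressions on the same cohort: `status ~ smoking`
#' (epidemiologic), `status ~ grs` (genetic) and `status ~ smoking + grs`
#' (extended).
#'
#' @param phenotypes Phenotype tibble with `status` and `smoking`.
#' @param scores Score tibble with `grs`.
#' @return A named list of class `risk_models` with elements
#'   `epidemiologic`, `genetic`, `extended` (each a `glm`), plus the
#'   joined `data`. Quasi-separated fits carry a `separation` flag.
#' @export
fit_risk_models <- function(phenotypes, scores) {
  d <- dplyr::inner_join(phenotypes, scores, by = "sample_id")
  if (!nrow(d)) abort("no overlapping samples between phenotypes and scores")
  assert_binary_status(d$status)
  if (anyNA(d$smoking)) abort("smoking is missing for some samples")
  if (length(unique(d$smoking)) < 2) {
    abort("smoking is constant: the epidemiologic model is degenerate")
  }
  if (length(unique(d$grs)) < 2) abort("GRS is constant: the genetic model is degenerate")
  fits <- list(
    epidemiologic = glm(status ~ smoking, data = d, family = binomial()),
    genetic = glm(status ~ grs, data = d, family = binomial()),
    extended = glm(status ~ smoking + grs, data = d, family = binomial())
  )
  for (nm in names(fits)) {
    f <- fits[[nm]]
    fits[[nm]]$separation <- !f$converged || any(abs(coef(f)[-1]) > 15)
    if (fits[[nm]]$separation) {
      warn(sprintf("%s model shows quasi-separation; coefficients unreliable", nm))
    }
  }
  structure(c(fits, list(data = d)), class = "risk_models")
}

# placement values: per-case fraction of controls scored below it (ties
# 1/2), and per-control fraction of cases scored above it
placements <- function(score, status) {
  cases <- score[status == 1]
  controls <- score[status == 0]
  m <- length(cases); n <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # V10_i = P(control < case_i) + 0.5 P(tie); from ranks within pooled vector
  rc <- r[seq_len(m)] - rank(cases, ties.method = "average")
  v10 <- rc / n
  rn <- r[m + seq_len(n)] - rank(controls, ties.method = "average")
  v01 <- 1 - rn / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' C-statistic (AUC) with a structural-components confidence interval
#'
#' The AUC is the concordance probability that a random case outranks a
#' random control (ties counted 1/2), computed by the rank method. The
#' variance is the sum of the per-case and per-control placement-value
#' variances (DeLong components); the normal-interval CI is truncated to
#' \[0, 1\].
#'
#' @param score Numeric risk score per sample.
#' @param status Binary outcome (1 = case).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `auc`, `auc_low`, `auc_high`, `se`, `n_cases`,
#'   `n_controls`.
#' @export
auc_ci <- function(score, status, conf_level = 0.95) {
  assert_binary_status(status)
  if (anyNA(score)) abort("scores contain missing values")
  pl <- placements(score, status)
  se <- sqrt(var(pl$v10) / pl$m + var(pl$v01) / pl$n)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(auc = pl$auc,
                 auc_low = max(0, pl$auc - zq * se),
                 auc_high = min(1, pl$auc + zq * se),
                 se = se, n_cases = pl$m, n_controls = pl$n)
}

#' Paired nonparametric comparison of two correlated AUCs
#'
#' DeLong-style structural-components test for two risk scores measured on
#' the same samples: the variance of the AUC difference is estimated from
#' the paired per-sample placement values, and a two-sided normal p-value
#' is reported. When the two scores induce identical placements the
#' difference is exactly 0 and `p = 1` is returned with a `degenerate`
#' flag.
#'
#' @param score_a,score_b Two risk scores on identical samples.
#' @param status Binary outcome.
#' @return A tibble: `auc_a`, `auc_b`, `diff`, `se`, `p_value`,
#'   `degenerate`.
#' @export
compare_auc <- function(score_a, score_b, status) {
  assert_binary_status(status)
  if (length(score_a) != length(score_b) ||
      length(score_a) != length(status)) {
    abort("score_a, score_b and status must have equal length (paired design)")
  }
  pa <- placements(score_a, status)
  pb <- placements(score_b, status)
  dv10 <- pa$v10 - pb$v10
  dv01 <- pa$v01 - pb$v01
  v <- var(dv10) / pa$m + var(dv01) / pa$n
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, diff = d,
                          se = 0, p_value = 1, degenerate = TRUE))
  }
  se <- sqrt(v)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = se,
                 p_value = 2 * pnorm(-abs(d / se)), degenerate = FALSE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups samples into `groups` quantile bins of predicted probability
#' ("deciles of risk" for the default 10) and compares observed and
#' expected event counts: the statistic is
#' `sum (O - E)^2 / (E (1 - E / n_g))`, referred to chi-square with
#' `groups - 2` degrees of freedom. Groups with zero expected events are
#' merged into their neighbour with a warning.
#'
#' @param predicted Predicted event probabilities in (0, 1).
#' @param status Binary outcome.
#' @param groups Number of risk groups (>= 2, default 10).
#' @return A tibble: `statistic`, `df`, `p_value`, `groups`.
#' @export
hosmer_lemeshow <- function(predicted, status, groups = 10) {
  assert_binary_status(status)
  if (groups < 2) abort("groups must be >= 2")
  if (any(predicted <= 0 | predicted >= 1)) {
    abort("predicted probabilities must lie strictly in (0, 1)")
  }
  br <- unique(quantile(predicted, probs = seq(0, 1, length.out = groups + 1),
                        type = 7, names = FALSE))
  g <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  obs <- tapply(status, g, sum)
  exp_ <- tapply(predicted, g, sum)
  ng <- tapply(status, g, length)
  while (any(exp_ == 0 | exp_ == ng) && length(obs) > 2) {
    warn("merging a risk group with degenerate expected count")
    i <- which(exp_ == 0 | exp_ == ng)[1]
    j <- if (i == 1) 2 else i - 1
    obs[j] <- obs[j] + obs[i]; exp_[j] <- exp_[j] + exp_[i]
    ng[j] <- ng[j] + ng[i]
    obs <- obs[-i]; exp_ <- exp_[-i]; ng <- ng[-i]
  }
  stat <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / ng)))
  df <- max(length(obs) - 2, 0)
  p <- if (df >= 1) pchisq(stat, df = df, lower.tail = FALSE)
       else if (stat < 1e-8) 1 else NA_real_
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 groups = length(obs))
}

#' ROC curve points for a risk score
#'
#' @param score Numeric risk score.
#' @param status Binary outcome.
#' @return A tibble `threshold`, `fpr`, `tpr` sweeping all distinct score
#'   values.
#' @export
roc_points <- function(score, status) {
  assert_binary_status(status)
  th <- sort(unique(score), decreasing = TRUE)
  m <- sum(status == 1); n <- sum(status == 0)
  tpr <- vapply(th, function(t) sum(score >= t & status == 1) / m, 0)
  fpr <- vapply(th, function(t) sum(score >= t & status == 0) / n, 0)
  tibble::tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate the three risk models on a scored cohort
#'
#' Fits the epidemiologic, genetic and extended models
#' ([fit_risk_models()]), computes each model's C-statistic with CI,
#' compares each model's AUC with the epidemiologic baseline by the
#' paired structural-components test, and runs the Hosmer-Lemeshow
#' calibration test on every model's predicted probabilities.
#'
#' @param phenotypes Phenotype tibble.
#' @param scores Score tibble with `grs`.
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @return A tibble of class `eval_report`, one row per model: `model`,
#'   `auc`, `auc_low`, `auc_high`, `p_vs_epidemiologic` (paired AUC
#'   comparison; `NA` for the baseline itself), `hl_statistic`, `hl_p`,
#'   `hl_groups`. Attributes: `"models"` (the fitted `risk_models`) and
#'   `"roc"` (long tibble of ROC points per model).
#' @export
evaluate_models <- function(phenotypes, scores, hl_groups = 10) {
  fits <- fit_risk_models(phenotypes, scores)
  d <- fits$data
  nms <- c("epidemiologic", "genetic", "extended")
  pred <- lapply(fits[nms], predict, type = "response")
  rows <- purrr::map(nms, function(nm) {
    a <- auc_ci(pred[[nm]], d$status)
    hl <- hosmer_lemeshow(pmin(pmax(pred[[nm]], 1e-12), 1 - 1e-12),
                          d$status, groups = hl_groups)
    tibble::tibble(model = nm, auc = a$auc, auc_low = a$auc_low,
                   auc_high = a$auc_high,
                   p_vs_epidemiologic = if (nm == "epidemiologic") NA_real_
                   else compare_auc(pred[[nm]], pred$epidemiologic,
                                    d$status)$p_value,
                   hl_statistic = hl$statistic, hl_p = hl$p_value,
                   hl_groups = hl$groups)
  })
  out <- dplyr::bind_rows(rows)
  roc <- dplyr::bind_rows(lapply(nms, function(nm) {
    dplyr::mutate(roc_points(pred[[nm]], d$status), model = nm)
  }))
  attr(out, "models") <- fits
  attr(out, "roc") <- roc
  class(out) <- c("eval_report", class(out))
  out
}

#' Serialize an evaluation report
#'
#' Writes the per-model table as TSV, a JSON mirror, and the ROC curve
#' points as `<path>.roc.tsv`.
#'
#' @param report An `eval_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  readr::write_tsv(as.data.frame(report), path)
  jsonlite::write_json(as.data.frame(report), paste0(path, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  roc <- attr(report, "roc")
  if (!is.null(roc)) readr::write_tsv(roc, paste0(path, ".roc.tsv"))
  invisible(path)
}
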