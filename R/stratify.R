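#' Assign samples to quantile-based risk categories
#'
#' Cut points are quantiles (type 7, linear interpolation) of the basis
#' population's scores — controls by default, which yields near-equal
#' control counts per category in a case-control sample. Intervals are
#' `[lower, upper)` with the top interval closed above, so a score exactly
#' equal to the top cut point lands in the top category.
#'
#' @param scores Score tibble (`sample_id`, score column).
#' @param phenotypes Phenotype tibble (required when `basis = "controls"`).
#' @param probs Quantile probabilities of the interior cut points
#'   (default quartiles `c(0.25, 0.5, 0.75)`).
#' @param basis `"controls"` (default) or `"all"`.
#' @param score_col Name of the score column (default `"grs"`).
#' @return A tibble `sample_id`, score column, `category` (integer
#'   `0..length(probs)`), with attribute `"cutpoints"`.
#' @export
quantile_categories <- function(scores, phenotypes = NULL,
                                probs = c(0.25, 0.5, 0.75),
                                basis = c("controls", "all"),
                                score_col = "grs") {
  basis <- match.arg(basis)
  x <- scores[[score_col]]
  if (is.null(x)) abort(sprintf("no column `%s` in scores", score_col))
  if (length(unique(x)) < length(probs) + 1) {
    abort("scores are degenerate: need more distinct values than categories")
  }
  base <- if (basis == "controls") {
    if (is.null(phenotypes)) abort("basis = 'controls' needs phenotypes")
    ctrl <- phenotypes$sample_id[phenotypes$status == 0]
    x[scores$sample_id %in% ctrl]
  } else x
  cut_points <- quantile(base, probs = probs, type = 7, names = FALSE)
  category <- findInterval(x, cut_points)
  counts <- tabulate(category + 1, nbins = length(probs) + 1)
  if (any(counts == 0)) {
    abort(sprintf("tied scores leave category %d (cut at quantile %.2f) empty",
                  which(counts == 0)[1] - 1,
                  c(probs, 1)[which(counts == 0)[1]]))
  }
  out <- scores
  out$category <- category
  attr(out, "cutpoints") <- cut_points
  out
}

#' Split scores into low/high risk groups at an upper percentile
#'
#' @param scores Score tibble.
#' @param prob Percentile defining the cutoff (default 0.90).
#' @param basis `"all"` (default) or `"controls"`.
#' @param phenotypes Needed for `basis = "controls"`.
#' @param score_col Score column name.
#' @return A tibble with `sample_id`, score, `group` (`"low"` if score <
#'   cutoff, else `"high"`); attribute `"cutoff"`.
#' @export
highlow_split <- function(scores, prob = 0.90, basis = c("all", "controls"),
                          phenotypes = NULL, score_col = "grs") {
  basis <- match.arg(basis)
  x <- scores[[score_col]]
  if (length(unique(x)) < 2) abort("scores are degenerate: all values equal")
  base <- if (basis == "controls") {
    if (is.null(phenotypes)) abort("basis = 'controls' needs phenotypes")
    x[scores$sample_id %in% phenotypes$sample_id[phenotypes$status == 0]]
  } else x
  cutoff <- quantile(base, probs = prob, type = 7, names = FALSE)
  out <- scores
  out$group <- ifelse(x < cutoff, "low", "high")
  if (length(unique(out$group)) < 2) abort("degenerate split: one group is empty")
  attr(out, "cutoff") <- cutoff
  out
}

#' Per-category odds ratios against a reference category
#'
#' Crude mode: the OR of category `c` versus the reference is the 2x2
#' cross-product ratio with Woolf (log-scale Wald) 95% CI
#' `exp(log OR +/- 1.96 sqrt(sum 1/cell))`; any zero cell triggers the
#' Haldane-Anscombe 0.5 correction, flagged in the output. Adjusted mode
#' (when `data` and `adjust` are given) uses indicator-coded logistic
#' regression with covariates and Wald CIs.
#'
#' @param counts Tibble with columns `category`, `cases`, `controls`
#'   (first row = reference unless `reference` names another category).
#' @param reference Reference category value (default: first row).
#' @param data Optional per-sample tibble (`category`, `status`, covariate
#'   columns) for adjusted ORs.
#' @param adjust Character vector of covariate names in `data`.
#' @return A tibble: `category`, `cases`, `controls`, `or`, `or_low`,
#'   `or_high`, `p_value`, `corrected` (Haldane flag). Reference OR is 1.
#' @export
category_or <- function(counts, reference = NULL, data = NULL, adjust = NULL) {
  stopifnot(all(c("category", "cases", "controls") %in% names(counts)))
  ref <- reference %||% counts$category[1]
  if (!ref %in% counts$category) abort("reference category not found")
  i0 <- match(ref, counts$category)
  if (counts$cases[i0] == 0 || counts$controls[i0] == 0) {
    abort("reference category must contain both cases and controls")
  }
  out <- tibble::tibble(category = counts$category, cases = counts$cases,
                        controls = counts$controls, or = NA_real_,
                        or_low = NA_real_, or_high = NA_real_,
                        p_value = NA_real_, corrected = FALSE)
  if (is.null(adjust)) {
    a0 <- counts$cases[i0]; b0 <- counts$controls[i0]
    for (i in seq_len(nrow(counts))) {
      if (i == i0) { out$or[i] <- 1; next }
      cell <- c(counts$cases[i], counts$controls[i], a0, b0)
      if (any(cell == 0)) { cell <- cell + 0.5; out$corrected[i] <- TRUE }
      lor <- log(cell[1]) - log(cell[2]) - log(cell[3]) + log(cell[4])
      se <- sqrt(sum(1 / cell))
      out$or[i] <- exp(lor)
      out$or_low[i] <- exp(lor - 1.96 * se)
      out$or_high[i] <- exp(lor + 1.96 * se)
      out$p_value[i] <- 2 * pnorm(-abs(lor / se))
    }
  } else {
    if (is.null(data)) abort("adjusted ORs need per-sample `data`")
    miss <- setdiff(c("category", "status", adjust), names(data))
    if (length(miss)) abort(sprintf("`data` missing column(s): %s",
                                    paste(miss, collapse = ", ")))
    d <- data
    d$category <- factor(d$category, levels = counts$category)
    d$category <- stats::relevel(d$category, ref = as.character(ref))
    fml <- stats::reformulate(c("category", adjust), response = "status")
    fit <- glm(fml, data = d, family = binomial())
    cf <- coef(fit); vc <- vcov(fit)
    for (i in seq_len(nrow(counts))) {
      if (i == i0) { out$or[i] <- 1; next }
      term <- paste0("category", counts$category[i])
      b <- cf[[term]]; se <- sqrt(vc[term, term])
      out$or[i] <- exp(b)
      out$or_low[i] <- exp(b - 1.96 * se)
      out$or_high[i] <- exp(b + 1.96 * se)
      out$p_value[i] <- 2 * pnorm(-abs(b / se))
    }
  }
  out
}

#' Test for trend in risk across ordered categories
#'
#' Wald p-value for the ordinal category score entered as a single linear
#' term in logistic regression (optionally covariate-adjusted). With
#' `score_type = "median"` the per-category median of a supplied numeric
#' score is used as the trend variable instead of the category index.
#'
#' @param category Ordinal category per sample (integer 0..K).
#' @param status Binary outcome per sample.
#' @param data Optional tibble of covariates (same row order).
#' @param adjust Covariate names in `data`.
#' @param score_type `"index"` (default) or `"median"`.
#' @param scores Numeric per-sample scores, required for
#'   `score_type = "median"`.
#' @return Two-sided Wald p-value for the trend term.
#' @export
trend_test <- function(category, status, data = NULL, adjust = NULL,
                       score_type = c("index", "median"), scores = NULL) {
  score_type <- match.arg(score_type)
  assert_binary_status(status)
  if (length(unique(category)) < 2) abort("need >= 2 non-empty categories")
  trend <- if (score_type == "index") as.numeric(category) else {
    if (is.null(scores)) abort("score_type = 'median' needs `scores`")
    med <- tapply(scores, category, median)
    unname(med[as.character(category)])
  }
  d <- data.frame(status = status, trend = trend)
  if (!is.null(adjust)) {
    miss <- setdiff(adjust, names(data))
    if (length(miss)) abort(sprintf("`data` missing column(s): %s",
                                    paste(miss, collapse = ", ")))
    d <- cbind(d, data[adjust])
  }
  fit <- glm(status ~ ., data = d, family = binomial())
  b <- coef(fit)[["trend"]]
  se <- sqrt(vcov(fit)["trend", "trend"])
  2 * pnorm(-abs(b / se))
}

#' Stratified risk table for a scored cohort
#'
#' Assigns quantile categories, tabulates case/control counts with
#' column percentages (100 * count / column total, rounded half-up to two
#' decimals), computes per-category ORs against the bottom category
#' ([category_or()]) and the trend p-value ([trend_test()]).
#'
#' @param scores Score tibble.
#' @param phenotypes Phenotype tibble.
#' @param probs Interior quantile cut points.
#' @param basis Quantile basis population, `"controls"` or `"all"`.
#' @param adjust Optional covariate names (taken from `phenotypes`) for
#'   adjusted ORs and an adjusted trend test.
#' @param score_col Score column name.
#' @return A tibble of class `stratified_risk_table`: `category`, `label`,
#'   `cases`, `case_pct`, `controls`, `control_pct`, `or`, `or_low`,
#'   `or_high`, `p_value`, `corrected`. Attributes: `p_trend`,
#'   `cutpoints`, `adjustment`.
#' @export
stratify_risk <- function(scores, phenotypes, probs = c(0.25, 0.5, 0.75),
                          basis = "controls", adjust = NULL,
                          score_col = "grs") {
  qc <- quantile_categories(scores, phenotypes, probs = probs, basis = basis,
                            score_col = score_col)
  d <- dplyr::inner_join(
    qc[c("sample_id", "category")],
    phenotypes[c("sample_id", "status", intersect(adjust, names(phenotypes)))],
    by = "sample_id")
  counts <- d |>
    dplyr::count(.data$category, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$category)
  counts <- tibble::tibble(category = counts$category,
                           cases = counts[["1"]] %||% 0L,
                           controls = counts[["0"]] %||% 0L)
  ors <- category_or(counts, reference = counts$category[1],
                     data = d, adjust = adjust)
  cut_points <- attr(qc, "cutpoints")
  k <- length(probs)
  labels <- c(sprintf("0 (< Q%d)", round(100 * probs[1])),
              sprintf("%d (Q%d-Q%d)", seq_len(k - 1),
                      round(100 * probs[-k]), round(100 * probs[-1])),
              sprintf("%d (>= Q%d)", k, round(100 * probs[k])))
  out <- tibble::tibble(
    category = ors$category,
    label = labels[ors$category + 1],
    cases = ors$cases,
    case_pct = round_half_up(100 * ors$cases / sum(ors$cases), 2),
    controls = ors$controls,
    control_pct = round_half_up(100 * ors$controls / sum(ors$controls), 2),
    or = ors$or, or_low = ors$or_low, or_high = ors$or_high,
    p_value = ors$p_value, corrected = ors$corrected
  )
  attr(out, "p_trend") <- trend_test(d$category, d$status, data = d,
                                     adjust = adjust)
  attr(out, "cutpoints") <- cut_points
  attr(out, "adjustment") <- adjust %||% character(0)
  class(out) <- c("stratified_risk_table", class(out))
  out
}

#' @export
print.stratified_risk_table <- function(x, ...) {
  cat(sprintf("Stratified risk table (%s-adjusted), P for trend = %.3g\n",
              if (length(attr(x, "adjustment"))) "covariate" else "un",
              attr(x, "p_trend")))
  NextMethod()
}
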