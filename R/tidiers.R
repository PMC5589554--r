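# broom-style tidiers

#' Tidy a penalized logistic fit
#'
#' @param x A `lasso_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (all coefficients, including
#'   zeros, plus the intercept).
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$beta)),
                 estimate = c(x$intercept, unname(x$beta)))
}

#' @rdname tidy.lasso_fit
#' @return For `glance()`: one row with `lambda`, `nonzero`, `converged`,
#'   `iterations`, `n`.
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, nonzero = length(x$nonzero),
                 converged = x$converged, iterations = x$iterations,
                 n = x$n)
}

#' Tidy a cross-validated penalty path
#'
#' @param x A `lasso_path`.
#' @param ... Unused.
#' @return The path tibble (`lambda`, `cvm`, `cvse`, `nonzero`).
#' @export
tidy.lasso_path <- function(x, ...) x$path

#' @rdname tidy.lasso_path
#' @export
glance.lasso_path <- function(x, ...) {
  tibble::tibble(chosen_lambda = x$chosen_lambda, rule = x$rule,
                 folds = x$folds, seed = x$seed,
                 nonzero = length(x$fit$nonzero))
}

#' Tidy the three fitted risk models
#'
#' @param x A `risk_models` list from [fit_risk_models()].
#' @param ... Unused.
#' @return Tibble with `model`, `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `or`.
#' @export
tidy.risk_models <- function(x, ...) {
  rows <- lapply(c("epidemiologic", "genetic", "extended"), function(nm) {
    s <- summary(x[[nm]])$coefficients
    tibble::tibble(model = nm, term = rownames(s), estimate = s[, 1],
                   std_error = s[, 2], statistic = s[, 3],
                   p_value = s[, 4], or = exp(s[, 1]))
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.risk_models
#' @export
glance.risk_models <- function(x, ...) {
  rows <- lapply(c("epidemiologic", "genetic", "extended"), function(nm) {
    f <- x[[nm]]
    tibble::tibble(model = nm, null_deviance = f$null.deviance,
                   deviance = f$deviance, aic = f$aic,
                   separation = isTRUE(f$separation))
  })
  dplyr::bind_rows(rows)
}
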