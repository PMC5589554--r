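# L1-penalized logistic selection of the sparse GRS weight vector.
#
# The objective is (1/n) * negative log-likelihood + lambda * sum(|beta_j|)
# over penalized columns; the intercept and any unpenalized covariates are
# never shrunk. Predictors are left on the allele-count scale by default so
# each coefficient is a per-allele log-odds weight, directly usable in a
# weighted-sum risk score.

prep_design <- function(X, y) {
  if (is.data.frame(X)) {
    if ("sample_id" %in% names(X)) X <- X[setdiff(names(X), "sample_id")]
    X <- as.matrix(X)
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("design matrix contains missing values; impute first")
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("y must be binary 0/1 with both classes present")
  }
  if (nrow(X) != length(y)) abort("nrow(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, y = y)
}

#' Fit an L1-penalized logistic regression at a fixed penalty
#'
#' Minimizes the mean negative log-likelihood plus `lambda * sum(|beta|)`
#' over penalized columns by proximal Newton with coordinate descent.
#' Convergence is declared when the largest coefficient update in an outer
#' iteration falls below `tol`. The returned solution satisfies the
#' subgradient (KKT) stationarity conditions (see [check_kkt()]).
#'
#' @param X Numeric matrix or genotype tibble (a `sample_id` column is
#'   dropped); columns are predictors on their original scale.
#' @param y Binary 0/1 outcome with both classes present.
#' @param lambda Non-negative penalty. `lambda = 0` gives the unpenalized
#'   maximum-likelihood fit.
#' @param penalty_mask Logical vector, one per column; `FALSE` columns
#'   (e.g. covariates) are never shrunk. Default: all penalized.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default `1e-7`).
#' @param max_iter Maximum outer (quadratic-approximation) iterations.
#' @param init Optional list with `beta` and `intercept` warm start.
#' @return An object of class `lasso_fit`: list with named `beta`,
#'   `intercept`, `lambda`, `penalty_mask`, `nonzero` (named non-zero
#'   coefficients), `converged`, `iterations`, `n`.
#' @export
fit_lasso_logistic <- function(X, y, lambda, penalty_mask = NULL,
                               tol = 1e-7, max_iter = 250, init = NULL) {
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    abort("lambda must be a single non-negative number")
  }
  d <- prep_design(X, y)
  p <- ncol(d$X)
  mask <- penalty_mask %||% rep(TRUE, p)
  if (length(mask) != p) abort("penalty_mask length must match ncol(X)")
  b0 <- if (is.null(init)) qlogis(mean(d$y)) else init$intercept
  bstart <- if (is.null(init)) numeric(p) else init$beta
  # centre columns to decouple the intercept from the coefficients; the
  # penalized solution is centring-invariant, only the intercept shifts
  cm <- colMeans(d$X)
  Xc <- sweep(d$X, 2, cm)
  res <- cd_logistic_cpp(Xc, d$y, lambda, as.integer(mask), bstart,
                         b0 + sum(cm * bstart), tol, max_iter, 1000L)
  beta <- as.numeric(res$beta)
  # clamp float residue on coordinates the penalty holds at zero
  beta[mask & abs(beta) < 1e-10] <- 0
  beta <- setNames(beta, colnames(d$X))
  structure(list(beta = beta, intercept = res$intercept - sum(cm * beta),
                 lambda = lambda,
                 penalty_mask = mask,
                 nonzero = beta[beta != 0],
                 converged = res$converged, iterations = res$iterations,
                 n = nrow(d$X)),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit: lambda = %.5g, %d/%d non-zero, %sconverged>\n",
              x$lambda, length(x$nonzero), length(x$beta),
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Verify the KKT stationarity conditions of a penalized fit
#'
#' For the objective `(1/n) NLL + lambda * sum(|beta_j|)` the stationarity
#' conditions are `|score_j| <= lambda` for zero coefficients and
#' `score_j = lambda * sign(beta_j)` for non-zero ones, where
#' `score_j = (1/n) sum_i x_ij (y_i - p_i)`. Unpenalized columns must have
#' `score_j = 0`.
#'
#' @param fit A `lasso_fit`.
#' @param X,y The data the fit was computed on.
#' @param tol Violation tolerance (default `1e-5`).
#' @return A list with `ok` (logical) and `max_violation`.
#' @export
check_kkt <- function(fit, X, y, tol = 1e-5) {
  d <- prep_design(X, y)
  eta <- fit$intercept + drop(d$X %*% fit$beta)
  score <- drop(crossprod(d$X, d$y - plogis(eta))) / nrow(d$X)
  viol <- numeric(length(score))
  pen <- fit$penalty_mask
  nz <- fit$beta != 0
  viol[pen & nz] <- abs(score[pen & nz] -
                          fit$lambda * sign(fit$beta[pen & nz]))
  viol[pen & !nz] <- pmax(abs(score[pen & !nz]) - fit$lambda, 0)
  viol[!pen] <- abs(score[!pen])
  # intercept stationarity
  v0 <- abs(mean(d$y - plogis(eta)))
  mv <- max(c(viol, v0))
  list(ok = mv <= tol, max_violation = mv)
}

#' Smallest penalty that zeroes every penalized coefficient
#'
#' @inheritParams fit_lasso_logistic
#' @return `max_j |(1/n) sum_i x_ij (y_i - p_i)|` over penalized columns,
#'   with `p` from the null model (intercept plus any unpenalized
#'   covariates).
#' @export
lambda_max <- function(X, y, penalty_mask = NULL) {
  d <- prep_design(X, y)
  p <- ncol(d$X)
  mask <- penalty_mask %||% rep(TRUE, p)
  if (all(mask)) {
    mu <- rep(mean(d$y), nrow(d$X))
  } else {
    df <- data.frame(y = d$y, d$X[, !mask, drop = FALSE])
    mu <- predict(glm(y ~ ., data = df, family = binomial()),
                  type = "response")
  }
  max(abs(drop(crossprod(d$X[, mask, drop = FALSE], d$y - mu))) / nrow(d$X))
}

#' Choose the penalty by stratified cross-validated deviance
#'
#' Builds a log-spaced penalty path from [lambda_max()] down four decades
#' and evaluates mean held-out binomial deviance by stratified k-fold
#' cross-validation (fold assignment is a pure function of `seed` and the
#' sample order). `rule = "cv_min"` picks the deviance-minimizing penalty;
#' `"cv_1se"` (default) the largest penalty whose CV deviance is within
#' one standard error of the minimum.
#'
#' @inheritParams fit_lasso_logistic
#' @param folds Number of cross-validation folds (>= 2; each fold must
#'   hold at least 10 samples and both classes).
#' @param rule `"cv_1se"` or `"cv_min"`.
#' @param seed Integer seed controlling the fold assignment.
#' @param nlambda Number of path points.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest.
#' @return An object of class `lasso_path`: list with the path tibble
#'   (`lambda`, `cvm`, `cvse`, `nonzero`), `chosen_lambda`, `rule`,
#'   `seed`, `folds`, and `fit`, the full-data [fit_lasso_logistic()] fit
#'   at the chosen penalty.
#' @export
select_lambda <- function(X, y, folds = 10, rule = c("cv_1se", "cv_min"),
                          seed = 1, nlambda = 50, lambda_min_ratio = 1e-4,
                          penalty_mask = NULL, tol = 1e-7) {
  rule <- match.arg(rule)
  d <- prep_design(X, y)
  n <- nrow(d$X)
  if (folds < 2) abort("folds must be >= 2")
  if (n / folds < 10) abort("need at least 10 samples per fold")
  if (min(sum(d$y == 1), sum(d$y == 0)) < folds) {
    abort("too few samples in one class to stratify across folds")
  }
  lmax <- lambda_max(d$X, d$y, penalty_mask)
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
  fold <- integer(n)
  with_local_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(d$y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  dev <- matrix(NA_real_, folds, nlambda)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- d$X[tr, , drop = FALSE]; ytr <- d$y[tr]
    Xte <- d$X[!tr, , drop = FALSE]; yte <- d$y[!tr]
    init <- NULL
    for (k in seq_len(nlambda)) {
      fit <- fit_lasso_logistic(Xtr, ytr, lambda[k],
                                penalty_mask, tol = tol, init = init)
      init <- list(beta = unname(fit$beta), intercept = fit$intercept)
      eta <- fit$intercept + drop(Xte %*% fit$beta)
      pr <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
      dev[f, k] <- -2 * mean(yte * log(pr) + (1 - yte) * log(1 - pr))
    }
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(folds)
  imin <- which.min(cvm)
  ichosen <- if (rule == "cv_min") imin else
    min(which(cvm <= cvm[imin] + cvse[imin]))
  # full-data path (warm-started) for sparsity profile + chosen fit
  nonzero <- integer(nlambda)
  init <- NULL
  chosen_fit <- NULL
  for (k in seq_len(nlambda)) {
    fit <- fit_lasso_logistic(d$X, d$y, lambda[k], penalty_mask, tol = tol,
                              init = init)
    init <- list(beta = unname(fit$beta), intercept = fit$intercept)
    nonzero[k] <- length(fit$nonzero)
    if (k == ichosen) chosen_fit <- fit
  }
  structure(list(
    path = tibble::tibble(lambda = lambda, cvm = cvm, cvse = cvse,
                          nonzero = nonzero),
    chosen_lambda = lambda[ichosen], chosen_index = ichosen,
    rule = rule, seed = seed, folds = folds, fit = chosen_fit
  ), class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path: %d lambdas, rule %s -> lambda = %.5g (%d non-zero)>\n",
              nrow(x$path), x$rule, x$chosen_lambda,
              length(x$fit$nonzero)))
  invisible(x)
}

#' Convert a penalized fit into a weight table
#'
#' Extracts the non-zero coefficients of a `lasso_fit` (or the chosen fit
#' of a `lasso_path`) as a weight table of the same shape as the packaged
#' panel, so that [compute_grs()] consumes a fresh fit and the packaged
#' fixture interchangeably.
#'
#' @param fit A `lasso_fit` or `lasso_path`.
#' @param variants Optional variant metadata (`rsid`, `chrom`, `pos`,
#'   `effect_allele`, ...) merged onto the selected SNPs.
#' @return A weight tibble with at least `rsid` and `beta` (only non-zero,
#'   non-negative weights; negatively weighted columns are re-oriented to
#'   the opposite allele when allele metadata is available).
#' @export
as_weight_table <- function(fit, variants = NULL) {
  if (inherits(fit, "lasso_path")) fit <- fit$fit
  stopifnot(inherits(fit, "lasso_fit"))
  nz <- fit$nonzero
  out <- tibble::tibble(rsid = names(nz), beta = unname(nz),
                        effect_allele = NA_character_, flipped = FALSE)
  if (!is.null(variants)) {
    v <- variants[match(out$rsid, variants$rsid), ]
    out$chrom <- v$chrom
    out$pos <- v$pos
    if ("effect_allele" %in% names(v)) out$effect_allele <- v$effect_allele
    if ("effect_freq" %in% names(v)) out$effect_freq <- v$effect_freq
  }
  neg <- out$beta < 0
  out$count_complement <- neg
  if (any(neg)) {
    # a negative per-allele weight means the opposite allele carries risk;
    # count_complement tells the scorer to count 2 - dosage there
    out$beta[neg] <- -out$beta[neg]
    out$flipped[neg] <- TRUE
    if ("effect_freq" %in% names(out)) {
      out$effect_freq[neg] <- 1 - out$effect_freq[neg]
    }
    out$effect_allele[neg] <- NA_character_
    warn(sprintf("%d coefficient(s) re-oriented to the risk allele", sum(neg)))
  }
  out
}
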