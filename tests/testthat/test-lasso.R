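make_lasso_instance <- function(seed = 1, n = 500, p = 10, k = 3,
                                effect = 0.5) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.5)[rep(1:p, each = n)]),
              n, p, dimnames = list(NULL, paste0("s", 1:p)))
  b <- c(rep(effect, k), rep(0, p - k))
  y <- rbinom(n, 1, plogis(-0.5 + X %*% b))
  list(X = X, y = y, beta_true = b)
}

test_that("at or above lambda_max every penalized coefficient is exactly zero", {
  inst <- make_lasso_instance(1)
  lm <- lambda_max(inst$X, inst$y)
  for (lam in c(lm, lm * 1.5)) {
    fit <- fit_lasso_logistic(inst$X, inst$y, lam)
    expect_identical(unname(fit$beta), rep(0, ncol(inst$X)))
    expect_kkt(fit, inst$X, inst$y)
  }
  fit <- fit_lasso_logistic(inst$X, inst$y, lm * 0.9)
  expect_gt(length(fit$nonzero), 0)
})

test_that("lambda = 0 recovers the unpenalized IRLS maximum likelihood fit", {
  inst <- make_lasso_instance(2)
  fit <- fit_lasso_logistic(inst$X, inst$y, 0)
  ml <- glm(inst$y ~ inst$X, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ml)[-1]), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(coef(ml)[1]), tolerance = 1e-5)
  expect_kkt(fit, inst$X, inst$y)
})

test_that("fixed-lambda solutions match the proximal-gradient oracle and glmnet", {
  inst <- make_lasso_instance(3)
  lam <- lambda_max(inst$X, inst$y) * 0.2
  fit <- fit_lasso_logistic(inst$X, inst$y, lam)
  expect_kkt(fit, inst$X, inst$y)

  oracle <- fista_lasso_logistic(inst$X, inst$y, lam, iters = 20000)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-4)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)

  gl <- glmnet::glmnet(inst$X, inst$y, family = "binomial", alpha = 1,
                       lambda = lam, standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$beta), as.numeric(gl$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(gl$a0), tolerance = 1e-4)
})

test_that("unpenalized covariates are never shrunk", {
  inst <- make_lasso_instance(4)
  mask <- c(FALSE, rep(TRUE, ncol(inst$X) - 1))
  lam <- lambda_max(inst$X, inst$y, penalty_mask = mask)
  fit <- fit_lasso_logistic(inst$X, inst$y, lam * 1.2, penalty_mask = mask)
  expect_true(all(fit$beta[-1] == 0))
  expect_true(fit$beta[1] != 0)   # the unpenalized (truly associated) column
  expect_kkt(fit, inst$X, inst$y)
})

test_that("invalid inputs error", {
  inst <- make_lasso_instance(5)
  expect_error(fit_lasso_logistic(inst$X, inst$y, -1), "non-negative")
  expect_error(fit_lasso_logistic(inst$X, rep(2, length(inst$y)), 0.1),
               "binary")
  expect_error(fit_lasso_logistic(inst$X, rep(1, length(inst$y)), 0.1),
               "binary")
})

test_that("cross-validated selection is deterministic given its seed", {
  inst <- make_lasso_instance(6, n = 300, p = 8)
  a <- select_lambda(inst$X, inst$y, folds = 5, seed = 99, nlambda = 25)
  b <- select_lambda(inst$X, inst$y, folds = 5, seed = 99, nlambda = 25)
  expect_identical(a$chosen_lambda, b$chosen_lambda)
  expect_identical(a$fit$beta, b$fit$beta)
  expect_identical(a$path, b$path)
})

test_that("the sparsity profile is monotone along decreasing lambda", {
  inst <- make_lasso_instance(7, n = 400, p = 15, k = 5)
  sel <- select_lambda(inst$X, inst$y, folds = 5, seed = 1, nlambda = 40)
  nz <- sel$path$nonzero
  frac_monotone <- mean(diff(nz) >= 0)
  expect_gte(frac_monotone, 0.95)
})

test_that("cv_1se keeps near-empty models under the null and finds a dominant effect", {
  null_sizes <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 300; p <- 10
    X <- matrix(rbinom(n * p, 2, 0.3), n, p,
                dimnames = list(NULL, paste0("s", 1:p)))
    y <- rbinom(n, 1, 0.45)
    sel <- select_lambda(X, y, folds = 5, rule = "cv_1se", seed = s,
                         nlambda = 30)
    length(sel$fit$nonzero)
  }, 0L)
  expect_gte(sum(null_sizes <= 2), 18)

  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 2000; p <- 8
    X <- matrix(rbinom(n * p, 2, 0.3), n, p,
                dimnames = list(NULL, paste0("s", 1:p)))
    y <- rbinom(n, 1, plogis(-1 + log(3) * X[, 1]))
    sel <- select_lambda(X, y, folds = 5, rule = "cv_1se", seed = s,
                         nlambda = 30)
    "s1" %in% names(sel$fit$nonzero)
  }, NA)
  expect_gte(sum(hits), 19)
})

test_that("cross-validation preconditions are enforced", {
  inst <- make_lasso_instance(8, n = 60)
  expect_error(select_lambda(inst$X, inst$y, folds = 1), "folds")
  expect_error(select_lambda(inst$X, inst$y, folds = 10), "10 samples")
  y_rare <- c(rep(1, 3), rep(0, 57))
  expect_error(select_lambda(inst$X, y_rare, folds = 5), "stratify")
})

test_that("weight-table export mirrors the fixture shape and re-orients negatives", {
  inst <- make_lasso_instance(9)
  lam <- lambda_max(inst$X, inst$y) * 0.3
  fit <- fit_lasso_logistic(inst$X, inst$y, lam)
  v <- tibble::tibble(rsid = colnames(inst$X), chrom = "1",
                      pos = seq_len(ncol(inst$X)),
                      effect_allele = "G", effect_freq = 0.3)
  expect_warning(w <- as_weight_table(fit, variants = v), "re-oriented")
  expect_true(all(c("rsid", "beta", "effect_allele") %in% names(w)))
  expect_true(all(w$beta >= 0))
  expect_setequal(w$rsid, names(fit$nonzero))
  # a re-oriented weight scores 2 - dosage: scoring respects the flag
  g <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("S%03d",
                                                           1:nrow(inst$X))),
                        tibble::as_tibble(as.data.frame(inst$X * 1.0)))
  sc <- compute_grs(g, w)
  M <- inst$X[, w$rsid, drop = FALSE]
  M[, w$count_complement] <- 2 - M[, w$count_complement]
  expect_equal(sc$grs, drop(M %*% w$beta), tolerance = 1e-12)
})
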