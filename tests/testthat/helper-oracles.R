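# independent oracles used across the suite; none share code with the
# implementation paths they check

# exact HWE p by direct enumeration of the conditional distribution using
# the closed-form log-factorial expression
hwe_enum_p <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  nb <- 2 * nbb + nab
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    a <- (na - h) / 2; b <- (nb - h) / 2
    lfactorial(na) + lfactorial(nb) + lfactorial(n) + h * log(2) -
      (lfactorial(a) + lfactorial(h) + lfactorial(b) + lfactorial(2 * n))
  }, 0)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  pobs <- pr[match(nab, hets)]
  min(sum(pr[pr <= pobs * (1 + 1e-9)]), 1)
}

# all-pairs concordance count (O(mn))
auc_brute <- function(score, status) {
  ca <- score[status == 1]; co <- score[status == 0]
  tot <- 0
  for (x in ca) tot <- tot + sum(x > co) + 0.5 * sum(x == co)
  tot / (length(ca) * length(co))
}

# FISTA (accelerated proximal gradient) for the same L1 logistic objective:
# (1/n) NLL + lambda * sum(|beta|), intercept unpenalized
fista_lasso_logistic <- function(X, y, lambda, iters = 20000) {
  n <- nrow(X)
  Xa <- cbind(1, X)
  L <- (svd(Xa, nu = 0, nv = 0)$d[1]^2) / (4 * n)
  th <- rep(0, ncol(Xa))
  z <- th; tt <- 1
  for (it in seq_len(iters)) {
    p <- plogis(drop(Xa %*% z))
    g <- -drop(crossprod(Xa, y - p)) / n
    u <- z - g / L
    th_new <- c(u[1], sign(u[-1]) * pmax(abs(u[-1]) - lambda / L, 0))
    tt_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    z <- th_new + ((tt - 1) / tt_new) * (th_new - th)
    th <- th_new; tt <- tt_new
  }
  list(intercept = unname(th[1]), beta = unname(th[-1]))
}

# paired sign-flip permutation p-value for an AUC difference
perm_auc_diff_p <- function(score_a, score_b, status, reps = 20000, seed = 1) {
  d_obs <- abs(auc_rank(score_a, status) - auc_rank(score_b, status))
  n <- length(status)
  hits <- 0
  set.seed(seed)
  for (r in seq_len(reps)) {
    swap <- runif(n) < 0.5
    sa <- ifelse(swap, score_b, score_a)
    sb <- ifelse(swap, score_a, score_b)
    if (abs(auc_rank(sa, status) - auc_rank(sb, status)) >= d_obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / reps
}

auc_rank <- function(score, status) {
  m <- sum(status == 1); n <- sum(status == 0)
  r <- rank(score)
  (sum(r[status == 1]) - m * (m + 1) / 2) / (m * n)
}

expect_kkt <- function(fit, X, y, tol = 1e-5) {
  kk <- check_kkt(fit, X, y, tol = tol)
  expect_true(kk$ok,
              label = sprintf("KKT violation %.3g within %g", kk$max_violation, tol))
}
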