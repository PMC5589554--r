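test_that("AUC equals hand-enumerated and brute-force concordance", {
  # perfectly separating scores
  expect_equal(auc_ci(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # exhaustive pair enumeration: cases (0.9, 0.4), controls (0.5, 0.3)
  expect_equal(auc_ci(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))$auc, 0.75)
  # random scores vs the O(n^2) oracle, with ties
  set.seed(14)
  s <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)
  y <- rbinom(200, 1, 0.4)
  expect_equal(auc_ci(s, y)$auc, auc_brute(s, y), tolerance = 1e-12)
  expect_error(auc_ci(s, rep(1, 200)), "both cases")
})

test_that("AUC is invariant under strictly increasing transforms and agrees with pROC", {
  set.seed(15)
  s <- rnorm(150)
  y <- rbinom(150, 1, plogis(s))
  a1 <- auc_ci(s, y)
  a2 <- auc_ci(exp(2 * s) + 7, y)
  expect_equal(a1$auc, a2$auc)
  expect_equal(a1$se, a2$se)
  # cross-check point estimate, DeLong variance and CI against pROC
  r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(a1$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(sqrt(pROC::var(r, method = "delong")), a1$se,
               tolerance = 1e-10)
  expect_equal(a1$auc_low, max(0, ci[1]), tolerance = 1e-8)
  expect_equal(a1$auc_high, min(1, ci[3]), tolerance = 1e-8)
})

test_that("paired AUC comparison is degenerate-safe and transform-invariant", {
  set.seed(16)
  s <- rnorm(80)
  y <- rbinom(80, 1, plogis(s))
  self <- compare_auc(s, s, y)
  expect_equal(self$diff, 0)
  expect_equal(self$p_value, 1)
  expect_true(self$degenerate)
  mono <- compare_auc(plogis(3 * s) + 1, s, y)
  expect_equal(mono$diff, 0)
  expect_true(mono$degenerate)
})

test_that("paired AUC comparison matches pROC's DeLong test", {
  set.seed(17)
  n <- 120
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  sa <- x + 0.5 * z
  sb <- x - 0.3 * z
  ours <- compare_auc(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(ours$diff, as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-12)
})

test_that("adding pure noise to a predictor rarely 'improves' AUC significantly", {
  set.seed(18)
  rej <- 0
  for (r in 1:200) {
    n <- 150
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(x))
    p <- compare_auc(x + 0.3 * rnorm(n), x, y)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 200, 0.10)
})

test_that("Hosmer-Lemeshow matches hand arithmetic and is exact under perfect calibration", {
  # two groups, hand-computable
  pr <- rep(c(0.2, 0.6), each = 50)
  set.seed(19)
  y <- rbinom(100, 1, pr)
  hl <- hosmer_lemeshow(pr, y, groups = 2)
  o <- tapply(y, rep(1:2, each = 50), sum)
  e <- c(10, 30)
  stat_hand <- sum((o - e)^2 / (e * (1 - e / 50)))
  expect_equal(hl$statistic, stat_hand, tolerance = 1e-10)

  # predicted equal to group event rates: statistic 0, p = 1
  y2 <- rep(c(1, 0, 1, 0), c(2, 8, 6, 4))
  pr2 <- rep(c(0.2, 0.6), each = 10)
  # jitter within groups so deciles still form but rates stay exact
  hl2 <- hosmer_lemeshow(pr2, y2, groups = 2)
  expect_equal(hl2$statistic, 0)
  expect_equal(hl2$p_value, 1)

  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "strictly")
  expect_error(hosmer_lemeshow(pr, y, groups = 1), ">= 2")
})

test_that("risk models require variation and recover generator effects", {
  set.seed(20)
  n <- 2500
  smoking <- rbinom(n, 1, 0.5)
  grs <- rnorm(n, 1, 0.15)
  y <- rbinom(n, 1, plogis(-2.4 + log(3) * smoking + 1.5 * grs))
  ph <- tibble::tibble(sample_id = sprintf("S%04d", 1:n),
                       status = y, smoking = smoking)
  sc <- tibble::tibble(sample_id = ph$sample_id, grs = grs)
  fits <- fit_risk_models(ph, sc)
  td <- tidy(fits)
  or_smoke <- td$or[td$model == "epidemiologic" & td$term == "smoking"]
  expect_gt(or_smoke, 2.3)
  expect_lt(or_smoke, 3.9)
  expect_s3_class(glance(fits), "tbl_df")

  ph$smoking <- 1L
  expect_error(fit_risk_models(ph, sc), "smoking is constant")
})

test_that("evaluate_models emits the three-model report with ROC data", {
  set.seed(22)
  n <- 800
  smoking <- rbinom(n, 1, 0.5)
  grs <- rnorm(n, 1, 0.15)
  y <- rbinom(n, 1, plogis(-2 + 1 * smoking + 1.2 * grs))
  ph <- tibble::tibble(sample_id = sprintf("S%04d", 1:n), status = y,
                       smoking = smoking)
  sc <- tibble::tibble(sample_id = ph$sample_id, grs = grs)
  ev <- evaluate_models(ph, sc)
  expect_s3_class(ev, "eval_report")
  expect_equal(ev$model, c("epidemiologic", "genetic", "extended"))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_true(all(ev$auc_low <= ev$auc & ev$auc <= ev$auc_high))
  expect_true(is.na(ev$p_vs_epidemiologic[1]))
  expect_false(anyNA(ev$p_vs_epidemiologic[-1]))
  # the extended model contains both signals: best AUC
  expect_equal(which.max(ev$auc), 3L)
  roc <- attr(ev, "roc")
  expect_setequal(unique(roc$model), ev$model)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
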