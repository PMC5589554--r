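test_that("control-based quartiles split uniform controls 25/25/25/25", {
  sc <- tibble::tibble(sample_id = sprintf("S%03d", 1:140),
                       grs = c(1:100, seq(0.5, 100.5, length.out = 40)))
  ph <- tibble::tibble(sample_id = sc$sample_id,
                       status = rep(c(0L, 1L), c(100, 40)))
  qc <- quantile_categories(sc, ph, basis = "controls")
  ctrl_counts <- table(qc$category[ph$status == 0])
  expect_equal(unname(c(ctrl_counts)), c(25, 25, 25, 25))
  expect_equal(attr(qc, "cutpoints"),
               unname(quantile(1:100, c(0.25, 0.5, 0.75))))
})

test_that("a score exactly at the top cut point lands in the top category", {
  sc <- tibble::tibble(sample_id = sprintf("S%02d", 1:9),
                       grs = c(1, 2, 3, 4, 5, 6, 7, 8, 7))
  qc <- quantile_categories(sc, probs = c(0.25, 0.5, 0.75), basis = "all")
  q75 <- unname(quantile(sc$grs, 0.75))
  expect_equal(unique(qc$category[sc$grs == q75]), 3L)
  # [lower, upper): a score exactly at Q25 is in category 1, not 0
  q25 <- unname(quantile(sc$grs, 0.25))
  expect_true(all(qc$category[sc$grs == q25] == 1L))
})

test_that("category assignment is invariant under strictly increasing transforms", {
  set.seed(5)
  sc <- tibble::tibble(sample_id = sprintf("S%03d", 1:200),
                       grs = rnorm(200))
  ph <- tibble::tibble(sample_id = sc$sample_id,
                       status = rbinom(200, 1, 0.4))
  a <- quantile_categories(sc, ph)$category
  sc2 <- dplyr::mutate(sc, grs = exp(3 * grs) + 2)
  b <- quantile_categories(sc2, ph)$category
  expect_identical(a, b)
})

test_that("degenerate scores are rejected", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"), grs = c(1, 1, 1))
  expect_error(quantile_categories(sc, basis = "all"), "degenerate")
  expect_error(highlow_split(sc), "degenerate")
})

test_that("the 90th-percentile split puts one of ten distinct scores in the high group", {
  sc <- tibble::tibble(sample_id = sprintf("S%02d", 1:10), grs = 1:10)
  hl <- highlow_split(sc, prob = 0.90)
  expect_equal(sum(hl$group == "high"), 1)
  expect_equal(hl$group[10], "high")
  # boundary: a score equal to the cutoff is high ("GRS >= cutoff")
  expect_equal(attr(hl, "cutoff"), unname(quantile(1:10, 0.9)))
})

test_that("crude category ORs equal the cross-product ratio (panel counts check)", {
  counts <- tibble::tibble(category = c(0, 3), cases = c(251, 1060),
                           controls = c(775, 773))
  res <- category_or(counts)
  expect_equal(res$or[1], 1)
  expect_equal(res$or[2], (1060 * 775) / (251 * 773), tolerance = 1e-12)
  expect_equal(round_half_up(res$or[2], 2), 4.23)

  # symmetric null table
  nul <- category_or(tibble::tibble(category = 0:1, cases = c(10, 10),
                                    controls = c(10, 10)))
  expect_equal(nul$or[2], 1)
  expect_equal(nul$or_low[2] * nul$or_high[2], 1, tolerance = 1e-10)

  # any 2x2 matches a from-scratch logistic fit
  set.seed(8)
  for (i in 1:3) {
    cc <- matrix(sample(5:60, 4), 2)
    tab <- tibble::tibble(category = 0:1, cases = cc[, 1], controls = cc[, 2])
    res <- category_or(tab)
    y <- rep(c(1, 0, 1, 0), c(cc[1, 1], cc[1, 2], cc[2, 1], cc[2, 2]))
    x <- rep(c(0, 0, 1, 1), c(cc[1, 1], cc[1, 2], cc[2, 1], cc[2, 2]))
    fit <- glm(y ~ x, family = binomial())
    expect_equal(res$or[2], exp(unname(coef(fit)[2])), tolerance = 1e-6)
  }
})

test_that("zero cells get the Haldane-Anscombe correction with a flag", {
  counts <- tibble::tibble(category = 0:1, cases = c(10, 0),
                           controls = c(10, 12))
  res <- category_or(counts)
  expect_true(res$corrected[2])
  expect_equal(res$or[2], (0.5 * 10.5) / (12.5 * 10.5), tolerance = 1e-12)
  expect_error(category_or(tibble::tibble(category = 0:1, cases = c(0, 5),
                                          controls = c(10, 10))),
               "reference")
})

test_that("the trend test reduces to the two-level Wald test and gains power", {
  set.seed(9)
  # two categories: equals the single binary-predictor Wald p
  cat2 <- rep(0:1, each = 150)
  y2 <- rbinom(300, 1, plogis(-0.5 + 0.8 * cat2))
  p_trend <- trend_test(cat2, y2)
  fit <- glm(y2 ~ cat2, family = binomial())
  z <- coef(summary(fit))["cat2", "z value"]
  expect_equal(p_trend, 2 * pnorm(-abs(z)), tolerance = 1e-10)

  # strong ordered signal at n = 4000, OR 1.5 per category
  cat4 <- sample(0:3, 4000, replace = TRUE)
  y4 <- rbinom(4000, 1, plogis(-1.2 + log(1.5) * cat4))
  expect_lt(trend_test(cat4, y4), 1e-4)
  expect_error(trend_test(rep(1, 10), rep(c(0, 1), 5)), "categories")
})

test_that("stratified risk tables carry printed-style percentages and a trend p", {
  set.seed(10)
  n <- 2000
  grs <- rnorm(n, 1, 0.15)
  status <- rbinom(n, 1, plogis(-2 + 2.5 * grs))
  sc <- tibble::tibble(sample_id = sprintf("S%04d", 1:n), grs = grs)
  ph <- tibble::tibble(sample_id = sc$sample_id, status = status)
  st <- stratify_risk(sc, ph)
  expect_s3_class(st, "stratified_risk_table")
  expect_equal(sum(st$cases) + sum(st$controls), n)
  expect_equal(st$case_pct, round_half_up(100 * st$cases / sum(st$cases), 2))
  expect_equal(st$or[1], 1)
  # positive effect: case counts rise across categories, controls near-equal
  expect_true(all(diff(st$cases) > 0))
  expect_true(max(st$controls) - min(st$controls) <= 2)
  expect_lt(attr(st, "p_trend"), 1e-6)
  expect_equal(st$label[c(1, 4)], c("0 (< Q25)", "3 (>= Q75)"))

  # covariate adjustment is wired through
  ph$age <- rnorm(n, 60, 8)
  st_adj <- stratify_risk(sc, ph, adjust = "age")
  expect_equal(attr(st_adj, "adjustment"), "age")
  expect_false(identical(st$or, st_adj$or))
})

test_that("printed-percentage convention is round-half-up to 2 decimals", {
  expect_equal(round_half_up(100 * 1060 / 2331, 2), 45.47)
  expect_equal(round_half_up(100 * 775 / 3077, 2), 25.19)
  expect_equal(round_half_up(2.005, 2), 2.01)  # half-up, not banker's
})
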