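test_that("HWE exact test matches known configurations and the enumeration oracle", {
  # the perfect-HWE mode configuration: every configuration qualifies
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  # full heterozygote deficiency at intermediate frequency
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  # spot values against the independent enumeration oracle
  for (cc in list(c(3, 5, 12), c(10, 2, 1), c(0, 10, 0), c(7, 7, 7),
                  c(1, 0, 30))) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_enum_p(cc[1], cc[2], cc[3]), tolerance = 1e-12)
  }
  expect_equal(hwe_exact_test(3, 5, 12), 0.107236268527, tolerance = 1e-10)
  # monomorphic: single attainable configuration
  expect_equal(hwe_exact_test(20, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  # mid-p is strictly smaller, chi-square agrees roughly for large counts
  expect_lt(hwe_exact_test(300, 500, 200, midp = TRUE),
            hwe_exact_test(300, 500, 200))
  expect_equal(hwe_exact_test(300, 500, 200, method = "chisq"),
               hwe_exact_test(300, 500, 200), tolerance = 0.1)
})

test_that("control MAF folds the effect-allele frequency", {
  g <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                      v1 = c(2, 2, 0, 0, 0, 0),   # cases first two
                      v2 = c(0, 0, 2, 2, 2, 2),
                      v3 = c(1, 1, 0, 1, 1, 2))
  ph <- tibble::tibble(sample_id = g$sample_id,
                       status = c(1L, 1L, 0L, 0L, 0L, 0L))
  cm <- compute_control_maf(g, ph)
  expect_equal(cm$maf[cm$rsid == "v1"], 0)       # monomorphic ref in controls
  expect_equal(cm$maf[cm$rsid == "v2"], 0)       # monomorphic alt still MAF 0
  expect_equal(cm$freq[cm$rsid == "v2"], 1)
  expect_equal(cm$maf[cm$rsid == "v3"], 0.5)     # 4 / (2*4)
  expect_error(compute_control_maf(g, dplyr::mutate(ph, status = 1L)),
               "no controls")
})

test_that("composite LD r2 is squared Pearson correlation with NA for monomorphic", {
  x <- c(0, 1, 2, 0)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)   # perfect negative correlation
  x2 <- c(0, 1, 2, 1, 0); y2 <- c(0, 0, 2, 1, 1)
  expect_equal(ld_r2(x2, y2), 0.413265306122, tolerance = 1e-10)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_error(ld_r2(c(NA, 1), c(1, NA)), "at least 2")
})

test_that("QC filters fire in sequence and LD pruning keeps the most significant SNP", {
  set.seed(41)
  n <- 400
  status <- rep(c(1L, 0L), each = n / 2)
  base <- rbinom(n, 2, 0.3)
  dos <- cbind(
    v_info = rbinom(n, 2, 0.3),
    v_maf = rbinom(n, 2, 0.02),          # control MAF ~0.02 < 0.05
    v_hwe = sample(rep(c(0, 2), n / 2)), # no heterozygotes at freq 0.5
    v_keep = base,                        # LD pair, 100 bp apart
    v_prune = base
  )
  variants <- tibble::tibble(rsid = colnames(dos), chrom = "7",
                             pos = c(1e5, 2e5, 3e5, 5e5, 5e5 + 100),
                             info = c(0.7, 1, 1, 0.95, 0.99))
  co <- toy_cohort(dos, status, variants = variants)
  ap <- c(v_info = 0.5, v_maf = 0.5, v_hwe = 0.5, v_keep = 0.01,
          v_prune = 0.02)
  rep_ <- apply_qc(co, qc_thresholds(), assoc_p = ap)
  expect_s3_class(rep_, "qc_report")
  expect_equal(qc_keep(rep_), "v_keep")
  expect_equal(rep_$fail_rule[match(c("v_info", "v_maf", "v_hwe", "v_prune"),
                                    rep_$rsid)],
               c("info", "maf", "hwe", "ld"))
  sc <- attr(rep_, "stage_counts")
  expect_true(all(diff(sc) <= 0))
  expect_equal(unname(sc["input"]), 5)
  expect_equal(unname(sc["ld"]), 1)
  expect_equal(sum(rep_$pass) + sum(!rep_$pass), nrow(rep_))

  # vacuous thresholds keep everything (window 0 still prunes at distance 0;
  # use r2 threshold 1 on distinct columns)
  rep0 <- apply_qc(co, qc_thresholds(min_info = 0, min_maf = 0,
                                     min_hwe_p = 0, ld_r2 = 1,
                                     ld_window_bp = 0), assoc_p = ap)
  expect_equal(sort(qc_keep(rep0)), sort(colnames(dos)))
})

test_that("perfectly correlated variants outside the window both survive", {
  set.seed(7)
  base <- rbinom(300, 2, 0.4)
  dos <- cbind(far_a = base, far_b = base)
  variants <- tibble::tibble(rsid = colnames(dos), chrom = "2",
                             pos = c(1e6, 1e6 + 3e5), info = 1)
  co <- toy_cohort(dos, rep(c(1L, 0L), 150), variants = variants)
  rep_ <- apply_qc(co, qc_thresholds(min_maf = 0, min_hwe_p = 0),
                   assoc_p = c(far_a = 0.01, far_b = 0.02))
  expect_setequal(qc_keep(rep_), c("far_a", "far_b"))
})

test_that("pruning is stable under permutations of variant order", {
  set.seed(11)
  n <- 300
  h <- rbinom(n, 2, 0.4)
  dos <- cbind(a = h, b = h, c = rbinom(n, 2, 0.3),
               d = rbinom(n, 2, 0.2), e = h)
  variants <- tibble::tibble(rsid = colnames(dos), chrom = "3",
                             pos = c(1000, 2000, 3000, 4000, 5000), info = 1)
  ap <- c(a = 0.03, b = 0.01, c = 0.2, d = 0.4, e = 0.02)
  status <- rep(c(1L, 0L), n / 2)
  kept <- lapply(1:4, function(k) {
    set.seed(k)
    perm <- sample(colnames(dos))
    co <- toy_cohort(dos[, perm], status, variants = variants[match(perm, variants$rsid), ])
    sort(qc_keep(apply_qc(co, qc_thresholds(min_maf = 0, min_hwe_p = 0),
                          assoc_p = ap)))
  })
  expect_length(unique(kept), 1)
  expect_equal(kept[[1]], sort(c("b", "c", "d")))
})

test_that("a surviving variant without an association p is a hard error", {
  dos <- cbind(v1 = c(0, 1, 2, 1), v2 = c(2, 1, 0, 1))
  co <- toy_cohort(dos, c(1L, 1L, 0L, 0L))
  expect_error(apply_qc(co, qc_thresholds(min_maf = 0, min_hwe_p = 0),
                        assoc_p = c(v1 = 0.1)),
               "assoc_p missing.*v2")
})
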