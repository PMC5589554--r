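#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic SNP: given the observed genotype
#' counts, the number of heterozygotes is compared against its exact
#' conditional distribution given the allele totals. The two-sided p-value
#' is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration. Probabilities are evaluated by the standard stable
#' recurrence over heterozygote counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygous a/a, heterozygous,
#'   homozygous b/b). Must be non-negative with positive total.
#' @param method `"exact"` (default) or `"chisq"` for the 1-df chi-square
#'   goodness-of-fit test against expected Hardy-Weinberg proportions.
#' @param midp If `TRUE`, subtract half the observed configuration's
#'   probability (mid-p variant). Default `FALSE` (plain exact p).
#' @return p-value in (0, 1\].
#' @examples
#' hwe_exact_test(25, 50, 25) # perfect HWE at p = 0.5 -> 1
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq"),
                           midp = FALSE) {
  method <- match.arg(method)
  counts <- c(n_aa, n_ab, n_bb)
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0)) {
    abort("genotype counts must be three non-negative numbers")
  }
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")
  if (method == "chisq") {
    p <- (2 * n_aa + n_ab) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    stat <- sum((counts - e)^2 / e)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  na <- 2 * n_aa + n_ab     # a-allele count
  nb <- 2 * n_bb + n_ab
  rare <- min(na, nb)
  if (rare == 0) return(1)  # monomorphic: single attainable configuration
  # attainable heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # recurrence in log space: P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+1)(h+2))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    lp[k] <- lp[k - 1] + log(4 * haa * hbb) - log((h + 1) * (h + 2))
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- match(n_ab, hets)
  if (is.na(obs)) abort("observed heterozygote count inconsistent with allele totals")
  p_obs <- pr[obs]
  p <- sum(pr[pr <= p_obs * (1 + 1e-9)])
  if (midp) p <- p - p_obs / 2
  min(p, 1)
}

#' Genotype counts from hard-called dosages
#'
#' @param dosage Numeric dosages; values are rounded to \{0, 1, 2\} hard
#'   calls, missing values dropped.
#' @return Integer vector `c(n_ref_hom, n_het, n_alt_hom)` counting 0, 1
#'   and 2 effect-allele copies.
#' @export
genotype_counts <- function(dosage) {
  g <- round(dosage[!is.na(dosage)])
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Control minor-allele and effect-allele frequency per variant
#'
#' The effect-allele frequency in controls is
#' `f = sum(dosage) / (2 * n non-missing controls)`; the MAF is
#' `min(f, 1 - f)`.
#'
#' @param genotypes Genotype tibble.
#' @param phenotypes Phenotype tibble with `status` (0 = control).
#' @return A tibble with `rsid`, `freq` (effect-allele frequency in
#'   controls), `maf`, `n_controls` (non-missing).
#' @export
compute_control_maf <- function(genotypes, phenotypes) {
  ctrl_ids <- phenotypes$sample_id[phenotypes$status == 0]
  if (!length(ctrl_ids)) abort("no controls in phenotype table")
  m <- dosage_matrix(genotypes)[genotypes$sample_id %in% ctrl_ids, , drop = FALSE]
  nn <- colSums(!is.na(m))
  if (any(nn == 0)) {
    abort(sprintf("variant %s has no non-missing control genotypes",
                  colnames(m)[which(nn == 0)[1]]))
  }
  f <- colSums(m, na.rm = TRUE) / (2 * nn)
  tibble::tibble(rsid = colnames(m), freq = unname(f),
                 maf = unname(pmin(f, 1 - f)), n_controls = unname(nn))
}

#' Composite linkage-disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of the (unphased) allele dosages. When
#' either vector has zero variance across the jointly non-missing samples,
#' LD is undefined and `NA` is returned; pruning treats this as r² = 0, so
#' monomorphic variants never prune neighbours.
#'
#' @param x,y Numeric dosage vectors of equal length.
#' @return r² in \[0, 1\], or `NA` for undefined LD.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) abort("need at least 2 samples with both dosages non-missing")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Quality-control thresholds
#'
#' Defaults follow standard post-imputation GWAS screening: imputation
#' INFO >= 0.8, control MAF >= 0.05, control HWE exact p >= 0.05, and
#' windowed LD pruning at r² >= 0.5 within 200 kb.
#'
#' @param min_info,min_maf,min_hwe_p Fractions in \[0, 1\].
#' @param ld_r2 Pruning r² threshold in \[0, 1\].
#' @param ld_window_bp Pruning window in base pairs (> 0; pairs farther
#'   apart, or on different chromosomes, are never pruned).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.8, min_maf = 0.05, min_hwe_p = 0.05,
                          ld_r2 = 0.5, ld_window_bp = 200000L) {
  fr <- c(min_info = min_info, min_maf = min_maf, min_hwe_p = min_hwe_p,
          ld_r2 = ld_r2)
  if (any(fr < 0 | fr > 1)) abort("QC thresholds must be fractions in [0, 1]")
  if (ld_window_bp < 0) abort("ld_window_bp must be non-negative")
  structure(list(min_info = min_info, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, ld_r2 = ld_r2,
                 ld_window_bp = as.integer(ld_window_bp)),
            class = "qc_thresholds")
}

#' Apply variant quality control to a cohort
#'
#' Implements the screening sequence (all computed in controls):
#' imputation INFO, minor-allele frequency, exact Hardy-Weinberg test,
#' then greedy windowed LD pruning. Pruning processes surviving variants
#' in ascending association p-value (ties broken by chromosome, position,
#' rsid); a variant is dropped when it lies within `ld_window_bp` of an
#' already-kept variant on the same chromosome with r² at or above the
#' threshold — so of any LD cluster only the most significant SNP is kept.
#'
#' @param cohort A [cohort_bundle()].
#' @param thresholds A [qc_thresholds()] object.
#' @param assoc_p Named vector `rsid -> association p-value` used to order
#'   the pruning (e.g. from [assoc_scan()] or a published table). Required
#'   for every variant surviving the marginal filters.
#' @param info Optional named vector `rsid -> INFO`; defaults to the
#'   `info` column of the cohort's variant metadata. Variants with no INFO
#'   available pass the INFO rule.
#' @param hwe_method Passed to [hwe_exact_test()].
#' @return A tibble of class `qc_report`, one row per variant: `rsid`,
#'   `chrom`, `pos`, `info`, `control_maf`, `hwe_p`, `assoc_p`,
#'   `fail_rule` (`NA` if kept; otherwise the first failing rule among
#'   `info`, `maf`, `hwe`, `ld`), `pass`. Attribute `"stage_counts"` gives
#'   the number of variants surviving after each stage.
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds(), assoc_p,
                     info = NULL, hwe_method = "exact") {
  stopifnot(inherits(cohort, "cohort_bundle"))
  g <- cohort$genotypes
  ids <- variant_ids(g)
  vmeta <- cohort$variants
  if (is.null(vmeta) || !all(c("chrom", "pos") %in% names(vmeta))) {
    abort("apply_qc needs variant metadata (chrom, pos) on the cohort")
  }
  vmeta <- vmeta[match(ids, vmeta$rsid), ]
  if (is.null(info)) {
    info <- if ("info" %in% names(vmeta)) setNames(vmeta$info, vmeta$rsid) else NULL
  }
  infov <- if (is.null(info)) rep(NA_real_, length(ids)) else unname(info[ids])

  cm <- compute_control_maf(g, cohort$phenotypes)
  ctrl <- g$sample_id %in%
    cohort$phenotypes$sample_id[cohort$phenotypes$status == 0]
  m <- dosage_matrix(g)
  hwe <- vapply(seq_along(ids), function(j) {
    cc <- genotype_counts(m[ctrl, j])
    hwe_exact_test(cc[1], cc[2], cc[3], method = hwe_method)
  }, 0)

  ap <- if (missing(assoc_p) || is.null(assoc_p)) {
    rep(NA_real_, length(ids))
  } else unname(assoc_p[ids])
  rep_tbl <- tibble::tibble(
    rsid = ids, chrom = as.character(vmeta$chrom), pos = vmeta$pos,
    info = infov, control_maf = cm$maf[match(ids, cm$rsid)], hwe_p = hwe,
    assoc_p = ap, fail_rule = NA_character_
  )
  fail_info <- !is.na(rep_tbl$info) & rep_tbl$info < thresholds$min_info
  fail_maf <- rep_tbl$control_maf < thresholds$min_maf
  fail_hwe <- rep_tbl$hwe_p < thresholds$min_hwe_p
  rep_tbl$fail_rule[fail_hwe] <- "hwe"
  rep_tbl$fail_rule[fail_maf] <- "maf"
  rep_tbl$fail_rule[fail_info] <- "info"

  surv <- which(is.na(rep_tbl$fail_rule))
  n_info <- sum(!fail_info)
  n_maf <- sum(!fail_info & !fail_maf)
  n_marg <- length(surv)
  if (length(surv) && anyNA(rep_tbl$assoc_p[surv])) {
    abort(sprintf("assoc_p missing for surviving variant(s): %s",
                  paste(rep_tbl$rsid[surv][is.na(rep_tbl$assoc_p[surv])],
                        collapse = ", ")))
  }
  # greedy prune: ascending (assoc_p, chrom, pos, rsid)
  ord <- surv[order(rep_tbl$assoc_p[surv], rep_tbl$chrom[surv],
                    rep_tbl$pos[surv], rep_tbl$rsid[surv])]
  kept <- integer(0)
  for (j in ord) {
    pruned <- FALSE
    for (k in kept) {
      if (rep_tbl$chrom[j] == rep_tbl$chrom[k] &&
          abs(rep_tbl$pos[j] - rep_tbl$pos[k]) <= thresholds$ld_window_bp) {
        r2 <- ld_r2(m[, j], m[, k])
        if (!is.na(r2) && r2 >= thresholds$ld_r2) { pruned <- TRUE; break }
      }
    }
    if (pruned) rep_tbl$fail_rule[j] <- "ld" else kept <- c(kept, j)
  }
  rep_tbl$pass <- is.na(rep_tbl$fail_rule)
  attr(rep_tbl, "stage_counts") <- c(input = length(ids), info = n_info,
                                     maf = n_maf, hwe = n_marg,
                                     ld = length(kept))
  class(rep_tbl) <- c("qc_report", class(rep_tbl))
  rep_tbl
}

#' Variants kept by a QC report
#'
#' @param report A `qc_report` from [apply_qc()].
#' @return Character vector of passing rsids, in input order.
#' @export
qc_keep <- function(report) report$rsid[report$pass]

#' Serialize a QC report
#'
#' Writes the per-variant table as TSV and, alongside it, a one-line JSON
#' summary of the stage survival counts.
#'
#' @param report A `qc_report`.
#' @param path Output TSV path; the JSON summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(as.data.frame(report), path)
  jsonlite::write_json(as.list(attr(report, "stage_counts")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
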