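# Case-control cohort simulator: Hardy-Weinberg genotypes at specified
# risk-allele frequencies, optional LD blocks via a haplotype
# copy-with-mutation model, a binary smoking exposure, and disease status
# from an additive logistic model with the baseline solved so the
# population prevalence matches the requested value. Case-control sampling
# is by transparent rejection sampling from the population model.

#' Specify a simulated case-control cohort
#'
#' @param n_cases,n_controls Target sample counts.
#' @param variants Tibble with one row per SNP: `rsid`, `chrom`, `pos`,
#'   `effect_freq` (risk-allele frequency in (0, 1); 0/1 allowed for
#'   degenerate fixed columns), `or` (per-allele odds ratio > 0), optional
#'   `info` and `effect_allele`.
#' @param smoking_prev_controls Smoking prevalence to emulate among
#'   controls; under the rare-disease regime this is also (approximately)
#'   the population prevalence used by the generator. Default 0.5266.
#' @param smoking_or Per-exposure odds ratio for smoking. The default
#'   solves the control/case smoking rates 52.66% vs 76.85% under the
#'   rare-disease approximation: `exp(qlogis(0.7685) - qlogis(0.5266))`
#'   (about 2.98).
#' @param prevalence Population disease prevalence used to solve the
#'   baseline logit (default 0.01, rare-disease regime).
#' @param ld_blocks Optional list of blocks, each
#'   `list(rsids = c(...), r2 = target)`; block members are generated from
#'   a shared latent haplotype pair by copy-with-mutation tuned to the
#'   target composite r².
#' @param seed Integer seed; identical specs (including seed) reproduce
#'   byte-identical cohorts.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_cases, n_controls, variants,
                     smoking_prev_controls = 0.5266,
                     smoking_or = exp(qlogis(0.7685) - qlogis(0.5266)),
                     prevalence = 0.01, ld_blocks = NULL, seed = 1) {
  stopifnot(n_cases + n_controls > 0, n_cases >= 0, n_controls >= 0)
  req <- c("rsid", "effect_freq", "or")
  miss <- setdiff(req, names(variants))
  if (length(miss)) abort(sprintf("variants missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  if (any(variants$effect_freq < 0 | variants$effect_freq > 1)) {
    abort("effect_freq must lie in [0, 1]")
  }
  if (any(variants$or <= 0)) abort("per-allele ORs must be positive")
  if (!"chrom" %in% names(variants)) variants$chrom <- "1"
  if (!"pos" %in% names(variants)) variants$pos <- seq_len(nrow(variants))
  if (!"info" %in% names(variants)) variants$info <- 1
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 variants = tibble::as_tibble(variants),
                 smoking_prev_controls = smoking_prev_controls,
                 smoking_or = smoking_or, prevalence = prevalence,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Training-set simulation spec at the packaged panel's conditions
#'
#' Cohort of 2,331 cases and 3,077 controls with the packaged 38-SNP
#' panel's risk-allele frequencies and per-allele odds ratios as the
#' generating truth.
#'
#' @param seed Integer seed.
#' @param ... Passed on to [sim_spec()].
#' @return A `sim_spec`.
#' @export
sim_spec_training <- function(seed = 1, ...) {
  w <- grs_weights()
  sim_spec(2331, 3077,
           variants = tibble::tibble(rsid = w$rsid, chrom = w$chrom,
                                     pos = w$pos, effect_freq = w$effect_freq,
                                     or = w$or, info = 1,
                                     effect_allele = w$effect_allele),
           seed = seed, ...)
}

#' Testing-set simulation spec with perturbed allele frequencies
#'
#' Emulates an external validation cohort of 1,937 cases and 1,984
#' controls: per-allele effects are kept, but risk-allele frequencies are
#' jittered (Beta-distributed around the panel frequencies with
#' concentration `concentration`, seeded) to stand in for a population of
#' different ancestry. This synthetic stand-in makes external-validation
#' transfer testable; it does not claim any real cohort's frequencies.
#'
#' @param seed Integer seed.
#' @param concentration Beta concentration of the frequency jitter
#'   (larger = closer to the panel frequencies; default 100).
#' @param ... Passed on to [sim_spec()].
#' @return A `sim_spec`.
#' @export
sim_spec_testing <- function(seed = 2, concentration = 100, ...) {
  w <- grs_weights()
  f <- with_local_seed(derive_seed(seed, 77), {
    stats::rbeta(nrow(w), w$effect_freq * concentration,
                 (1 - w$effect_freq) * concentration)
  })
  f <- pmin(pmax(f, 0.02), 0.98)
  sim_spec(1937, 1984,
           variants = tibble::tibble(rsid = w$rsid, chrom = w$chrom,
                                     pos = w$pos, effect_freq = f,
                                     or = w$or, info = 1,
                                     effect_allele = w$effect_allele),
           seed = seed, ...)
}

# haplotype copy coefficient for a target composite r2 between the block
# anchor (freq p1) and a member (freq p2); errors when infeasible
ld_copy_coef <- function(r2, p1, p2) {
  # haplotype correlation of anchor (freq p1) and a member copied with
  # probability c: corr = c * p1 (1 - p2) / sqrt(p1 q1 p2 q2)
  corr_max <- p1 * (1 - p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  cc <- sqrt(r2) / corr_max
  if (cc > 1) {
    abort(sprintf("target r2 = %.3f infeasible for freqs (%.3f, %.3f); max attainable r2 = %.3f",
                  r2, p1, p2, min(1, corr_max^2)))
  }
  cc
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent variants are drawn as Binomial(2, effect_freq) per sample.
#' Variants grouped in an LD block share a latent haplotype pair: each
#' member copies the block anchor's haplotype alleles with a per-site
#' copy probability tuned to the target composite r², mutating to a fresh
#' Bernoulli draw otherwise.
#'
#' @param spec A `sim_spec`, or a variants tibble (`rsid`, `effect_freq`).
#' @param n Number of samples.
#' @param seed Seed; defaults to the spec's.
#' @return Genotype tibble (`sample_id` + one column per rsid) with a
#'   `"variants"` attribute.
#' @export
simulate_genotypes <- function(spec, n, seed = NULL) {
  v <- if (inherits(spec, "sim_spec")) spec$variants else tibble::as_tibble(spec)
  blocks <- if (inherits(spec, "sim_spec")) spec$ld_blocks else NULL
  seed <- seed %||% (if (inherits(spec, "sim_spec")) spec$seed else 1)
  with_local_seed(seed, simulate_genotypes_impl(v, blocks, n))
}

simulate_genotypes_impl <- function(v, blocks, n) {
  p <- v$effect_freq
  m <- matrix(0, nrow = n, ncol = nrow(v),
              dimnames = list(NULL, v$rsid))
  in_block <- character(0)
  for (b in blocks %||% list()) {
    idx <- match(b$rsids, v$rsid)
    if (anyNA(idx)) abort("ld_blocks name unknown rsid(s)")
    in_block <- c(in_block, b$rsids[-1])
    p1 <- p[idx[1]]
    h1 <- matrix(rbinom(2 * n, 1, p1), n, 2)   # anchor haplotypes
    m[, idx[1]] <- rowSums(h1)
    for (j in idx[-1]) {
      cc <- ld_copy_coef(b$r2, p1, p[j])
      keep <- matrix(runif(2 * n) < cc, n, 2)
      fresh <- matrix(rbinom(2 * n, 1, p[j]), n, 2)
      hj <- ifelse(keep, h1, fresh)
      m[, j] <- rowSums(hj)
    }
  }
  # remaining variants are independent
  done <- unlist(lapply(blocks %||% list(), function(b) b$rsids))
  if (is.null(done)) done <- character(0)
  for (j in which(!v$rsid %in% done)) {
    m[, j] <- rbinom(n, 2, p[j])
  }
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%06d", seq_len(n))),
    tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
  attr(out, "variants") <- v
  out
}

# solve the baseline logit so that the population mean of
# plogis(b0 + sum(log or * g) + log(or_smoke) * smoke) equals `prevalence`;
# Monte-Carlo expectation with a derived, fixed internal seed
solve_baseline <- function(spec, n_mc = 40000) {
  lo <- log(spec$variants$or)
  with_local_seed(derive_seed(spec$seed, 1), {
    g <- matrix(rbinom(n_mc * length(lo), 2,
                       rep(spec$variants$effect_freq, each = n_mc)), n_mc)
    eta_g <- drop(g %*% lo) +
      log(spec$smoking_or) * rbinom(n_mc, 1, spec$smoking_prev_controls)
    f <- function(b0) mean(plogis(b0 + eta_g)) - spec$prevalence
    uniroot(f, lower = -30, upper = 10, tol = 1e-10)$root
  })
}

#' Simulate a case-control cohort from a logistic disease model
#'
#' Draws genotypes and smoking from the population model, assigns disease
#' status from `logit P(case) = baseline + sum(log(or_i) g_i) +
#' log(or_smoke) smoke` with the baseline solved numerically for the
#' requested prevalence, and rejection-samples until the case and control
#' quotas are met. The truth record (spec, solved baseline, realized
#' frequencies and smoking rates) is attached as `$truth` and can be
#' serialized with [write_truth()].
#'
#' @param spec A `sim_spec`.
#' @param label Cohort label.
#' @return A [cohort_bundle()] with an extra `truth` element.
#' @export
simulate_cohort <- function(spec, label = "simulated") {
  stopifnot(inherits(spec, "sim_spec"))
  b0 <- solve_baseline(spec)
  p_case_max <- plogis(b0 + sum(pmax(log(spec$variants$or), 0) * 2) +
                         max(log(spec$smoking_or), 0))
  if (spec$n_cases > 0 && p_case_max < 1e-6) {
    abort("case quota unreachable: expected case probability < 1e-6")
  }
  lo <- log(spec$variants$or)
  ls <- log(spec$smoking_or)
  res <- with_local_seed(derive_seed(spec$seed, 2), {
    need_ca <- spec$n_cases; need_co <- spec$n_controls
    Gca <- list(); Gco <- list(); sca <- list(); sco <- list()
    guard <- 0
    while (need_ca > 0 || need_co > 0) {
      guard <- guard + 1
      if (guard > 2000) abort("rejection sampling failed to meet quotas")
      chunk <- max(5000, min(4e5, ceiling(
        (need_ca / max(spec$prevalence, 1e-6)) * 1.1 + need_co * 1.1)))
      g <- simulate_genotypes_impl(spec$variants, spec$ld_blocks, chunk)
      gm <- dosage_matrix(g)
      smoke <- rbinom(chunk, 1, spec$smoking_prev_controls)
      y <- rbinom(chunk, 1, plogis(b0 + drop(gm %*% lo) + ls * smoke))
      ica <- which(y == 1)
      ica <- ica[seq_len(min(length(ica), need_ca))]
      ico <- which(y == 0)
      ico <- ico[seq_len(min(length(ico), need_co))]
      if (length(ica)) {
        Gca[[length(Gca) + 1]] <- gm[ica, , drop = FALSE]
        sca[[length(sca) + 1]] <- smoke[ica]
        need_ca <- need_ca - length(ica)
      }
      if (length(ico)) {
        Gco[[length(Gco) + 1]] <- gm[ico, , drop = FALSE]
        sco[[length(sco) + 1]] <- smoke[ico]
        need_co <- need_co - length(ico)
      }
    }
    list(G = rbind(do.call(rbind, Gca), do.call(rbind, Gco)),
         smoke = c(unlist(sca), unlist(sco)),
         status = rep(1:0, c(spec$n_cases, spec$n_controls)))
  })
  ids <- sprintf("S%06d", seq_len(nrow(res$G)))
  genotypes <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids),
    tibble::as_tibble(as.data.frame(res$G, check.names = FALSE)))
  attr(genotypes, "variants") <- spec$variants
  phenotypes <- tibble::tibble(sample_id = ids,
                               status = as.integer(res$status),
                               smoking = as.integer(res$smoke))
  cohort <- cohort_bundle(genotypes, phenotypes,
                          variants = spec$variants, label = label)
  ctrl <- phenotypes$status == 0
  cohort$truth <- list(
    spec = spec, baseline_logit = b0,
    realized_freq_controls = colSums(res$G[ctrl, , drop = FALSE]) /
      (2 * sum(ctrl)),
    smoking_rate_controls = mean(res$smoke[ctrl]),
    smoking_rate_cases = if (any(!ctrl)) mean(res$smoke[!ctrl]) else NA_real_
  )
  cohort
}

#' Serialize a cohort's truth record as JSON
#'
#' @param cohort A simulated [cohort_bundle()] carrying `$truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  tr <- cohort$truth
  if (is.null(tr)) abort("cohort carries no truth record")
  out <- list(
    n_cases = tr$spec$n_cases, n_controls = tr$spec$n_controls,
    seed = tr$spec$seed, prevalence = tr$spec$prevalence,
    smoking_prev_controls = tr$spec$smoking_prev_controls,
    smoking_or = tr$spec$smoking_or,
    baseline_logit = tr$baseline_logit,
    smoking_rate_controls = tr$smoking_rate_controls,
    smoking_rate_cases = tr$smoking_rate_cases,
    variants = as.data.frame(tr$spec$variants),
    realized_freq_controls = as.list(tr$realized_freq_controls)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits `<prefix>.vcf.gz` (genotypes), `<prefix>_phenotypes.tsv` and,
#' when present, `<prefix>_truth.json`.
#'
#' @param cohort A [cohort_bundle()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  write_genotypes_vcf(cohort$genotypes, paste0(prefix, ".vcf.gz"),
                      variants = cohort$variants)
  readr::write_tsv(cohort$phenotypes, paste0(prefix, "_phenotypes.tsv"))
  if (!is.null(cohort$truth)) write_truth(cohort, paste0(prefix, "_truth.json"))
  invisible(prefix)
}
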