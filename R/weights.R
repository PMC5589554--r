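#' Read a variant weight table
#'
#' Parses a per-variant weight/annotation table of the kind produced by a
#' penalized-regression fit on a case-control panel: one row per SNP with
#' identity (`rsid`, `position` as a 1-based `chr:pos` string), the allele
#' pair, minor-allele frequency, association odds ratio and the
#' non-negative score weight `beta`.
#'
#' Orientation convention: the printed odds ratio is taken per copy of
#' `allele_a` (whose frequency is the printed MAF). Rows with `or < 1` are
#' re-oriented so that the effect (risk) allele is `allele_b`: the effect
#' frequency becomes `1 - maf`, the OR and its CI are inverted, and the
#' `flipped` column records the change. After orientation every weight
#' counts risk alleles and all `beta` are non-negative.
#'
#' @param path Path to a TSV/CSV file. Defaults to the packaged 38-SNP
#'   lung-cancer panel (see [grs_weights()]).
#' @return A tibble with one row per variant: `rsid`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `effect_allele`, `effect_freq`, `maf`,
#'   `hwe_p`, `info`, `or`, `or_low`, `or_high`, `p_assoc`, `beta`,
#'   `starred`, `flipped`. `or`/CI columns are effect-allele oriented.
#' @export
read_weight_table <- function(path = grspipe_extdata("panel38_weights.tsv")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (!nrow(d)) abort("weight table is empty")
  if ("alleles" %in% names(d) && !all(c("allele_a", "allele_b") %in% names(d))) {
    parts <- strsplit(d$alleles, "/", fixed = TRUE)
    d$allele_a <- vapply(parts, `[`, "", 1)
    d$allele_b <- vapply(parts, `[`, "", 2)
  }
  req <- c("rsid", "position", "allele_a", "allele_b", "maf", "or", "beta")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    abort(sprintf("weight table missing required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d$rsid)) {
    abort(sprintf("duplicate rsid in weight table: %s",
                  paste(unique(d$rsid[duplicated(d$rsid)]), collapse = ", ")))
  }
  pp <- strsplit(d$position, ":", fixed = TRUE)
  d$chrom <- sub("^chr", "", vapply(pp, `[`, "", 1))
  d$pos <- as.integer(vapply(pp, `[`, "", 2))
  if (anyNA(d$pos)) abort("position must be 'chr:pos' with integer pos")
  for (col in c("hwe_p", "info", "or_low", "or_high", "p_assoc")) {
    if (!col %in% names(d)) d[[col]] <- NA_real_
  }
  if (!"starred" %in% names(d)) d$starred <- FALSE
  if (any(d$maf < 0 | d$maf > 0.5)) abort("MAF must lie in [0, 0.5]")
  if (any(d$beta < 0)) abort("beta must be non-negative (risk-allele oriented)")
  ok_ci <- is.na(d$or_low) | is.na(d$or_high) |
    (d$or_low <= d$or & d$or <= d$or_high)
  if (!all(ok_ci)) abort("or must lie within [or_low, or_high]")

  flip <- d$or < 1
  out <- tibble::tibble(
    rsid = d$rsid, chrom = d$chrom, pos = d$pos,
    allele_a = d$allele_a, allele_b = d$allele_b,
    effect_allele = ifelse(flip, d$allele_b, d$allele_a),
    effect_freq = ifelse(flip, 1 - d$maf, d$maf),
    maf = d$maf, hwe_p = d$hwe_p, info = d$info,
    or = ifelse(flip, 1 / d$or, d$or),
    or_low = ifelse(flip, 1 / d$or_high, d$or_low),
    or_high = ifelse(flip, 1 / d$or_low, d$or_high),
    p_assoc = d$p_assoc, beta = d$beta,
    starred = as.logical(d$starred), flipped = flip
  )
  out
}

#' Write a variant weight table
#'
#' Inverse of [read_weight_table()]: writes the table back in input
#' orientation (allele_a/allele_b with the printed-OR convention), at full
#' numeric precision, so that read/write round-trips exactly.
#'
#' @param weights Weight tibble from [read_weight_table()] or
#'   [as_weight_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  flip <- weights$flipped %||% rep(FALSE, nrow(weights))
  d <- tibble::tibble(
    rsid = weights$rsid,
    position = paste0("chr", weights$chrom, ":", weights$pos),
    allele_a = weights$allele_a,
    allele_b = weights$allele_b,
    maf = weights$maf,
    hwe_p = weights$hwe_p,
    or = ifelse(flip, 1 / weights$or, weights$or),
    or_low = ifelse(flip, 1 / weights$or_high, weights$or_low),
    or_high = ifelse(flip, 1 / weights$or_low, weights$or_high),
    p_assoc = weights$p_assoc,
    beta = weights$beta,
    starred = weights$starred %||% FALSE
  )
  readr::write_tsv(d, path)
  invisible(path)
}

#' The packaged 38-SNP lung-cancer weight panel
#'
#' Returns the packaged weight table for the 38-SNP lung-cancer genetic
#' risk score: per-SNP risk-allele weights (`beta`, all positive, range
#' 0.0075-0.0535) selected by LASSO-penalized logistic regression in a
#' Chinese case-control training set, together with each SNP's position,
#' alleles, control MAF, control HWE p-value, per-allele odds ratio with
#' 95% CI and association p-value. Effect alleles are oriented so every
#' weight counts risk alleles (see [read_weight_table()]).
#'
#' @return A 38-row weight tibble.
#' @export
grs_weights <- function() {
  read_weight_table(grspipe_extdata("panel38_weights.tsv"))
}

#' Packaged stratified case/control counts
#'
#' Case/control counts by score quartile for the published lung-cancer GRS
#' analysis: cohorts `training` (2,331/3,077), `testing` (1,937/1,984) and
#' `all` (4,268/5,061), each stratified by GRS quartile (`score = "grs"`)
#' and by the combined smoking + GRS score (`score = "smoke_grs"`).
#'
#' @return A tibble with columns `cohort`, `score`, `category` (0-3),
#'   `cases`, `controls`.
#' @export
strata_counts <- function() {
  d <- readr::read_tsv(grspipe_extdata("strata_counts.tsv"),
                       show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(d)
}

#' Packaged 90th-percentile high/low risk group counts
#'
#' @return A tibble with columns `group` (`low`/`high`), `cases`, `total`.
#' @export
highlow_counts <- function() {
  readr::read_tsv(grspipe_extdata("highlow_counts.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

grspipe_extdata <- function(file) {
  system.file("extdata", file, package = "grspipe", mustWork = TRUE)
}
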