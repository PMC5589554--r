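# internal helpers shared across modules

# evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so identical seeds give byte-identical results
with_local_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# derived sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k) %% 2147483629L)
}

# round-half-up to `digits` decimals (printed tables use half-up, R's
# round() is half-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

assert_binary_status <- function(status, arg = "status") {
  if (anyNA(status) || !all(status %in% c(0, 1))) {
    abort(sprintf("`%s` must be 0/1 with no missing values", arg))
  }
  if (length(unique(status)) < 2) {
    abort(sprintf("`%s` must contain both cases (1) and controls (0)", arg))
  }
  invisible(as.integer(status))
}

# genotype tibble -> numeric matrix (sample_id column dropped)
dosage_matrix <- function(genotypes) {
  stopifnot(is.data.frame(genotypes), "sample_id" %in% names(genotypes))
  m <- as.matrix(genotypes[setdiff(names(genotypes), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- genotypes$sample_id
  m
}

variant_ids <- function(genotypes) setdiff(names(genotypes), "sample_id")

`%||%` <- function(x, y) if (is.null(x)) y else x
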