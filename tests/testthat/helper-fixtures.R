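# in-code fixtures

write_toy_vcf <- function(path, ids = c("v1", "v2"),
                          samples = c("A", "B", "C"),
                          gts = rbind(c("0/0", "0/1", "1/1"),
                                      c("0/1", "0/1", "0/0")),
                          ref = c("A", "C"), alt = c("G", "T"),
                          chrom = c("1", "1"), pos = c(100, 5000)) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  recs <- vapply(seq_along(ids), function(i) {
    paste(c(chrom[i], pos[i], ids[i], ref[i], alt[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, recs), path)
  path
}

# small deterministic cohort built by hand from dosage columns
toy_cohort <- function(dosages, status, smoking = NULL, variants = NULL,
                       label = "toy") {
  n <- nrow(dosages)
  ids <- sprintf("S%03d", seq_len(n))
  g <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                        tibble::as_tibble(as.data.frame(dosages,
                                                        check.names = FALSE)))
  ph <- tibble::tibble(sample_id = ids, status = as.integer(status))
  if (!is.null(smoking)) ph$smoking <- as.integer(smoking)
  if (is.null(variants)) {
    variants <- tibble::tibble(rsid = colnames(dosages), chrom = "1",
                               pos = seq_len(ncol(dosages)) * 1000L,
                               info = 1)
  }
  attr(g, "variants") <- variants
  cohort_bundle(g, ph, variants = variants, label = label)
}
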