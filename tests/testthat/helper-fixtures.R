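# Small in-code fixtures shared by the test files.

toy_geno <- function(calls, chrom = NULL, pos = NULL, breed = NULL,
                     location = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(calls))),
                        stringsAsFactors = FALSE)
  if (!is.null(breed)) samples$breed <- breed
  if (!is.null(location)) samples$location <- location
  genotype_matrix(
    calls,
    map = data.frame(marker_id = sprintf("m%03d", seq_len(m)),
                     chrom = chrom %||% rep("1", m),
                     pos = pos %||% seq(1000L, by = 1000L, length.out = m),
                     ref = "A", alt = "G", stringsAsFactors = FALSE),
    samples = samples, sort_markers = FALSE)
}

# Genotypes in exact HWE proportions for allele frequency p (n even
# multiples work best); deterministic composition, shuffled by index.
hwe_calls <- function(n, p) {
  n_aa <- round(n * (1 - p)^2)
  n_ab <- round(n * 2 * p * (1 - p))
  n_bb <- n - n_aa - n_ab
  rep(c(0L, 1L, 2L), times = c(n_aa, n_ab, n_bb))
}

write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampleA", "sampleB", "sampleC", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("2", "500", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "1/1", "0/0", sep = "\t")
  ), path)
  path
}
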