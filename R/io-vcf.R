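#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts diploid `GT` calls to
#' Alt-allele dosages (0/1/2; `./.` becomes `NA`). Only biallelic SNP
#' records are usable; others are skipped with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param strict Error instead of skipping multi-allelic / non-SNP records.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_format("malformed VCF: ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_format("VCF contains no variant records")

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    if (strict) stop_format(sum(!snp), " multi-allelic or non-SNP records present")
    warning(sum(!snp), " multi-allelic or non-SNP records skipped")
  }

  gt <- vcfR::extract.gt(v, element = "GT")  # markers x samples
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop_validation("duplicate marker ids in VCF")

  alleles <- gsub("[|]", "/", gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- known[alleles]
  dose[] <- hit
  calls <- t(dose)

  genotype_matrix(
    calls,
    map = data.frame(marker_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  )
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Deterministic plain-text writer: fixed header, markers in map order,
#' unphased `GT`-only genotypes, missing calls as `./.`.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  calls <- geno$calls
  body <- vapply(seq_len(n_markers(geno)), function(j) {
    g <- calls[, j]
    gs <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    m <- geno$map[j, ]
    paste(c(m$chrom, ifelse(is.na(m$pos), ".", m$pos), m$marker_id,
            m$ref, m$alt, ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ovitherm",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples$sample_id), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
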