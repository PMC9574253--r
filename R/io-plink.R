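#' Read PLINK text PED/MAP files
#'
#' Parses the classic whitespace-delimited PED/MAP pair with base-coded
#' alleles ("0 0" = missing). The Alt allele is taken as the minor allele
#' observed at read time (ties broken alphabetically), so dosage counts
#' minor-allele copies; this orientation is recorded in the returned map.
#'
#' @param ped_path Path to the `.ped` file (6 leading columns then two
#'   allele columns per marker).
#' @param map_path Path to the `.map` file (chrom, marker id, cM, pos).
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4L) stop_format("MAP must have >= 4 columns")
  n_mark <- nrow(map_raw)

  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6L + 2L * n_mark) {
    stop_format("PED has ", ncol(ped), " columns; expected ",
                6L + 2L * n_mark, " for ", n_mark, " markers")
  }
  n_samp <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  if (any(is.na(a1) != is.na(a2))) {
    stop_format("half-missing genotypes (one allele '0') are not supported")
  }

  calls <- matrix(NA_integer_, n_samp, n_mark)
  ref <- alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    lev <- sort(unique(obs[!is.na(obs)]))
    if (length(lev) > 2L) {
      stop_format("marker ", map_raw[j, 2L], " has >2 alleles")
    }
    if (length(lev) == 0L) lev <- c("A", "A")  # fully missing marker
    if (length(lev) == 1L) lev <- c(lev, lev)
    counts <- c(sum(obs == lev[1L], na.rm = TRUE),
                sum(obs == lev[2L], na.rm = TRUE))
    # Alt = minor allele; ties go to the alphabetically first (lev is sorted).
    minor <- if (counts[2L] < counts[1L]) 2L else 1L
    alt[j] <- lev[minor]
    ref[j] <- lev[3L - minor]
    calls[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }

  genotype_matrix(
    calls,
    map = data.frame(marker_id = map_raw[, 2L], chrom = map_raw[, 1L],
                     pos = suppressWarnings(as.integer(map_raw[, 4L])),
                     ref = ref, alt = alt, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = ped[, 2L], stringsAsFactors = FALSE)
  )
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param geno A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_plink_text <- function(geno, ped_path, map_path) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0L,
               ifelse(is.na(map$pos), 0L, map$pos)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  n <- n_samples(geno)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- geno$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$alt, map$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$alt, map$ref))
    lines[i] <- paste(c(geno$samples$sample_id[i], geno$samples$sample_id[i],
                        "0", "0", "0", "-9", rbind(a1, a2)), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}
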