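#' Per-marker allele statistics
#'
#' @param geno A [genotype_matrix()].
#' @return Data frame with one row per marker: `marker_id`, `alt_freq`,
#'   `maf`, `call_rate`, plus genotype counts `n_rr`, `n_ra`, `n_aa`
#'   (Ref-hom, het, Alt-hom). Markers with no calls get `call_rate` 0,
#'   `maf`/`alt_freq` 0 and `degenerate = TRUE`.
#' @export
allele_stats <- function(geno) {
  calls <- geno$calls
  n <- nrow(calls)
  n_obs <- colSums(!is.na(calls))
  alt_count <- colSums(calls, na.rm = TRUE)
  alt_freq <- ifelse(n_obs > 0, alt_count / (2 * n_obs), 0)
  data.frame(
    marker_id = geno$map$marker_id,
    alt_freq = alt_freq,
    maf = pmin(alt_freq, 1 - alt_freq),
    call_rate = n_obs / n,
    n_rr = colSums(calls == 0L, na.rm = TRUE),
    n_ra = colSums(calls == 1L, na.rm = TRUE),
    n_aa = colSums(calls == 2L, na.rm = TRUE),
    degenerate = n_obs == 0L,
    stringsAsFactors = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test for a biallelic marker: given the
#' observed allele counts, the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count. Probabilities follow the classic recurrence on
#' the number of heterozygotes, evaluated in log space. The mid-p variant
#' halves the contribution of the observed outcome.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (either homozygote first; the
#'   test is symmetric in allele labels).
#' @param midp Use the mid-p variant.
#' @return The p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_validation("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop_validation("need at least one genotype")
  n1 <- 2 * min(n_aa, n_bb) + n_ab          # copies of the rarer allele
  if (n1 == 0) return(1)                    # monomorphic: single outcome

  hets <- seq.int(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logp <- .hwe_log_probs(n, n1, hets)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)

  obs <- probs[match(n_ab, hets)]
  p <- sum(probs[probs <= obs * (1 + 1e-10)])
  if (midp) p <- p - obs / 2
  min(1, p)
}

# Log conditional probabilities (up to a constant) of heterozygote counts
# `hets`, given n genotypes and n1 copies of the rarer allele:
# P(h) propto n1! n2! n! 2^h / (((n1-h)/2)! h! ((n2-h)/2)! ... ) --
# evaluated via lgamma.
.hwe_log_probs <- function(n, n1, hets) {
  n2 <- 2 * n - n1
  hets * log(2) - lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial((n2 - hets) / 2)
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' Removes markers with minor allele frequency below `maf_min`, call rate
#' below `callrate_min`, or exact HWE p-value below `hwe_alpha`. All three
#' criteria are evaluated on the input matrix (the retained set is
#' order-independent); for reporting, each removed marker is attributed to
#' the first criterion it fails in the order MAF, call rate, HWE.
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min,callrate_min,hwe_alpha Thresholds (defaults 0.01, 0.90,
#'   1e-6).
#' @param hwe_midp Use the mid-p exact HWE variant.
#' @return List with the filtered `geno` and a `report` (class
#'   `qc_report`): totals plus a per-marker table of `maf`, `call_rate`,
#'   `hwe_p` and `verdict` (`pass`/`fail_maf`/`fail_callrate`/`fail_hwe`).
#' @export
filter_snps <- function(geno, maf_min = 0.01, callrate_min = 0.90,
                        hwe_alpha = 1e-6, hwe_midp = FALSE) {
  assert_scalar_number(maf_min, "maf_min", 0, 1)
  assert_scalar_number(callrate_min, "callrate_min", 0, 1)
  assert_scalar_number(hwe_alpha, "hwe_alpha", 0, 1)

  st <- allele_stats(geno)
  hwe_p <- mapply(function(a, h, b) {
    if (a + h + b == 0) return(1)
    hwe_exact_test(a, h, b, midp = hwe_midp)
  }, st$n_rr, st$n_ra, st$n_aa)

  fail_maf <- st$maf < maf_min
  fail_cr <- st$call_rate < callrate_min
  fail_hwe <- hwe_p < hwe_alpha

  verdict <- rep("pass", nrow(st))
  verdict[fail_hwe] <- "fail_hwe"
  verdict[fail_cr] <- "fail_callrate"
  verdict[fail_maf] <- "fail_maf"   # last write wins: MAF takes precedence

  keep <- verdict == "pass"
  report <- structure(list(
    n_input = nrow(st),
    n_removed_maf = sum(verdict == "fail_maf"),
    n_removed_callrate = sum(verdict == "fail_callrate"),
    n_removed_hwe = sum(verdict == "fail_hwe"),
    n_retained = sum(keep),
    thresholds = c(maf_min = maf_min, callrate_min = callrate_min,
                   hwe_alpha = hwe_alpha),
    table = data.frame(marker_id = st$marker_id, maf = st$maf,
                       call_rate = st$call_rate, hwe_p = hwe_p,
                       verdict = verdict, stringsAsFactors = FALSE)
  ), class = "qc_report")

  list(geno = geno[, keep], report = report)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "SNP QC: %d markers in; removed %d (MAF < %.3g), %d (call rate < %.3g),",
    " %d (HWE p < %.1g); %d retained\n"),
    x$n_input, x$n_removed_maf, x$thresholds["maf_min"],
    x$n_removed_callrate, x$thresholds["callrate_min"],
    x$n_removed_hwe, x$thresholds["hwe_alpha"], x$n_retained))
  invisible(x)
}
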