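#' vanRaden genomic relationship matrix
#'
#' `K = W W' / (2 * sum_j p_j (1 - p_j))` with `W` the dosage matrix
#' column-centered by twice the Alt-allele frequency; missing dosages are
#' mean-imputed per marker. On Hardy-Weinberg data the diagonal averages
#' near 1.
#'
#' @param geno A [genotype_matrix()] (post-QC).
#' @return Symmetric n x n matrix with sample ids as dimnames.
#' @export
vanraden_kinship <- function(geno) {
  X <- impute_column_mean(geno$calls * 1.0)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_validation("all markers monomorphic: kinship undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2L, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(geno$samples$sample_id, geno$samples$sample_id)
  (K + t(K)) / 2
}

# Restricted log-likelihood profile in delta = sigma_e^2 / sigma_g^2,
# after projecting off X (EMMA parameterization). lambda, eta are the
# nonzero eigenvalues of S K S and the rotated phenotype.
.emma_restricted_ll <- function(log_delta, lambda, eta) {
  delta <- exp(log_delta)
  nq <- length(lambda)
  denom <- lambda + delta
  ss <- sum(eta^2 / denom)
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(ss) - sum(log(denom)))
}

#' REML variance components for the null polygenic model (EMMA)
#'
#' Fits `y = X beta + u + e` with `Var(u) = sigma_g^2 K` and
#' `Var(e) = sigma_e^2 I` by restricted maximum likelihood. The
#' restricted likelihood is profiled over `delta = sigma_e^2 / sigma_g^2`
#' on the spectrum of the kinship projected off `X` (the EMMA rotation):
#' a log-spaced grid over 1e-5..1e5 is scanned and the best bracket
#' refined with `optimize()`.
#'
#' @param y Phenotype vector (e.g. AHTI).
#' @param X Fixed-effect design matrix (default intercept-only).
#' @param K Kinship from [vanraden_kinship()].
#' @param grid_points Number of grid points for the profile scan.
#' @return List: `sigma_g2`, `sigma_e2`, `h2` (= sigma_g2/(sigma_g2 +
#'   sigma_e2)), `delta`, `loglik`, and the cached rotation (`U_r`,
#'   `lambda`, `eta`) reused by [marker_scan()].
#' @export
reml_null <- function(y, X = NULL, K = NULL, grid_points = 100L) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (n < q + 2L) stop_validation("need n >= rank(X) + 2")
  if (is.null(K)) stop_validation("kinship matrix K is required")
  K <- (K + t(K)) / 2

  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - q)
  lambda <- pmax(es$values[keep], 0)
  U_r <- es$vectors[, keep, drop = FALSE]
  eta <- drop(crossprod(U_r, y))

  grid <- seq(log(1e-5), log(1e5), length.out = grid_points)
  ll <- vapply(grid, .emma_restricted_ll, numeric(1), lambda = lambda, eta = eta)
  if (any(!is.finite(ll))) {
    stop(errorCondition("non-finite restricted likelihood on the delta grid",
                        class = c("ovitherm_numerical_error", "error")))
  }
  best <- which.max(ll)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(.emma_restricted_ll, c(lo, hi), maximum = TRUE,
                         lambda = lambda, eta = eta, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(eta^2 / (lambda + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       h2 = sigma_g2 / (sigma_g2 + sigma_e2), delta = delta,
       loglik = opt$objective,
       profile = data.frame(log_delta = grid, loglik = ll),
       U_r = U_r, lambda = lambda, eta = eta)
}

#' Mixed-model single-marker association scan (P3D)
#'
#' Tests each marker's Alt-dosage effect on the phenotype under
#' `y = g alpha + X beta + u + e`, with the polygenic covariance
#' `sigma_g^2 K + sigma_e^2 I` fixed at the null-model REML estimates
#' (P3D/EMMAX). The mixed model is reduced to OLS by a one-time spectral
#' rotation of the covariance; per marker, a two-sided t test with
#' `n - rank(X) - 1` degrees of freedom. Missing dosages are mean-imputed;
#' monomorphic markers get effect 0 and p 1 (flagged).
#'
#' @param geno A [genotype_matrix()] (post-QC).
#' @param y Phenotype vector in sample order.
#' @param X Covariate design (default intercept-only).
#' @param K Kinship; default [vanraden_kinship()] of `geno`.
#' @param vc Variance components from [reml_null()]; computed if `NULL`.
#' @return Data frame of class `gwas_result`, one row per marker:
#'   `marker_id`, `chrom`, `pos`, `ref`, `alt`, `effect` (phenotype units
#'   per Alt allele), `se`, `pvalue`, `lod` (= -log10 p), `qvalue`
#'   (Benjamini-Hochberg), `monomorphic`.
#' @export
marker_scan <- function(geno, y, X = NULL, K = NULL, vc = NULL) {
  y <- as.numeric(y)
  n <- n_samples(geno)
  if (length(y) != n) stop_validation("length(y) != n_samples")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (is.null(K)) K <- vanraden_kinship(geno)
  if (is.null(vc)) vc <- reml_null(y, X, K)

  # Rotate by V^{-1/2} using the eigendecomposition of K.
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- vc$sigma_g2 * pmax(ek$values, 0) + vc$sigma_e2
  Tm <- t(ek$vectors) / sqrt(d)          # V^{-1/2} rows
  y_t <- Tm %*% y
  X_t <- Tm %*% X

  qrX <- qr(X_t)
  q <- qrX$rank
  y_r <- stats::resid(stats::lm.fit(X_t, y_t))
  df <- n - q - 1L

  G <- impute_column_mean(geno$calls * 1.0)
  mono <- apply(G, 2L, function(g) stats::var(g) == 0)
  eff <- se <- rep(0, ncol(G))
  pval <- rep(1, ncol(G))
  Gt <- Tm %*% G
  Gr <- Gt - X_t %*% qr.coef(qrX, Gt)    # residualize markers on covariates
  gss <- colSums(Gr^2)
  ok <- !mono & gss > 1e-12
  b <- colSums(Gr[, ok, drop = FALSE] * drop(y_r)) / gss[ok]
  rss <- sum(y_r^2) - b^2 * gss[ok]
  s2 <- pmax(rss, 0) / df
  se_ok <- sqrt(s2 / gss[ok])
  tstat <- b / se_ok
  eff[ok] <- b
  se[ok] <- se_ok
  pval[ok] <- 2 * stats::pt(-abs(tstat), df)
  pval <- pmin(1, pmax(pval, .Machine$double.xmin))

  out <- data.frame(
    marker_id = geno$map$marker_id, chrom = geno$map$chrom,
    pos = geno$map$pos, ref = geno$map$ref, alt = geno$map$alt,
    effect = eff, se = se, pvalue = pval, lod = -log10(pval),
    qvalue = stats::p.adjust(pval, method = "BH"),
    monomorphic = mono, stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Assign significance status (Sig / SigLD / NS)
#'
#' `Sig` when the raw p-value is at or below `p_threshold`. `SigLD` when a
#' marker misses that cutoff but (a) its p-value is at or below
#' `2 * p_threshold` and (b) it is in strong linkage disequilibrium
#' (composite-dosage r-squared >= `ld_r2`) with a `Sig` marker on the same
#' chromosome within `ld_window_bp`. Markers without a chromosome or
#' position skip the LD step. Benjamini-Hochberg q-values are already in
#' the records.
#'
#' @param records A `gwas_result` from [marker_scan()].
#' @param geno The genotype matrix the scan used (for LD).
#' @param p_threshold Raw-p significance cutoff (default 1e-3).
#' @param ld_r2 Squared dosage correlation defining "linked".
#' @param ld_window_bp Maximum distance for LD pairs.
#' @return `records` with a `status` column.
#' @export
significance_status <- function(records, geno, p_threshold = 1e-3,
                                ld_r2 = 0.8, ld_window_bp = 1e6) {
  assert_scalar_number(p_threshold, "p_threshold", .Machine$double.xmin, 1 - 1e-12)
  assert_scalar_number(ld_r2, "ld_r2", 0, 1)
  if (!nrow(records)) {
    records$status <- character()
    return(records)
  }
  status <- ifelse(records$pvalue <= p_threshold, "Sig", "NS")

  sig_idx <- which(status == "Sig")
  cand <- which(status == "NS" & records$pvalue <= 2 * p_threshold &
                  !is.na(records$chrom) & records$chrom != "NA" &
                  !is.na(records$pos))
  for (i in cand) {
    partners <- sig_idx[!is.na(records$chrom[sig_idx]) &
                          records$chrom[sig_idx] == records$chrom[i] &
                          !is.na(records$pos[sig_idx]) &
                          abs(records$pos[sig_idx] - records$pos[i]) <= ld_window_bp]
    if (!length(partners)) next
    gi <- geno$calls[, match(records$marker_id[i], geno$map$marker_id)]
    for (p_ix in partners) {
      gp <- geno$calls[, match(records$marker_id[p_ix], geno$map$marker_id)]
      r <- suppressWarnings(stats::cor(gi, gp, use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= ld_r2) {
        status[i] <- "SigLD"
        break
      }
    }
  }
  records$status <- status
  records
}

#' Plot-ready Manhattan and QQ tables
#'
#' @param records A `gwas_result`.
#' @return List: `manhattan` (marker, chrom, pos, cumulative genome
#'   coordinate `coord`, lod, alternating `color_index`; unplaced markers
#'   appended as a final pseudo-chromosome), `qq` (`expected` vs
#'   `observed` -log10 p, sorted), and `lambda_gc` (median-chi-squared
#'   genomic inflation factor).
#' @export
manhattan_qq_data <- function(records) {
  m <- nrow(records)
  chrom <- ifelse(is.na(records$chrom), "NA", records$chrom)
  pos <- ifelse(is.na(records$pos), 1L, records$pos)
  placed <- chrom != "NA"
  chr_lev <- c(sort(unique(chrom[placed])), if (any(!placed)) "NA")
  offset <- 0
  coord <- numeric(m)
  color_index <- integer(m)
  for (ci in seq_along(chr_lev)) {
    sel <- chrom == chr_lev[ci]
    coord[sel] <- offset + pos[sel]
    color_index[sel] <- 1L + (ci %% 2L)
    offset <- offset + max(pos[sel]) + 1
  }
  manhattan <- data.frame(marker_id = records$marker_id, chrom = chrom,
                          pos = pos, coord = coord, lod = records$lod,
                          color_index = color_index,
                          stringsAsFactors = FALSE)
  manhattan <- manhattan[order(manhattan$coord), ]
  rownames(manhattan) <- NULL

  p_sorted <- sort(records$pvalue)
  qq <- data.frame(expected = -log10(stats::ppoints(m)),
                   observed = -log10(p_sorted))
  chisq <- stats::qchisq(records$pvalue, df = 1, lower.tail = FALSE)
  lambda_gc <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  list(manhattan = manhattan, qq = qq, lambda_gc = lambda_gc)
}
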