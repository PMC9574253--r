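#' Nei's unbiased gene diversity (Hexp)
#'
#' Per biallelic marker, \eqn{h = \frac{N}{N-1}(1 - \sum_a p_a^2)} with
#' N the number of observed allele copies (2 x non-missing genotypes);
#' the reported Hexp is the mean of h over markers.
#'
#' @param geno A [genotype_matrix()].
#' @return Mean unbiased gene diversity in [0, 1].
#' @export
nei_gene_diversity <- function(geno) {
  if (n_markers(geno) == 0L) stop_validation("empty marker set")
  calls <- geno$calls
  n_obs <- colSums(!is.na(calls))
  use <- n_obs >= 1L & (2L * n_obs) >= 2L
  if (!any(use)) stop_validation("no marker with >= 2 observed allele copies")
  N <- 2 * n_obs[use]
  p <- colSums(calls[, use, drop = FALSE], na.rm = TRUE) / N
  h <- (N / (N - 1)) * (1 - (p^2 + (1 - p)^2))
  mean(h)
}

# Pairwise per-locus distances d_j = |dosage_a - dosage_b| / 2 over all
# sample pairs (dist() ordering); NA where either genotype is missing.
.pair_locus_distances <- function(calls) {
  m <- ncol(calls)
  n <- nrow(calls)
  d <- matrix(NA_real_, n * (n - 1L) / 2L, m)
  for (j in seq_len(m)) {
    d[, j] <- as.vector(stats::dist(calls[, j], method = "manhattan")) / 2
  }
  d
}

# Population (divide-by-N) variance, NA-tolerant.
.pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Index of association and its standardized form (rbarD)
#'
#' Multilocus association statistics used to detect departure from random
#' mating / clonality. Per locus j and sample pair (a, b) the distance is
#' \eqn{d_j = |g_a - g_b|/2} (0, 0.5 or 1 for diploid dosages); the
#' multilocus pair distance is \eqn{D = \sum_j d_j}. With V_O the
#' variance of D over pairs and V_E the sum of per-locus distance
#' variances, \eqn{I_a = V_O/V_E - 1} and
#' \eqn{\bar r_d = (V_O - V_E) / (2\sum_{j<k}\sqrt{v_j v_k})}. Both have
#' expectation 0 under random mating; rbarD is bounded by 1. Variances
#' use the divide-by-N convention throughout, which makes the
#' duplicated-locus identity (Ia = rbarD = 1) exact. Pairs with a missing
#' genotype at a locus are dropped from that locus only
#' (pairwise-complete).
#'
#' @param geno A [genotype_matrix()] with >= 2 samples and >= 2 markers.
#' @return List with elements `Ia` and `rbarD`.
#' @export
index_of_association <- function(geno) {
  if (n_samples(geno) < 2L) stop_validation("need >= 2 samples")
  if (n_markers(geno) < 2L) {
    warning("single marker: Ia is 0 by convention, rbarD undefined")
    stop_validation("rbarD undefined for a single marker")
  }
  d <- .pair_locus_distances(geno$calls)
  v <- apply(d, 2L, .pop_var)
  keep <- !is.na(v)
  d <- d[, keep, drop = FALSE]
  v <- v[keep]
  VE <- sum(v)
  if (VE == 0) {
    stop_validation("all pairwise distances are zero: ",
                    "Ia/rbarD undefined (no multilocus variance)")
  }
  D <- rowSums(d, na.rm = TRUE)
  VO <- .pop_var(D)
  sv <- sqrt(v)
  cross <- (sum(sv)^2 - sum(v)) / 2  # sum over j<k of sqrt(v_j v_k)
  list(Ia = VO / VE - 1, rbarD = (VO - VE) / (2 * cross))
}

# Weir & Cockerham (1984) per-marker variance components a, b, c for two
# or more groups at a biallelic locus; returns the three component sums'
# addends per marker so callers can ratio the sums.
.wc_components <- function(calls, groups) {
  glev <- unique(groups)
  r <- length(glev)
  m <- ncol(calls)
  a <- b <- cc <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- calls[, j]
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      gk <- g[groups == glev[k]]
      gk <- gk[!is.na(gk)]
      ni[k] <- length(gk)
      if (ni[k] > 0) {
        pi[k] <- mean(gk) / 2
        hi[k] <- mean(gk == 1L)
      }
    }
    if (any(ni < 2)) next                     # marker unusable for this pair
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[j] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[j] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[j] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham Fst matrix
#'
#' Multilocus theta for every pair of groups: per-marker variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals) are summed over markers and
#' \eqn{\theta = \sum a / \sum(a+b+c)}. Small negative estimates are a
#' property of the estimator and are retained.
#'
#' @param geno A [genotype_matrix()].
#' @param grouping Per-sample labels, or the name of a sample metadata
#'   column (`"breed"`, `"location"`).
#' @return Symmetric matrix of pairwise theta values (class `fst_matrix`),
#'   zero diagonal; groups with fewer than 2 samples are dropped with a
#'   warning.
#' @export
weir_cockerham_fst <- function(geno, grouping) {
  groups <- group_labels(geno, grouping)
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("groups with < 2 samples excluded: ", paste(small, collapse = ", "))
  }
  lev <- setdiff(names(tab), small)
  if (length(lev) < 2L) stop_validation("need >= 2 groups with >= 2 samples")

  theta <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)]) {
    for (k in seq((i + 1), length(lev))) {
      sel <- groups %in% c(lev[i], lev[k])
      comp <- .wc_components(geno$calls[sel, , drop = FALSE], groups[sel])
      num <- sum(comp$a, na.rm = TRUE)
      den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
      theta[i, k] <- theta[k, i] <- if (den > 0) num / den else 0
    }
  }
  structure(theta, class = c("fst_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance (Fst) matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix; negative input entries and negative estimated branch lengths
#' are clamped to zero. The result is an unrooted `phylo` tree; use
#' `ape::write.tree()` for Newick text.
#'
#' @param dist_matrix Symmetric matrix (e.g. from [weir_cockerham_fst()]).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dist_matrix) {
  d <- unclass(as.matrix(dist_matrix))
  if (nrow(d) < 3L) stop_validation("need >= 3 taxa for neighbor joining")
  if (max(abs(d - t(d))) > 1e-8) stop_validation("distance matrix must be symmetric")
  d[d < 0] <- 0
  diag(d) <- 0
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Per-group diversity table
#'
#' One row per group (breed or location) plus a `Total` row over the whole
#' cohort, with sample count, Hexp, Ia and rbarD -- the layout of a
#' standard population-genetics diversity summary.
#'
#' @param geno A [genotype_matrix()].
#' @param grouping Sample metadata column name or per-sample labels.
#' @return Data frame with columns `group`, `n`, `Hexp`, `Ia`, `rbarD`.
#' @export
diversity_table <- function(geno, grouping) {
  groups <- group_labels(geno, grouping)
  lev <- unique(groups)
  rows <- lapply(c(lev, "__total__"), function(g) {
    sub <- if (g == "__total__") geno else geno[groups == g, ]
    ia <- if (n_samples(sub) >= 2L) index_of_association(sub)
          else list(Ia = NA_real_, rbarD = NA_real_)
    data.frame(group = if (g == "__total__") "Total" else g,
               n = n_samples(sub),
               Hexp = nei_gene_diversity(sub),
               Ia = ia$Ia, rbarD = ia$rbarD, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
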