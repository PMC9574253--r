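# Independent oracles used to cross-check the package's estimators.
# Each one takes a computational route different from the implementation.

# Exact HWE probabilities by direct evaluation of the conditional
# distribution: P(h | n, n1) = n! 2^h (2n)!^{-1} n1! n2! /
# (nAA! h! naa!), enumerated over every compatible genotype table.
oracle_hwe_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n_bb + n_ab
  hets <- seq.int(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lfactorial(n) + h * log(2) + lfactorial(nA) + lfactorial(nB) -
      lfactorial(2 * n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, numeric(1))
  probs <- exp(logp)
  obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# Weir-Cockerham theta via the ANOVA sums-of-squares route on raw
# genotypes (genes within individuals / individuals within populations /
# among populations), rather than the a/b/c component formulas.
oracle_wc_theta <- function(calls, groups) {
  lev <- unique(groups)
  r <- length(lev)
  num <- den <- 0
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    ok <- !is.na(g)
    if (!all(tapply(ok, groups, sum) >= 2)) next
    gi <- g[ok]
    gr <- groups[ok]
    ni <- as.vector(table(factor(gr, levels = lev)))
    ntot <- sum(ni)
    pij <- gi / 2
    pi_bar <- tapply(pij, factor(gr, levels = lev), mean)
    p_w <- sum(ni * pi_bar) / ntot

    ssp <- 2 * sum(ni * (pi_bar - p_w)^2)
    ssi <- 2 * sum((pij - pi_bar[match(gr, lev)])^2)
    ssg <- sum(gi == 1L) / 2

    msp <- ssp / (r - 1)
    msi <- ssi / (ntot - r)
    msg <- ssg / ntot
    nbar <- ntot / r
    nc <- (ntot - sum(ni^2) / ntot) / (r - 1)

    sig_p <- (msp - msi) / (2 * nc)
    sig_i <- (msi - msg) / 2
    sig_g <- msg
    num <- num + sig_p
    den <- den + sig_p + sig_i + sig_g
  }
  num / den
}

# One-sided hypergeometric tail by explicit enumeration of all
# list-sized draws from the universe (feasible for |universe| <= 15).
oracle_hypergeom_tail <- function(k, set_size, list_size, universe_size) {
  draws <- utils::combn(universe_size, list_size)
  in_set <- draws <= set_size        # wlog the set is the first set_size ids
  mean(colSums(in_set) >= k)
}

# Branch lengths of the unique unrooted 3-taxon tree (three-point formulas).
oracle_three_taxon_lengths <- function(d) {
  c(x = (d[1, 2] + d[1, 3] - d[2, 3]) / 2,
    y = (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
    z = (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
}

# Best row-permutation match of estimated Q against Q_true; returns the
# mean absolute error (K small, so all permutations are tried).
q_match_mae <- function(Q_hat, Q_true) {
  K <- ncol(Q_true)
  perms <- if (K == 1) list(1L) else asplit(.permutations(K), 1L)
  best <- Inf
  for (p in perms) {
    best <- min(best, mean(abs(Q_hat[, p, drop = FALSE] - Q_true)))
  }
  best
}

.permutations <- function(K) {
  if (K == 1L) return(matrix(1L))
  sub <- .permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, matrix(c(seq_len(K)[-i])[sub], nrow(sub)))
  }))
}
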