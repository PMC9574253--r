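#' PCA of a genotype matrix
#'
#' Markers are centered by twice the estimated Alt frequency and scaled by
#' `sqrt(2 p (1 - p))` (Patterson scaling); missing dosages are
#' mean-imputed before decomposition. Scores come from the SVD of the
#' scaled matrix.
#'
#' @param geno A [genotype_matrix()] (post-QC).
#' @param n_components Number of axes to return (default all).
#' @return List with `scores` (samples x components), `pct_variance`
#'   (percent of total variance per returned axis) and `center`/`scale`
#'   vectors used.
#' @export
pca_genotypes <- function(geno, n_components = NULL) {
  X <- impute_column_mean(geno$calls * 1.0)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop_validation("all markers monomorphic: zero-variance matrix")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")

  n_all <- min(dim(X)) - 1L
  n_components <- n_components %||% n_all
  if (n_components >= min(dim(X))) {
    stop_validation("n_components must be < min(n_samples, n_markers)")
  }
  sv <- svd(X, nu = n_components, nv = 0)
  ev <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- geno$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores,
       pct_variance = 100 * ev[seq_len(n_components)] / sum(ev),
       center = 2 * p, scale = sqrt(2 * p * (1 - p)))
}

#' Choose the number of clusters on PC scores by k-means + BIC
#'
#' Runs seeded multi-start k-means for each K and scores the solutions
#' with \eqn{BIC(K) = n \ln(WSS_K / n) + K \ln n}; the chosen K minimizes
#' BIC. This is the standard first stage of DAPC-style cluster detection.
#'
#' @param pc_scores Matrix of retained principal-component scores.
#' @param K_range Candidate cluster counts (default 1:10, capped below n).
#' @param seed Integer seed (all restarts derive from it).
#' @param nstart Random restarts per K.
#' @return List with `bic_by_K` (named vector), `chosen_K`, and
#'   `assignments` (list of per-K cluster label vectors).
#' @export
find_clusters_bic <- function(pc_scores, K_range = 1:10, seed = 1L,
                              nstart = 10L) {
  pc_scores <- as.matrix(pc_scores)
  n <- nrow(pc_scores)
  if (max(K_range) >= n) stop_validation("K_max must be < n_samples")
  bic <- stats::setNames(numeric(length(K_range)), K_range)
  assignments <- vector("list", length(K_range))
  names(assignments) <- K_range
  withr::with_seed(seed, {
    for (i in seq_along(K_range)) {
      K <- K_range[i]
      if (K == 1L) {
        wss <- sum(scale(pc_scores, scale = FALSE)^2)
        cl <- rep(1L, n)
      } else {
        km <- stats::kmeans(pc_scores, centers = K, nstart = nstart,
                            iter.max = 100L)
        wss <- km$tot.withinss
        cl <- km$cluster
      }
      bic[i] <- n * log(wss / n) + K * log(n)
      assignments[[i]] <- cl
    }
  })
  list(bic_by_K = bic,
       chosen_K = K_range[which.min(bic)],
       assignments = assignments)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant axes computed on retained PCs, for groups either
#' supplied or found by [find_clusters_bic()]. The within-group scatter is
#' ridge-regularized (trace-scaled epsilon) when singular.
#'
#' @param geno A [genotype_matrix()].
#' @param groups Per-sample labels; if `NULL`, k-means/BIC cluster labels
#'   are used.
#' @param n_pcs Number of PCs retained; default: enough to explain 90% of
#'   variance (capped at n - number of groups).
#' @param seed Seed for the clustering stage when `groups` is `NULL`.
#' @return List of class `dapc_result`: `assignments`, `chosen_K`,
#'   `bic_by_K` (when clustering was run), `discriminant_coords`
#'   (n x (K-1)), `pct_variance_by_axis` (sums to 100), `loadings`.
#' @export
dapc_genotypes <- function(geno, groups = NULL, n_pcs = NULL, seed = 1L) {
  pca <- pca_genotypes(geno)
  bic_by_K <- NULL
  if (is.null(groups)) {
    cl <- find_clusters_bic(pca$scores, K_range = 1:min(10L, n_samples(geno) - 1L),
                            seed = seed)
    groups <- cl$assignments[[as.character(cl$chosen_K)]]
    bic_by_K <- cl$bic_by_K
  }
  groups <- as.factor(groups)
  K <- nlevels(groups)
  if (K < 2L) stop_validation("need >= 2 groups for discriminant analysis")
  if (min(table(groups)) < 2L) stop_validation("every group needs >= 2 members")

  if (is.null(n_pcs)) {
    n_pcs <- max(1L, which(cumsum(pca$pct_variance) >= 90)[1L])
  }
  n_pcs <- min(n_pcs, n_samples(geno) - K, ncol(pca$scores))
  X <- pca$scores[, seq_len(n_pcs), drop = FALSE]

  # Between/within scatter; generalized eigenproblem solved directly.
  mu <- colMeans(X)
  W <- matrix(0, n_pcs, n_pcs)
  B <- matrix(0, n_pcs, n_pcs)
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2L, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - mu)
  }
  if (rcond(W) < 1e-12) {
    warning("singular within-group scatter; applying ridge regularization")
    W <- W + diag(1e-6 * sum(diag(W)) / n_pcs, n_pcs)
  }
  eg <- eigen(solve(W, B))
  n_axes <- K - 1L
  vec <- Re(eg$vectors[, seq_len(n_axes), drop = FALSE])
  val <- Re(eg$values[seq_len(n_axes)])
  coords <- X %*% vec
  colnames(coords) <- paste0("LD", seq_len(n_axes))

  structure(list(
    assignments = groups,
    chosen_K = K,
    bic_by_K = bic_by_K,
    discriminant_coords = coords,
    pct_variance_by_axis = 100 * val / sum(val),
    loadings = vec,
    n_pcs = n_pcs
  ), class = "dapc_result")
}

# Project rows of Q onto the probability simplex (Duchi et al. algorithm).
.project_simplex_rows <- function(Q) {
  K <- ncol(Q)
  if (K == 1L) return(matrix(1, nrow(Q), 1L))
  t(apply(Q, 1L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_len(K) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
  }))
}

# Exact simplex-constrained least squares: minimize q'Gq - 2 b'q subject
# to sum(q) = 1, q >= 0, by a small active-set iteration (K <= 10 here).
# KKT system on the free set; most-violating zero variable enters, most
# negative free variable leaves.
.simplex_lsq <- function(G, b) {
  K <- length(b)
  if (K == 1L) return(1)
  free <- rep(TRUE, K)
  q <- rep(0, K)
  for (pass in seq_len(4L * K)) {
    S <- which(free)
    ns <- length(S)
    kkt <- rbind(cbind(2 * G[S, S, drop = FALSE], 1), c(rep(1, ns), 0))
    sol <- try(solve(kkt, c(2 * b[S], 1)), silent = TRUE)
    if (inherits(sol, "try-error")) return(NULL)
    qs <- sol[seq_len(ns)]
    lam <- sol[ns + 1L]
    if (any(qs < -1e-10)) {
      free[S[which.min(qs)]] <- FALSE
      if (sum(free) == 0L) return(NULL)
      next
    }
    q[] <- 0
    q[S] <- pmax(qs, 0)
    # Stationarity for the variables held at zero.
    grad <- 2 * (G %*% q - b)
    viol <- which(!free & grad + lam < -1e-10)
    if (!length(viol)) return(q / sum(q))
    free[viol[which.min(grad[viol])]] <- TRUE
  }
  NULL
}

# Masked squared-error objective; M has NA at unobserved entries.
.admix_objective <- function(M, Q, F) {
  R <- M - Q %*% F
  sum(R[!is.na(R)]^2)
}

#' Least-squares admixture estimation
#'
#' Factorizes the observed half-dosage matrix `M = dosage/2` into
#' ancestry proportions `Q` (rows on the simplex) and ancestral Alt-allele
#' frequencies `F` (entries in [0, 1]) by minimizing the squared error
#' over observed entries. Optimization alternates projected-gradient
#' blocks with backtracking line search, so the objective is
#' non-increasing at every sweep; missing genotypes are simply excluded
#' from the objective. K = 1 has the closed-form solution (Q all ones,
#' F the per-marker mean half-dosage).
#'
#' @param geno A [genotype_matrix()] (post-QC).
#' @param K Number of ancestral populations (>= 1).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum alternating sweeps.
#' @param tol Convergence: relative objective change below this stops.
#' @param inner_steps Projected-gradient refinement steps per block and
#'   sweep.
#' @return List of class `structure_result`: `K`, `Q`, `F`,
#'   `objective` (trace of the masked SSE per sweep), `iterations_run`,
#'   `seed`.
#' @export
admixture_lsq <- function(geno, K, seed = 1L, max_iter = 500L, tol = 1e-8,
                          inner_steps = 15L) {
  if (K < 1L) stop_validation("K must be >= 1")
  n <- n_samples(geno)
  m <- n_markers(geno)
  if (K > n) stop_validation("K must be <= n_samples")
  M <- geno$calls / 2
  obs <- !is.na(M)
  M0 <- M
  M0[!obs] <- 0

  if (K == 1L) {
    F <- matrix(colSums(M0) / pmax(1L, colSums(obs)), 1L, m)
    Q <- matrix(1, n, 1L)
    dimnames(Q) <- list(geno$samples$sample_id, "K1")
    colnames(F) <- geno$map$marker_id
    return(structure(list(K = 1L, Q = Q, F = F,
                          objective = .admix_objective(M, Q, F),
                          iterations_run = 0L, seed = seed),
                     class = "structure_result"))
  }

  withr::with_seed(seed, {
    Q <- .project_simplex_rows(matrix(stats::runif(n * K, 0.2, 0.8), n, K))
    F <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  })

  obj <- .admix_objective(M, Q, F)
  trace <- obj

  complete <- all(obs)
  # Exact (unconstrained) block least-squares candidates; with missing
  # entries the normal equations are assembled per row/column.
  # Exact simplex-constrained solve per sample row; with complete data
  # the Gram matrix is shared across rows.
  ls_Q <- function(F) {
    Qc <- Q
    if (complete) {
      G <- tcrossprod(F)
      B <- F %*% t(M0)
      for (i in seq_len(n)) {
        sol <- .simplex_lsq(G, B[, i])
        if (!is.null(sol)) Qc[i, ] <- sol
      }
      return(Qc)
    }
    for (i in seq_len(n)) {
      o <- obs[i, ]
      A <- F[, o, drop = FALSE]
      sol <- .simplex_lsq(tcrossprod(A) + diag(1e-10, K),
                          drop(A %*% M[i, o]))
      if (!is.null(sol)) Qc[i, ] <- sol
    }
    Qc
  }
  ls_F <- function(Q) {
    if (complete) {
      sol <- try(solve(crossprod(Q), t(Q) %*% M0), silent = TRUE)
      if (!inherits(sol, "try-error")) return(sol)
    }
    Fc <- F
    for (j in seq_len(m)) {
      o <- obs[, j]
      A <- Q[o, , drop = FALSE]
      sol <- try(solve(crossprod(A) + diag(1e-10, K), t(A) %*% M[o, j]),
                 silent = TRUE)
      if (!inherits(sol, "try-error")) Fc[, j] <- sol
    }
    Fc
  }

  masked_resid <- function() {
    R <- Q %*% F - M0
    R[!obs] <- 0
    R
  }

  # Each sweep solves the Q block exactly (simplex-constrained active
  # set per row, so simplex faces are reachable) and takes the F block
  # as an unconstrained LS jump kept only when it descends, followed by
  # fixed-step projected-gradient refinement; 1/L steps on a convex
  # quadratic block are descent steps, so the sweep objective is
  # non-increasing.
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    cand <- ls_Q(F)
    if (.admix_objective(M, cand, F) <= obj) Q <- cand
    obj <- .admix_objective(M, Q, F)

    cand <- pmin(pmax(ls_F(Q), 0), 1)
    if (.admix_objective(M, Q, cand) <= obj) F <- cand
    lipF <- 2 * sum(Q * Q) + 1e-12
    for (s in seq_len(inner_steps)) {
      F <- pmin(pmax(F - (2 * t(Q) %*% masked_resid()) / lipF, 0), 1)
    }
    obj <- .admix_objective(M, Q, F)

    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (prev - obj <= tol * max(prev, 1e-12)) break
  }

  rownames(Q) <- geno$samples$sample_id
  colnames(Q) <- paste0("K", seq_len(K))
  colnames(F) <- geno$map$marker_id
  structure(list(K = K, Q = Q, F = F, objective = trace,
                 iterations_run = iter, seed = seed),
            class = "structure_result")
}

#' @method print structure_result
#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, %d samples x %d markers, %d sweeps, SSE %.4f\n",
              x$K, nrow(x$Q), ncol(x$F), x$iterations_run,
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Choose K by masked cross-entropy
#'
#' Holds out a seeded random fraction of the observed genotype entries,
#' fits [admixture_lsq()] on the rest for each K, and scores each fit by
#' the cross-entropy of the held-out half-dosages against the predicted
#' Alt-allele frequencies `pi = clip(QF, eps, 1 - eps)`:
#' \deqn{CE = -\mathrm{mean}[\,(g/2)\log\pi + (1 - g/2)\log(1-\pi)\,].}
#' The best K minimizes the criterion.
#'
#' @param geno A [genotype_matrix()].
#' @param K_range Candidate K values (default 1:10).
#' @param mask_fraction Fraction of observed entries held out (in (0, 0.5)).
#' @param seed Integer seed (mask and every fit derive from it).
#' @param max_iter,tol Passed to [admixture_lsq()].
#' @param eps Probability clip for the log terms.
#' @return List with `cross_entropy` (named by K), `best_K`, and `fits`
#'   (the per-K `structure_result`s refit on all data for the best K is
#'   `fits[[as.character(best_K)]]`).
#' @export
cross_entropy_select <- function(geno, K_range = 1:10, mask_fraction = 0.05,
                                 seed = 1L, max_iter = 200L, tol = 1e-6,
                                 eps = 1e-6) {
  if (mask_fraction <= 0 || mask_fraction >= 0.5) {
    stop_validation("mask_fraction must be in (0, 0.5)")
  }
  obs_idx <- which(!is.na(geno$calls))
  n_mask <- floor(length(obs_idx) * mask_fraction)
  if (n_mask < 1L) stop_validation("mask is empty; increase mask_fraction")
  withr::with_seed(seed, {
    masked <- sample(obs_idx, n_mask)
  })
  train <- geno
  train$calls[masked] <- NA_integer_
  g_held <- geno$calls[masked] / 2

  ce <- stats::setNames(rep(NA_real_, length(K_range)), K_range)
  fits <- vector("list", length(K_range))
  names(fits) <- K_range
  for (i in seq_along(K_range)) {
    fit <- admixture_lsq(train, K_range[i], seed = seed + i,
                         max_iter = max_iter, tol = tol)
    pi_hat <- (fit$Q %*% fit$F)[masked]
    pi_hat <- pmin(1 - eps, pmax(eps, pi_hat))
    ce[i] <- -mean(g_held * log(pi_hat) + (1 - g_held) * log(1 - pi_hat))
    fits[[i]] <- fit
  }
  list(cross_entropy = ce, best_K = K_range[which.min(ce)], fits = fits)
}
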