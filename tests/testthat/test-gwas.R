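test_that("vanRaden kinship matches hand arithmetic and row-duplication identity", {
  # 3 individuals x 2 markers, dosages [[0,2],[1,1],[2,0]]:
  # p = (0.5, 0.5), W = M - 1, denom = 2 * (0.25 + 0.25) = 1.
  g <- toy_geno(rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L)))
  K <- vanraden_kinship(g)
  W <- matrix(c(-1, 0, 1, 1, 0, -1), 3, 2)
  expect_equal(unname(K), W %*% t(W) / 1, tolerance = 1e-12)

  withr::with_seed(3, {
    calls <- matrix(rbinom(10 * 200, 2, rep(runif(200, 0.2, 0.8), each = 10)),
                    10, 200)
  })
  calls[4, ] <- calls[2, ]
  Kd <- vanraden_kinship(toy_geno(calls))
  expect_equal(Kd[2, 4], Kd[2, 2], tolerance = 1e-12)
  expect_equal(Kd[4, 4], Kd[2, 2], tolerance = 1e-12)
  expect_equal(max(abs(Kd - t(Kd))), 0, tolerance = 1e-12)
  expect_gte(min(eigen(Kd, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(vanraden_kinship(toy_geno(matrix(2L, 4, 3))),
               class = "ovitherm_validation_error")
})

test_that("kinship off-diagonals vanish for unrelated cohorts", {
  sim <- simulate_admixed_genotypes(250, 5000, K = 1, fst_target = 0.05,
                                    missing_rate = 0, seed = 14)
  K <- vanraden_kinship(sim$geno)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.01)
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
})

test_that("P3D scan with identity kinship reproduces OLS exactly", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(15:40, 1)
      m <- sample(3:8, 1)
      calls <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.8), each = n)),
                      n, m)
      y <- rnorm(n)
      g <- toy_geno(calls)
      res <- marker_scan(g, y, K = diag(n),
                         vc = list(sigma_g2 = 0.5, sigma_e2 = 0.5))
      for (j in seq_len(m)) {
        if (res$monomorphic[j]) next
        fit <- summary(lm(y ~ calls[, j]))$coefficients
        expect_equal(res$effect[j], fit[2, 1], tolerance = 1e-8)
        expect_equal(res$pvalue[j], fit[2, 4], tolerance = 1e-8)
      }
    }
  })
})

test_that("REML with identity kinship matches the OLS residual variance", {
  withr::with_seed(29, {
    y <- rnorm(80, mean = 3, sd = 2)
  })
  vc <- reml_null(y, K = diag(80))
  expect_equal(vc$sigma_g2 + vc$sigma_e2, var(y), tolerance = 1e-4)
})

test_that("REML detects absent and present polygenic signal", {
  sim <- simulate_admixed_genotypes(150, 2000, K = 2, fst_target = 0.05,
                                    alpha = 0.5, missing_rate = 0, seed = 37)
  K <- vanraden_kinship(sim$geno)
  withr::with_seed(38, {
    y_null <- rnorm(150)
    L <- chol(K + diag(1e-6, 150))
    u <- drop(crossprod(L, rnorm(150)))
    y_her <- u / sd(u) + rnorm(150)          # h2 = 0.5 by construction
  })
  expect_lt(reml_null(y_null, K = K)$h2, 0.25)
  expect_gt(reml_null(y_her, K = K)$h2, 0.2)
})

test_that("lod, q-values and effect antisymmetry are internally consistent", {
  sim <- simulate_admixed_genotypes(80, 300, K = 2, missing_rate = 0.02,
                                    seed = 43)
  phy <- simulate_physiology(sim$geno, sim$truth,
                             causal_markers = c(snp00025 = 1.5), h2 = 0.4,
                             seed = 44)
  a <- ahti_score(phy$panel)
  y <- a$ahti[match(sim$geno$samples$sample_id, a$animal_id)]
  res <- marker_scan(sim$geno, y)
  expect_equal(res$lod, -log10(res$pvalue), tolerance = 1e-9)
  ord <- order(res$pvalue)
  expect_true(all(diff(res$qvalue[ord]) >= -1e-12))

  # Published lod/p spot relation: -log10 p recovers the printed lod.
  expect_equal(round(-log10(3.07e-5), 2), 4.51)

  # Flipping Ref/Alt orientation (dosage g -> 2 - g) flips the sign only.
  flipped <- sim$geno
  flipped$calls <- 2L - flipped$calls
  res_f <- marker_scan(flipped, y)
  expect_equal(res_f$effect, -res$effect, tolerance = 1e-8)
  expect_equal(res_f$pvalue, res$pvalue, tolerance = 1e-8)
})

test_that("monomorphic markers are emitted flagged with null effect", {
  calls <- cbind(rep(1L, 12), rbinom(12, 2, 0.5))
  calls[1, 2] <- 1L  # keep polymorphic
  g <- toy_geno(calls)
  y <- rnorm(12)
  res <- marker_scan(g, y, K = diag(12),
                     vc = list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_true(res$monomorphic[1])
  expect_equal(res$effect[1], 0)
  expect_equal(res$pvalue[1], 1)
})

test_that("significance status separates Sig, SigLD and NS", {
  withr::with_seed(53, {
    base <- rbinom(60, 2, 0.5)
  })
  calls <- cbind(base, base, rbinom(60, 2, 0.5))
  g <- toy_geno(calls, pos = c(1000L, 2000L, 900000L))
  records <- data.frame(marker_id = g$map$marker_id, chrom = g$map$chrom,
                        pos = g$map$pos, ref = "A", alt = "G",
                        effect = c(1, 1, 0.1),
                        pvalue = c(5e-4, 1.5e-3, 0.4),
                        lod = -log10(c(5e-4, 1.5e-3, 0.4)),
                        stringsAsFactors = FALSE)
  out <- significance_status(records, g)
  expect_equal(out$status, c("Sig", "SigLD", "NS"))

  # Without an LD partner in range the borderline marker stays NS.
  far <- records
  far$pos[2] <- 5e7
  g_far <- g
  g_far$map$pos <- far$pos
  expect_equal(significance_status(far, g_far)$status[2], "NS")

  empty <- records[0, ]
  expect_equal(nrow(significance_status(empty, g)), 0L)
  expect_error(significance_status(records, g, p_threshold = 2),
               class = "ovitherm_validation_error")
})

test_that("Manhattan coordinates accumulate and lambda is near 1 under the null", {
  withr::with_seed(59, {
    p <- runif(2000)
  })
  recs <- data.frame(marker_id = paste0("m", 1:2000),
                     chrom = rep(c("1", "2"), each = 1000),
                     pos = rep(seq_len(1000) * 1000L, 2),
                     pvalue = p, lod = -log10(p), stringsAsFactors = FALSE)
  mq <- manhattan_qq_data(recs)
  expect_true(all(diff(mq$manhattan$coord) > 0))
  expect_gt(mq$lambda_gc, 0.9)
  expect_lt(mq$lambda_gc, 1.1)
  expect_equal(nrow(mq$qq), 2000L)

  single <- manhattan_qq_data(recs[1, ])
  expect_equal(nrow(single$manhattan), 1L)
  expect_equal(single$manhattan$coord, recs$pos[1])
})
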