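test_that("genotype simulation is seed-deterministic and validates inputs", {
  a <- simulate_admixed_genotypes(20, 50, K = 3, seed = 5)
  b <- simulate_admixed_genotypes(20, 50, K = 3, seed = 5)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$truth$Q_true, b$truth$Q_true)
  c <- simulate_admixed_genotypes(20, 50, K = 3, seed = 6)
  expect_false(identical(a$geno$calls, c$geno$calls))

  expect_equal(rowSums(a$truth$Q_true), rep(1, 20), tolerance = 1e-12)
  expect_true(all(a$truth$F_true >= 0 & a$truth$F_true <= 1))
  expect_error(simulate_admixed_genotypes(1, 50), class = "ovitherm_validation_error")
  expect_error(simulate_admixed_genotypes(20, 50, fst_target = 1.5),
               class = "ovitherm_validation_error")
})

test_that("a single ancestral population shows no differentiation", {
  sim <- simulate_admixed_genotypes(200, 2000, K = 1, fst_target = 0.1,
                                    missing_rate = 0, seed = 21)
  halves <- rep(c("h1", "h2"), each = 100)
  th <- weir_cockerham_fst(toy_geno(sim$geno$calls, breed = halves), "breed")
  expect_lt(abs(th["h1", "h2"]), 0.01)
})

test_that("marker dosage marginals match the mixture frequencies", {
  sim <- simulate_admixed_genotypes(300, 400, K = 3, fst_target = 0.05,
                                    alpha = 0.5, missing_rate = 0, seed = 17)
  q <- sim$truth$Q_true %*% sim$truth$F_true
  mean_dose <- colMeans(sim$geno$calls)
  se <- sqrt(colMeans(2 * q * (1 - q)) / nrow(q))
  expect_true(all(abs(mean_dose - 2 * colMeans(q)) < 3 * pmax(se, 1e-3) + 0.05))
  # Aggregate check: tight agreement on the overall mean.
  expect_equal(mean(mean_dose), mean(2 * q), tolerance = 0.01)
})

test_that("missingness is injected at the requested rate", {
  sim <- simulate_admixed_genotypes(100, 500, K = 2, missing_rate = 0.05,
                                    seed = 9)
  rate <- mean(is.na(sim$geno$calls))
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("physiology with zero stress deltas yields AHTI 0 everywhere", {
  sim <- simulate_admixed_genotypes(30, 100, K = 2, seed = 2)
  base0 <- data.frame(param = c("RT", "ET", "RR", "TV", "MR"),
                      rest_mean = c(39, 36, 40, 0.25, 140),
                      rest_sd = c(0.35, 0.6, 8, 0.03, 10),
                      delta = 0)
  phy <- simulate_physiology(sim$geno, sim$truth, h2 = 0.3,
                             baselines = base0, seed = 4)
  res <- ahti_score(phy$panel)
  expect_equal(res$ahti, rep(0L, 30))
})

test_that("physiology simulation validates causal markers and is seeded", {
  sim <- simulate_admixed_genotypes(25, 60, K = 2, seed = 3)
  expect_error(
    simulate_physiology(sim$geno, sim$truth,
                        causal_markers = c(not_a_marker = 1)),
    class = "ovitherm_validation_error")
  p1 <- simulate_physiology(sim$geno, sim$truth,
                            causal_markers = c(snp00007 = 1), seed = 12)
  p2 <- simulate_physiology(sim$geno, sim$truth,
                            causal_markers = c(snp00007 = 1), seed = 12)
  expect_identical(p1$panel, p2$panel)
  expect_equal(p1$truth$h2, 0.3)
  # Derivations hold exactly on the generated raw measurements.
  d <- derive_physio(p1$panel)
  expect_equal(d$TV, d$GV / d$RR)
  expect_equal(d$MR, 1440 * (3.941 * d$VO2 + 1.106 * d$VCO2) / d$BW^0.75)
})

test_that("null phenotype (h2 = 0, no causal markers) gives uniform GWAS p-values", {
  sim <- simulate_admixed_genotypes(200, 2000, K = 1, fst_target = 0.05,
                                    alpha = 1, missing_rate = 0, seed = 31)
  phy <- simulate_physiology(sim$geno, sim$truth, h2 = 0, seed = 32)
  y <- ahti_score(phy$panel)
  y <- y$ahti[match(sim$geno$samples$sample_id, y$animal_id)]
  res <- marker_scan(sim$geno, y)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("heritability set in the generator is recovered by REML on AHTI", {
  # Transmission of h2 = 0.5 through the threshold score, averaged over
  # seeds; the staircase attenuates mildly, so the band is +/- 0.15.
  h2_hat <- vapply(1:10, function(s) {
    sim <- simulate_admixed_genotypes(300, 5000, K = 2, fst_target = 0.05,
                                      alpha = 0.5, missing_rate = 0,
                                      seed = 500 + s)
    phy <- simulate_physiology(sim$geno, sim$truth, h2 = 0.5,
                               seed = 600 + s)
    a <- ahti_score(phy$panel)
    y <- a$ahti[match(sim$geno$samples$sample_id, a$animal_id)]
    reml_null(y, K = vanraden_kinship(sim$geno))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.15)
})

test_that("meteorological tables validate sites and ranges", {
  tab <- simulate_meteo(data.frame(location = c("A", "B"),
                                   DBT_am = c(27, 30), RH_am = c(70, 50),
                                   DBT_pm = c(45, 46), RH_pm = c(25, 22)))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$clock_time, c("07:00", "14:00"))
  expect_equal(nrow(simulate_meteo(data.frame(location = character(),
                                              DBT_am = numeric(), RH_am = numeric(),
                                              DBT_pm = numeric(), RH_pm = numeric()))), 0L)
  expect_error(simulate_meteo(data.frame(location = c("A", "A"),
                                         DBT_am = 27, RH_am = 70,
                                         DBT_pm = 45, RH_pm = 25)),
               class = "ovitherm_validation_error")
  expect_error(simulate_meteo(data.frame(location = "A", DBT_am = 27,
                                         RH_am = 170, DBT_pm = 45, RH_pm = 25)),
               class = "ovitherm_validation_error")
})
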