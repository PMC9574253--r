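test_that("Nei's unbiased gene diversity follows the N/(N-1) correction", {
  # Monomorphic marker contributes 0.
  expect_equal(nei_gene_diversity(toy_geno(matrix(2L, 5, 1))), 0)
  # Two individuals, dosages {0, 2}: N = 4, p = 0.5, h = (4/3) * 0.5.
  expect_equal(nei_gene_diversity(toy_geno(matrix(c(0L, 2L), 2, 1))),
               2 / 3, tolerance = 1e-12)
  # Large N at p = 0.5 approaches 0.5.
  big <- toy_geno(matrix(rep(c(0L, 2L), 500), ncol = 1))
  expect_equal(nei_gene_diversity(big), 0.5, tolerance = 1e-3)
  expect_error(nei_gene_diversity(toy_geno(matrix(NA_integer_, 3, 1))),
               class = "ovitherm_validation_error")
})

test_that("duplicated loci give Ia = rbarD = 1 exactly", {
  withr::with_seed(5, {
    base <- sample(0:2, 40, replace = TRUE)
  })
  g <- toy_geno(cbind(base, base))
  res <- index_of_association(g)
  expect_equal(res$Ia, 1, tolerance = 1e-12)
  expect_equal(res$rbarD, 1, tolerance = 1e-12)

  # Four copies of one locus: V_O = 16v, V_E = 4v -> Ia = 3, rbarD = 1.
  g4 <- toy_geno(cbind(base, base, base, base))
  res4 <- index_of_association(g4)
  expect_equal(res4$Ia, 3, tolerance = 1e-12)
  expect_equal(res4$rbarD, 1, tolerance = 1e-12)
})

test_that("independent loci under random mating give Ia and rbarD near zero", {
  withr::with_seed(101, {
    n <- 150
    calls <- vapply(runif(80, 0.2, 0.8),
                    function(p) rbinom(n, 2L, p), integer(n))
  })
  res <- index_of_association(toy_geno(calls))
  expect_lt(abs(res$Ia), 0.25)
  expect_lt(abs(res$rbarD), 0.01)
})

test_that("Ia/rbarD are invariant under sample and locus permutation, degenerate inputs error", {
  withr::with_seed(31, {
    calls <- matrix(sample(0:2, 20 * 6, replace = TRUE), 20, 6)
    calls[sample(length(calls), 10)] <- NA
    i_perm <- sample(20)
    j_perm <- sample(6)
  })
  g <- toy_geno(calls)
  base <- index_of_association(g)
  perm <- index_of_association(toy_geno(calls[i_perm, j_perm]))
  expect_equal(perm$Ia, base$Ia, tolerance = 1e-12)
  expect_equal(perm$rbarD, base$rbarD, tolerance = 1e-12)
  expect_lte(base$rbarD, 1)

  # All individuals identical: no variance anywhere.
  expect_error(index_of_association(toy_geno(matrix(1L, 5, 4))),
               class = "ovitherm_validation_error")
  # A single marker leaves rbarD undefined.
  expect_error(
    suppressWarnings(index_of_association(toy_geno(matrix(c(0L, 1L, 2L), 3, 1)))),
    class = "ovitherm_validation_error")
})

test_that("Weir-Cockerham theta hits the two degenerate references", {
  withr::with_seed(8, {
    half <- matrix(rbinom(60 * 80, 2, 0.4), 60, 80)
  })
  same <- toy_geno(rbind(half, half), breed = rep(c("A", "B"), each = 60))
  th <- weir_cockerham_fst(same, "breed")
  expect_lt(abs(th["A", "B"]), 0.01)
  expect_equal(diag(th), c(A = 0, B = 0))

  fixed <- toy_geno(rbind(matrix(0L, 10, 20), matrix(2L, 10, 20)),
                    breed = rep(c("A", "B"), each = 10))
  expect_equal(weir_cockerham_fst(fixed, "breed")["A", "B"], 1)
})

test_that("theta equals the ANOVA sums-of-squares oracle on random instances", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      m <- sample(2:10, 1)
      calls <- matrix(rbinom((n1 + n2) * m, 2,
                             rep(runif(m, 0.1, 0.9), each = n1 + n2)),
                      n1 + n2, m)
      groups <- rep(c("g1", "g2"), c(n1, n2))
      g <- toy_geno(calls, breed = groups)
      th <- weir_cockerham_fst(g, "breed")["g1", "g2"]
      expect_equal(th, oracle_wc_theta(calls, groups), tolerance = 1e-10)
    }
  })
  # Textbook-style pair: HWE genotypes at alt freq 0.9 vs 0.1.
  calls <- cbind(c(hwe_calls(50, 0.9), hwe_calls(50, 0.1)))
  groups <- rep(c("hi", "lo"), each = 50)
  expect_equal(weir_cockerham_fst(toy_geno(calls, breed = groups),
                                  "breed")["hi", "lo"],
               oracle_wc_theta(calls, groups), tolerance = 1e-10)
})

test_that("neighbor joining recovers closed-form and additive trees", {
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  want <- oracle_three_taxon_lengths(d3)   # x=2, y=3, z=7
  tip_len <- tr$edge.length[match(seq_len(3), tr$edge[, 2])]
  expect_equal(sort(tip_len), sort(unname(want)))

  # Additive 4-taxon distances from a known unrooted tree.
  ref <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  dd <- cophenetic(ref)
  rec <- nj_tree(dd)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), rec)), 0)
  expect_equal(sort(cophenetic(rec)[rownames(dd), colnames(dd)][upper.tri(dd)]),
               sort(dd[upper.tri(dd)]), tolerance = 1e-10)

  # Zero matrix -> all branch lengths zero.
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(z)$edge.length == 0))
  expect_error(nj_tree(z[1:2, 1:2]), class = "ovitherm_validation_error")
})

test_that("diversity table covers groups plus total and is internally consistent", {
  withr::with_seed(13, {
    calls <- matrix(rbinom(30 * 40, 2, rep(runif(40, 0.2, 0.8), each = 30)),
                    30, 40)
  })
  g <- toy_geno(calls, breed = rep("only", 30),
                location = rep(c("L1", "L2", "L3"), each = 10))
  tab_b <- diversity_table(g, "breed")
  expect_equal(tab_b$Hexp[1], tab_b$Hexp[2])     # single group == Total
  expect_equal(tab_b$Ia[1], tab_b$Ia[2])

  tab_l <- diversity_table(g, "location")
  expect_equal(sum(tab_l$n[tab_l$group != "Total"]), 30L)
  expect_equal(tab_l$group[nrow(tab_l)], "Total")
  expect_error(diversity_table(g, "no_such_column"),
               class = "ovitherm_validation_error")
})
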