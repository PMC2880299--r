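# polymorphism measures and the four phylogeographic parameters

test_that("polymorphism summary matches direct counts on the worked example", {
  s <- summarizePolymorphism(truth4())
  expect_identical(s$S, 2L)
  expect_identical(s$A_N, 3L)
  expect_identical(s$G_N, 2L)
  expect_identical(s$H_O, 0.5)
  # monomorphic dataset
  mono <- make_truth(rep("AAAA", 4))
  sm <- summarizePolymorphism(mono)
  expect_identical(c(sm$S, sm$A_N, sm$G_N), c(0L, 1L, 1L))
  expect_identical(sm$H_O, 0)
})

test_that("Watterson's theta follows the harmonic-number closed form", {
  th <- wattersonTheta(S = 2, n = 4, L = 3)
  expect_equal(th$theta_locus, 2 / (1 + 1/2 + 1/3), tolerance = 1e-12)
  expect_identical(wattersonTheta(0, 10, 100)$theta_locus, 0)
  th2 <- wattersonTheta(S = 20, n = 100, L = 250)
  expect_equal(th2$theta_site, 20 / sum(1 / 1:99) / 250, tolerance = 1e-12)
  expect_equal(th2$theta_site, 0.015452, tolerance = 1e-4)
  expect_error(wattersonTheta(1, 1, 10), "n >= 2")
})

test_that("nucleotide diversity averages all C(n,2) pairwise differences", {
  pi4 <- nucleotideDiversity(c("AAA", "AAA", "AAT", "ATT"))
  expect_equal(pi4$pi_locus, 7 / 6, tolerance = 1e-12)
  expect_identical(nucleotideDiversity(rep("ACGT", 5))$pi_locus, 0)
  two <- nucleotideDiversity(c(strrep("A", 250),
                               paste0(strrep("A", 249), "T")))
  expect_equal(two$pi_site, 1 / 250, tolerance = 1e-12)
})

test_that("Tajima's D matches hand evaluation and an independent oracle", {
  expect_equal(tajimasD(c("AAA", "AAA", "AAT", "ATT")), 0.5916, tolerance = 1e-3)
  expect_true(is.na(tajimasD(rep("AAAA", 4))))
  # frozen cross-check against an independent reference implementation
  expect_equal(tajimasD(fixture12()), -1.1089810, tolerance = 1e-6)
  expect_equal(nucleotideDiversity(fixture12())$pi_locus, 1.4090909,
               tolerance = 1e-6)
  expect_equal(wattersonTheta(6, 12, 40)$theta_locus, 1.9868357,
               tolerance = 1e-6)
})

test_that("mean Tajima's D is near zero across neutral replicates", {
  cfg <- simulationConfig(n_individuals = 25, locus_length = 100L,
                          ne_haploid = 1000)
  set.seed(99)
  res <- replicate(200, {
    tr <- simulateGeneTree(cfg)
    aln <- evolveAlignment(tr, cfg, scaling = 1e-5)
    m <- phasebias:::.as_base_matrix(aln)
    c(tajimasD(m), nucleotideDiversity(m)$pi_locus,
      wattersonTheta(phasebias:::.count_segregating(m), nrow(m),
                     ncol(m))$theta_locus)
  })
  d <- res[1, ]
  expect_lt(abs(mean(d, na.rm = TRUE)), 3 * sd(d, na.rm = TRUE) / sqrt(sum(!is.na(d))))
  # equilibrium identity E[pi] = E[theta_W]
  diff <- res[2, ] - res[3, ]
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))
})

test_that("Ewens distribution normalises and matches a CRP simulation", {
  for (theta in c(0.5, 2.5, 10)) {
    expect_equal(sum(ewensDistribution(25, theta)), 1, tolerance = 1e-10)
  }
  # Chinese-restaurant-process oracle for P(K >= k)
  n <- 15; theta <- 2
  set.seed(123)
  K <- replicate(4000, {
    k <- 1L
    for (i in 2:n) if (runif(1) < theta / (theta + i - 1)) k <- k + 1L
    k
  })
  pk <- ewensDistribution(n, theta)
  for (k0 in c(3L, 5L, 8L)) {
    p_hat <- mean(K >= k0)
    se <- sqrt(p_hat * (1 - p_hat) / length(K))
    expect_lt(abs(p_hat - sum(pk[k0:n])), 3.5 * se + 1e-9)
  }
})

test_that("Fu's F_S matches the Stirling-number worked example", {
  fs <- fusFS(c("AAA", "AAA", "AAT", "ATT"))
  # theta = 7/6, k_obs = 3: S' = (6 theta^3 + theta^4) / rising(theta, 4)
  theta <- 7 / 6
  sprime <- (6 * theta^3 + theta^4) /
    (theta * (theta + 1) * (theta + 2) * (theta + 3))
  expect_equal(sprime, 0.34121, tolerance = 1e-4)
  expect_equal(as.numeric(fs), log(sprime / (1 - sprime)), tolerance = 1e-10)
  expect_equal(as.numeric(fs), -0.658, tolerance = 1e-3)
  # boundary cases propagate as missing with a reason flag
  mono <- fusFS(rep("AAAA", 4))
  expect_true(is.na(mono))
  expect_identical(attr(mono, "reason"), "theta_hat_zero")
})

test_that("statistics are invariant to sequence order and monotone under removal", {
  seqs <- fixture12()
  set.seed(42)
  perm <- sample(length(seqs))
  expect_equal(tajimasD(seqs), tajimasD(seqs[perm]), tolerance = 1e-12)
  expect_equal(as.numeric(fusFS(seqs)), as.numeric(fusFS(seqs[perm])),
               tolerance = 1e-12)
  # removing a sequence never increases A_N or S
  m <- phasebias:::.as_base_matrix(seqs)
  S_full <- phasebias:::.count_segregating(m)
  A_full <- length(unique(apply(m, 1, paste, collapse = "")))
  for (drop in seq_along(seqs)) {
    m2 <- m[-drop, , drop = FALSE]
    expect_lte(phasebias:::.count_segregating(m2), S_full)
    expect_lte(length(unique(apply(m2, 1, paste, collapse = ""))), A_full)
  }
})

test_that("p-distance matrix is symmetric, zero-diagonal and correct", {
  D <- pDistanceMatrix(c(a = "AAA", b = "ATT", c = "AAA"))
  expect_equal(D["a", "b"], 2 / 3, tolerance = 1e-12)
  expect_identical(D["a", "c"], 0)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  expect_error(pDistanceMatrix(c("AA", "AAA")), "ragged")
})
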