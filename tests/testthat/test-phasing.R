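# the Gibbs phase sampler: candidate enumeration, posterior behaviour,
# replicate selection, thresholding

test_that("candidate enumeration counts 2^(h-1) decompositions", {
  expect_identical(nrow(enumeratePairCandidates("ACGT")), 1L)       # h = 0
  expect_identical(nrow(enumeratePairCandidates("AMGT")), 1L)       # h = 1
  expect_identical(nrow(enumeratePairCandidates("AMRT")), 2L)       # h = 2
  cand3 <- enumeratePairCandidates("MRW")
  expect_identical(nrow(cand3), 4L)                                 # h = 3
  # every candidate collapses back to the observed genotype
  for (r in seq_len(nrow(cand3))) {
    a <- strsplit(cand3$hap1[r], "")[[1]]
    b <- strsplit(cand3$hap2[r], "")[[1]]
    expect_identical(paste(iupacConsensus(a, b), collapse = ""), "MRW")
  }
  expect_error(enumeratePairCandidates(strrep("M", 25)), "cap")
})

test_that("phase-trivial genotypes are resolved with probability 1", {
  g <- c(i1 = "AMGT", i2 = "ACGT", i3 = "ACGT")   # single-site het + homs
  res <- gibbsPhase(g, phasingRunConfig(n_replicates = 1), seed = 4)
  b <- bestPairs(res)
  expect_true(all(b$prob == 1))
  expect_identical(sort(c(b$hap1[1], b$hap2[1])), c("AAGT", "ACGT"))
  expect_identical(goodnessOfFit(res), 1)
})

test_that("sampled posterior matches the exhaustive-enumeration oracle", {
  # one 2-site heterozygote among fixed homozygotes: the chain draws i.i.d.
  # from the exact conditional, which we enumerate independently here
  g <- c(h1 = "AAAA", h2 = "AAAA", h3 = "AAAA", h4 = "CGAA", h5 = "CGAA",
         amb = "MRAA")
  cfg <- phasingRunConfig(n_replicates = 1, main_iterations = 2000)
  res <- gibbsPhase(g, cfg, seed = 7)
  po <- posteriors(res)[["amb"]]
  # oracle: pi(x|H) = sum_k n_k g(d) / n, g(d) = (1-q) q^d (d <= 2)
  n2 <- 12; S <- 2; L <- 4
  theta <- S / sum(1 / seq_len(n2 - 1)) / 1   # per locus
  q <- theta / (n2 + theta)
  g_d <- function(d) if (d <= 2) (1 - q) * q^d else 0
  pool <- c(AAAA = 6, CGAA = 4)   # the 10 fixed haplotypes
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  pi_hat <- function(x, extra = NULL) {
    hs <- c(pool, if (!is.null(extra)) setNames(1, extra))
    tot <- sum(hs)
    sum(vapply(names(hs), function(h) hs[[h]] * g_d(hd(h, x)), 0)) / tot
  }
  w <- c(pi_hat("AAAA") * pi_hat("CGAA", "AAAA"),
         pi_hat("AGAA") * pi_hat("CAAA", "AGAA"))
  oracle <- w[1] / sum(w)
  p_best <- po$prob[po$hap1 == "AAAA" | po$hap2 == "AAAA"][1]
  mc_se <- sqrt(oracle * (1 - oracle) / res@nSamples)
  expect_lt(abs(p_best - oracle), 3 * mc_se + 1e-6)
})

test_that("every sampled pair collapses to its observed genotype and sums to 1", {
  cfg <- small_sim_config(n_individuals = 10L, seed = 61)
  tr <- simulateGeneTree(cfg, seed = 62)
  aln <- evolveAlignment(tr, cfg, scaling = 1.5e-5, seed = 63)
  ag <- assembleGenotypes(aln, seed = 64)
  res <- gibbsPhase(ag$genotypes, phasingRunConfig(n_replicates = 1), seed = 65)
  gs <- as.character(ag$genotypes)
  for (id in names(posteriors(res))) {
    po <- posteriors(res)[[id]]
    expect_equal(sum(po$prob), 1, tolerance = 1e-9)
    for (r in seq_len(nrow(po))) {
      a <- strsplit(po$hap1[r], "")[[1]]
      b <- strsplit(po$hap2[r], "")[[1]]
      expect_identical(paste(iupacConsensus(a, b), collapse = ""), gs[[id]])
    }
  }
})

test_that("alleles anchored by homozygotes are phased accurately", {
  # every allele of the heterozygotes also occurs in a homozygote
  g <- c(x1 = "AAAA", x2 = "AAAA", x3 = "AAAA",
         y1 = "CCAA", y2 = "CCAA", y3 = "CCAA",
         z1 = "MMAA", z2 = "MMAA")
  res <- gibbsPhase(g, phasingRunConfig(n_replicates = 1), seed = 19)
  for (id in c("z1", "z2")) {
    b <- bestPairs(res)
    row <- b[b$individual == id, ]
    expect_identical(sort(c(row$hap1, row$hap2)), c("AAAA", "CCAA"))
    expect_gt(row$prob, 0.9)
  }
})

test_that("same seed gives identical posteriors; different seeds may differ", {
  g <- c(h1 = "AAAA", h2 = "AAAA", h3 = "CGAA", h4 = "CGAA", amb = "MRAA",
         amb2 = "MRWA")
  cfg <- phasingRunConfig(n_replicates = 1, main_iterations = 200)
  r1 <- gibbsPhase(g, cfg, seed = 5)
  r2 <- gibbsPhase(g, cfg, seed = 5)
  expect_identical(posteriors(r1), posteriors(r2))
})

test_that("the best replicate wins and ties break reproducibly", {
  mk <- function(goodness, seed, prob = goodness) {
    po <- list(i1 = data.frame(hap1 = c("AA", "AT"), hap2 = c("TT", "TA"),
                               prob = c(prob, 1 - prob)))
    best <- data.frame(individual = "i1", hap1 = "AA", hap2 = "TT",
                       prob = prob, n_het = 2L)
    methods::new("PhasingResult", posteriors = po, best = best,
                 seed = as.integer(seed), goodness = goodness,
                 nSamples = 500L, theta = 1)
  }
  expect_identical(selectBestReplicate(list(mk(0.8, 1)))@seed, 1L)
  expect_identical(selectBestReplicate(list(mk(0.8, 1), mk(0.9, 2)))@seed, 2L)
  expect_error(selectBestReplicate(list()), "no replicates")
  # exact 0.5/0.5 tie: seeded draw, reproducible
  tied <- mk(0.5, 3, prob = 0.5)
  pick1 <- selectBestReplicate(list(tied), seed = 11)@best
  pick2 <- selectBestReplicate(list(tied), seed = 11)@best
  expect_identical(pick1, pick2)
})

test_that("thresholding uses the >= boundary and is monotone across levels", {
  g <- c(h1 = "AAAA", h2 = "AAAA", h3 = "CGAA", h4 = "CGAA", amb = "MRAA",
         amb2 = "MRWA")
  res <- gibbsPhase(g, phasingRunConfig(n_replicates = 1), seed = 8)
  # exact-boundary rule on a scripted result
  res@best$prob[res@best$individual == "amb"] <- 0.90
  thr <- applyConfidenceThreshold(res, 0.90)
  expect_true("amb" %in% resolvedIds(thr))
  t90 <- applyConfidenceThreshold(res, 0.90)
  t60 <- applyConfidenceThreshold(res, 0.60)
  expect_true(all(unresolvedIds(t60) %in% unresolvedIds(t90)))
  expect_setequal(c(resolvedIds(t90), unresolvedIds(t90)),
                  c("amb", "amb2"))
  expect_error(applyConfidenceThreshold(res, 0), "threshold")
})

test_that("cross-replicate agreement reports a sensible numeric summary", {
  g <- c(x1 = "AAAA", x2 = "AAAA", x3 = "CCAA", x4 = "CCAA",
         z1 = "MMAA", z2 = "MMAA")
  reps <- phaseReplicates(g, phasingRunConfig(n_replicates = 3), seed = 2)
  agr <- crossReplicateAgreement(reps)
  expect_true(agr$agreement >= 0 && agr$agreement <= 1)
  expect_gte(agr$mean_prob_range, 0)
})
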