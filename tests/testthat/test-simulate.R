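# coalescent simulator, HKY evolution, genotype assembly, suite generation

test_that("gene trees have the Kingman shape and are reproducible", {
  cfg <- simulationConfig(n_individuals = 50)
  tr <- simulateGeneTree(cfg, seed = 3)
  expect_identical(ape::Ntip(tr), 100L)
  expect_identical(tr$Nnode, 99L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  tr2 <- simulateGeneTree(cfg, seed = 3)
  expect_identical(tr$edge, tr2$edge)
  expect_identical(tr$edge.length, tr2$edge.length)
  expect_error(simulateGeneTree(simulationConfig(ne_haploid = -1)),
               "positive")
})

test_that("pairwise TMRCA matches the analytic haploid expectation E[T2] = Ne", {
  cfg <- simulationConfig(n_individuals = 1, ne_haploid = 1000)
  set.seed(11)
  tm <- replicate(2000, {
    tr <- simulateGeneTree(cfg)
    sum(tr$edge.length) / 2
  })
  expect_lt(abs(mean(tm) - 1000) / 1000, 0.05)
})

test_that("HKY85 evolution hits the stationary base composition", {
  cfg <- simulationConfig(n_individuals = 1, locus_length = 100000L)
  # one extremely long branch: tip composition ~ equilibrium frequencies
  tr <- ape::read.tree(text = "(t1:0,t2:5000000);")
  aln <- evolveAlignment(tr, cfg, scaling = 1e-5, seed = 21)
  bases <- strsplit(as.character(aln[["t2"]]), "")[[1]]
  freq <- table(factor(bases, levels = c("A", "C", "G", "T"))) / length(bases)
  expect_true(all(abs(freq - c(0.30, 0.20, 0.15, 0.35)) < 0.01))
})

test_that("observed transition:transversion ratio is consistent with 2.5", {
  cfg <- simulationConfig(n_individuals = 1, locus_length = 1000000L)
  tr <- ape::read.tree(text = "(t1:0,t2:5000);")   # 0.05 expected subs/site
  aln <- evolveAlignment(tr, cfg, scaling = 1e-5, seed = 22)
  m <- phasebias:::.as_base_matrix(aln)
  d <- which(m[1, ] != m[2, ])
  pur <- c("A", "G")
  ts <- sum((m[1, d] %in% pur) == (m[2, d] %in% pur))
  tv <- length(d) - ts
  expect_gt(length(d), 10000)
  # ~4 Monte-Carlo SEs plus a little multiple-hit attenuation at this depth
  expect_lt(abs(ts / tv - 2.5), 0.12)
})

test_that("zero substitution rate returns the root sequence everywhere", {
  cfg <- simulationConfig(n_individuals = 3, locus_length = 50L)
  tr <- simulateGeneTree(cfg, seed = 5)
  aln <- evolveAlignment(tr, cfg, scaling = 0, seed = 6)
  expect_identical(length(unique(as.character(aln))), 1L)
})

test_that("random pairing collapses to lossless IUPAC consensus", {
  ag <- assembleGenotypes(c("ACGT", "ACGA", "ACGT", "ACGT"), seed = 2)
  expect_identical(nrow(ag$pairing), 2L)
  # the W individual must carry exactly the A/T ambiguity at position 4
  gs <- as.character(ag$genotypes)
  het_ind <- grep("W", gs)
  expect_length(het_ind, 1L)
  expect_identical(unname(substr(gs[het_ind], 1, 3)), "ACG")
  expect_error(assembleGenotypes(c("ACG", "ACG", "ACG")), "odd")
})

test_that("collapsing the two true alleles reproduces the stored genotype", {
  cfg <- small_sim_config(seed = 9)
  tr <- simulateGeneTree(cfg, seed = 31)
  aln <- evolveAlignment(tr, cfg, scaling = 1e-5, seed = 32)
  ag <- assembleGenotypes(aln, seed = 33)
  ds <- newTruthDataset(ag$alleles, ag$pairing, ag$genotypes)
  m <- phasebias:::.as_base_matrix(alleles(ds))
  p <- pairing(ds)
  for (i in seq_len(nrow(p))) {
    recon <- paste(iupacConsensus(m[p$allele_a[i], ], m[p$allele_b[i], ]),
                   collapse = "")
    expect_identical(recon,
                     as.character(consensusGenotypes(ds)[[p$individual[i]]]))
  }
})

test_that("suite generation fills every S target and is byte-reproducible", {
  cfg <- small_sim_config(seed = 101)
  suite <- generateSuite(cfg)
  mf <- attr(suite, "manifest")
  expect_identical(nrow(mf), 4L)
  expect_identical(sort(mf$S), c(2L, 2L, 4L, 4L))
  # realised S recomputed by the popgen module equals the label
  for (ds in suite) {
    expect_identical(summarizePolymorphism(ds)$S, provenance(ds)$s_target)
  }
  suite2 <- generateSuite(cfg)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  writeFastaAlignment(alleles(suite[[1]]), f1)
  writeFastaAlignment(alleles(suite2[[1]]), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # vacuous request
  empty <- generateSuite(simulationConfig(replicates_per_target = 0, seed = 1))
  expect_length(empty, 0L)
  # unreachable target fails naming it
  cfg_bad <- small_sim_config(seed = 1)
  cfg_bad$s_targets <- 59L   # more segregating sites than plausible at L=60
  cfg_bad$replicates_per_target <- 1L
  cfg_bad$max_attempts <- 25L
  expect_error(generateSuite(cfg_bad), "59")
})

test_that("Watterson estimator is calibrated on unconditioned simulations", {
  # theta = 2 * Ne * scaling * L = 2; 200 replicates, n = 50 alleles
  cfg <- simulationConfig(n_individuals = 25, locus_length = 100L,
                          ne_haploid = 1000)
  set.seed(77)
  th <- replicate(200, {
    tr <- simulateGeneTree(cfg)
    aln <- evolveAlignment(tr, cfg, scaling = 1e-5)
    m <- phasebias:::.as_base_matrix(aln)
    wattersonTheta(phasebias:::.count_segregating(m), nrow(m),
                   ncol(m))$theta_locus
  })
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 2), 3 * se)
})

test_that("H_O equals the heterozygote proportion and lies in [0, 1]", {
  ds <- truth4()
  s <- summarizePolymorphism(ds)
  expect_identical(s$H_O, 0.5)
  cfg <- small_sim_config(seed = 15)
  tr <- simulateGeneTree(cfg, seed = 51)
  aln <- evolveAlignment(tr, cfg, scaling = 1e-5, seed = 52)
  ag <- assembleGenotypes(aln, seed = 53)
  ds2 <- newTruthDataset(ag$alleles, ag$pairing, ag$genotypes)
  m <- phasebias:::.as_base_matrix(alleles(ds2))
  p <- pairing(ds2)
  hets <- sum(vapply(seq_len(nrow(p)), function(i)
    any(m[p$allele_a[i], ] != m[p$allele_b[i], ]), TRUE))
  s2 <- summarizePolymorphism(ds2)
  expect_equal(s2$H_O, hets / nrow(p))
  expect_true(s2$H_O >= 0 && s2$H_O <= 1)
})
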