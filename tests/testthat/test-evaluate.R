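# error taxonomy, unresolved accounting, lost alleles, configurations,
# divergence skew

test_that("error classification covers the published taxonomy", {
  known <- c("AA", "TT", "AT")
  expect_identical(classifyError(c("AA", "TT"), c("AA", "TT"), known),
                   "CORRECT")
  expect_identical(classifyError(c("AA", "TT"), c("TT", "AA"), known),
                   "CORRECT")
  # one misidentified (AT exists), one novel (TA does not)
  expect_identical(classifyError(c("AA", "TT"), c("AT", "TA"), known),
                   "E_MIS_NOV")
  expect_identical(classifyError(c("AA", "TT"), c("AT", "TA"),
                                 c(known, "TA")), "E_MIS_MIS")
  expect_identical(classifyError(c("AA", "TT"), c("AA", "AT"), known),
                   "E_COR_MIS")
  expect_identical(classifyError(c("AA", "TT"), c("AA", "GG"), known),
                   "E_COR_NOV")
  expect_identical(classifyError(c("AA", "TT"), c("GG", "CC"), known),
                   "E_NOV_NOV")
  expect_error(classifyError(c("AA", "TT"), c("A", "T"), known), "mismatch")
})

test_that("complement-consistent pairs can never be E_COR_*", {
  # property: if the inferred pair collapses to the same genotype as the
  # true pair, a correct haplotype forces a correct complement
  set.seed(31)
  for (rep in 1:200) {
    L <- 6
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    b <- a
    het <- sample.int(L, 3)
    for (v in het) b[v] <- sample(setdiff(c("A", "C", "G", "T"), a[v]), 1)
    truth <- c(paste(a, collapse = ""), paste(b, collapse = ""))
    # random consistent decomposition
    x <- a; y <- b
    for (v in het) if (runif(1) < 0.5) { tmp <- x[v]; x[v] <- y[v]; y[v] <- tmp }
    inferred <- c(paste(x, collapse = ""), paste(y, collapse = ""))
    known <- unique(c(truth, replicate(3, paste(sample(c("A", "C", "G", "T"),
                                                       L, replace = TRUE),
                                                collapse = ""))))
    cls <- classifyError(truth, inferred, known)
    expect_true(cls %in% c("CORRECT", "E_MIS_MIS", "E_MIS_NOV", "E_NOV_NOV"))
  }
})

test_that("dataset evaluation matches a hand-enumerated fixture", {
  # 5 individuals: i1 correct above threshold; i2 wrong above threshold
  # (E_MIS_NOV); i3 correct below; i4 wrong below (E_MIS_MIS); i5 correct
  # above
  seqs <- c("AATT", "TTTT",   # i1
            "AAAA", "TTTT",   # i2
            "AATT", "TTAA",   # i3
            "AAAA", "AATT",   # i4
            "AAAA", "TTAA")   # i5
  ds <- make_truth(seqs)
  calls <- make_calls(data.frame(
    individual = c("i1", "i2", "i3", "i4", "i5"),
    hap1 = c("AATT", "AATT", "AATT", "AATT", "AAAA"),
    hap2 = c("TTTT", "TTAA", "TTAA", "TTAA", "TTAA"),
    prob = c(0.99, 0.95, 0.70, 0.55, 0.93),
    n_het = c(2L, 4L, 4L, 2L, 2L),
    stringsAsFactors = FALSE), threshold = 0.90)
  ev <- evaluateDataset(ds, calls)
  ct <- evalCounts(ev)
  expect_identical(ct[["n_ambiguous"]], 5L)
  expect_identical(ct[["n_err"]], 1L)
  expect_identical(ct[["n_lcp"]], 2L)
  expect_identical(ct[["n_lcp_correct"]], 1L)
  expect_identical(ct[["n_lcp_incorrect"]], 1L)
  expect_equal(proportionUnresolved(ev), 2 / 5)
  cc <- errorClassCounts(ev)
  expect_identical(cc["E_MIS_MIS", "err"], 1L)   # i2: AATT & TTAA both exist
  expect_identical(sum(cc[, "lcp_incorrect"]), 1L)
  # unresolved individual not present in truth errors out
  bad <- make_calls(data.frame(individual = "ghost", hap1 = "AAAA",
                               hap2 = "AAAA", prob = 0.5, n_het = 2L,
                               stringsAsFactors = FALSE), 0.9)
  expect_error(evaluateDataset(ds, bad), "ghost")
})

test_that("lost alleles are exactly those confined to unresolved individuals", {
  seqs <- c("AAAA", "CCCC",   # i1 het, singleton CCCC
            "AAAA", "AAAA",   # i2 hom
            "GGGG", "AAAA")   # i3 het, singleton GGGG
  ds <- make_truth(seqs)
  res <- findLostAlleles(ds, "i1")
  expect_identical(res$n_lost, 1L)
  expect_identical(res$lost_alleles, "CCCC")
  # allele also in a resolved homozygote is not lost
  expect_identical(findLostAlleles(ds, "i2")$n_lost, 0L)
  expect_identical(findLostAlleles(ds, character(0))$n_lost, 0L)
  # monotone: adding an unresolved individual never decreases losses
  expect_gte(findLostAlleles(ds, c("i1", "i3"))$n_lost,
             findLostAlleles(ds, "i1")$n_lost)
  # definitional audit: every lost allele's copies are all unresolved
  la <- findLostAlleles(ds, c("i1", "i3"))
  m <- phasebias:::.as_base_matrix(alleles(ds))
  seqv <- apply(m, 1, paste, collapse = "")
  owner <- setNames(rep(pairing(ds)$individual, 2),
                    c(pairing(ds)$allele_a, pairing(ds)$allele_b))
  for (al in la$lost_alleles) {
    expect_true(all(owner[names(seqv)[seqv == al]] %in% c("i1", "i3")))
  }
})

test_that("configuration profiles order frequencies and flag rare alleles", {
  # 2N = 10 copies: AAAA x6 (0.6), CCCC x1 (0.1), GGGG x2, TTTT x1
  seqs <- c("AAAA", "CCCC",
            "AAAA", "AAAA",
            "GGGG", "GGGG",
            "AAAA", "TTTT",
            "AAAA", "AAAA")
  ds <- make_truth(seqs)
  cp <- configurationProfile(ds, c("i1", "i4"))
  expect_identical(nrow(cp), 2L)
  r1 <- cp[cp$individual == "i1", ]
  expect_equal(r1$freq_common, 0.6)
  expect_equal(r1$freq_rare, 0.1)
  expect_true(r1$rare_is_singleton)
  expect_false(r1$rare_is_rare)       # 0.1 >= 0.05 in this small sample
  expect_identical(nrow(configurationProfile(ds, character(0))), 0L)
})

test_that("divergence skew matches hand arithmetic and symmetry", {
  # star-like: all pairwise distances equal -> difference 0
  star <- make_truth(c("AAAA", "CCAA", "AAAA", "AACC", "CCAA", "AACC"))
  la <- findLostAlleles(star, "i2")    # loses nothing (all alleles shared)
  expect_identical(la$n_lost, 0L)
  d0 <- divergenceSkew(star, character(0))
  expect_true(is.na(d0$difference))
  # hand-computed 4-allele toy
  seqs <- c(h1 = "AAAA", h2 = "AAAT", h3 = "AATT", h4 = "TTTT")
  ds <- make_truth(c(seqs[1], seqs[1], seqs[2], seqs[3], seqs[4], seqs[4]))
  D <- pDistanceMatrix(seqs)
  p_dataset <- mean(D[upper.tri(D)])
  p_lost <- mean(D["h4", c("h1", "h2", "h3")])
  sk <- divergenceSkew(ds, "TTTT")
  expect_equal(sk$p_dataset, p_dataset, tolerance = 1e-12)
  expect_equal(sk$difference, p_lost - p_dataset, tolerance = 1e-12)
  # a maximally divergent lost allele gives a positive difference
  expect_gt(sk$difference, 0)
})

test_that("het-site/error correlation follows the textbook formula", {
  rec <- data.frame(n_het = rep(c(2, 3, 4, 5), each = 4),
                    error = c(1,1,1,0, 1,1,0,0, 1,0,0,0, 0,0,0,0))
  out <- hetErrorRelationship(rec)
  expect_equal(out$r, cor(c(2, 3, 4, 5), c(0.75, 0.5, 0.25, 0)),
               tolerance = 1e-12)
  expect_equal(out$r, -1, tolerance = 1e-12)
  # constant error proportion -> undefined
  flat <- data.frame(n_het = rep(c(2, 3, 4), each = 2), error = rep(TRUE, 6))
  expect_true(is.na(hetErrorRelationship(flat)$r))
})

test_that("pooled rates reproduce the published false-positive arithmetic", {
  expect_identical(round(pooledErrorRate(5, 1077), 1), 0.5)
  expect_identical(round(pooledErrorRate(9, 1077), 1), 0.8)
  expect_identical(round(pooledErrorRate(3, 126), 1), 2.4)
})
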