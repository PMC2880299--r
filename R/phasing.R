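# Bayesian phase resolution of ambiguity-coded genotypes: candidate
# enumeration, the Gibbs sampler wrapper, replicate selection, thresholding.

#' Phasing run configuration
#'
#' Run protocol defaults follow common practice for confidence-scored
#' phasing of population datasets: 500 burn-in iterations, 500 main
#' iterations, thinning interval 1, three replicate runs with different
#' seeds, and confidence thresholds 0.90 (the usual software default) and
#' 0.60.
#'
#' @param burn_in,main_iterations,thinning MCMC schedule (all positive).
#' @param n_replicates number of independent replicate runs (default 3).
#' @param thresholds confidence probability cut-offs in (0, 1].
#' @param theta_mode either \code{"watterson"} (per-locus Watterson estimate
#'   from the dataset being phased, recomputed once before sampling) or a
#'   positive number used directly.
#' @param trunc_steps truncation of the mutation kernel: haplotypes more
#'   than this many steps from every existing haplotype get conditional
#'   probability 0 (default 2).
#' @param cap_enumeration refuse exhaustive candidate enumeration above this
#'   many heterozygous sites (default 20).
#' @param cap_pair_sampling individuals with up to this many free phase bits
#'   (h - 1) are Gibbs-updated by whole-pair enumeration; larger ones are
#'   updated site-by-site (default 10).
#' @return a validated list of class \code{PhasingRunConfig}.
#' @export
phasingRunConfig <- function(burn_in = 500L, main_iterations = 500L,
                             thinning = 1L, n_replicates = 3L,
                             thresholds = c(0.90, 0.60),
                             theta_mode = "watterson",
                             trunc_steps = 2L, cap_enumeration = 20L,
                             cap_pair_sampling = 10L) {
  stopifnot(burn_in >= 0, main_iterations >= 1, thinning >= 1,
            n_replicates >= 1, trunc_steps >= 0)
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  if (is.numeric(theta_mode) && theta_mode <= 0)
    stop("numeric theta_mode must be positive")
  cfg <- list(burn_in = as.integer(burn_in),
              main_iterations = as.integer(main_iterations),
              thinning = as.integer(thinning),
              n_replicates = as.integer(n_replicates),
              thresholds = thresholds, theta_mode = theta_mode,
              trunc_steps = as.integer(trunc_steps),
              cap_enumeration = as.integer(cap_enumeration),
              cap_pair_sampling = as.integer(cap_pair_sampling))
  class(cfg) <- "PhasingRunConfig"
  cfg
}

# decode a set of consensus genotypes into the structures the sampler needs
.parse_genotypes <- function(genotypes) {
  if (is(genotypes, "TruthDataset")) genotypes <- consensusGenotypes(genotypes)
  gm <- .as_base_matrix(genotypes)
  if (is.null(rownames(gm)))
    rownames(gm) <- paste0("ind", seq_len(nrow(gm)))
  dec <- .decode_genotype_matrix(gm)
  # variable columns: more than one base in the union of possible states
  nstates <- vapply(seq_len(ncol(gm)), function(j)
    length(unique(c(dec$baseA[, j], dec$baseB[, j]))), 0L)
  vcols <- which(nstates > 1L)
  list(gm = gm, baseA = dec$baseA, baseB = dec$baseB, het = dec$het,
       vcols = vcols, individuals = rownames(gm))
}

#' Enumerate all candidate haplotype pairs of an ambiguous genotype
#'
#' A genotype heterozygous at h sites admits 2^(h-1) distinct unordered
#' decompositions into a haplotype pair (1 when h <= 1); each candidate
#' collapses back to the observed genotype.
#'
#' @param genotype one consensus sequence (character scalar or
#'   \code{DNAString}); only two-base ambiguity codes are legal.
#' @param cap refuse exhaustive enumeration above this many heterozygous
#'   sites (default 20): such individuals are handled in sampler-only mode.
#' @return data.frame with columns \code{hap1}, \code{hap2}.
#' @examples
#' enumeratePairCandidates("AMR")  # het at 2 sites -> 2 candidate pairs
#' @export
enumeratePairCandidates <- function(genotype, cap = 20L) {
  g <- strsplit(toupper(as.character(genotype)), "")[[1L]]
  gm <- matrix(g, nrow = 1L, dimnames = list("g", NULL))
  dec <- .decode_genotype_matrix(gm)
  het <- which(dec$het[1L, ])
  h <- length(het)
  if (h > cap)
    stop("genotype has ", h, " heterozygous sites (> cap = ", cap,
         "); exhaustive enumeration refused, use the sampler")
  if (h <= 1L) {
    return(data.frame(hap1 = paste(dec$baseA[1L, ], collapse = ""),
                      hap2 = paste(dec$baseB[1L, ], collapse = ""),
                      stringsAsFactors = FALSE))
  }
  nc <- 2L^(h - 1L)
  hap1 <- character(nc)
  hap2 <- character(nc)
  for (mask in 0:(nc - 1L)) {
    a <- dec$baseA[1L, ]
    b <- dec$baseB[1L, ]
    for (s in seq_len(h - 1L)) {
      if (bitwAnd(bitwShiftR(mask, s - 1L), 1L) == 1L) {
        v <- het[s + 1L]
        tmp <- a[v]; a[v] <- b[v]; b[v] <- tmp
      }
    }
    hap1[mask + 1L] <- paste(a, collapse = "")
    hap2[mask + 1L] <- paste(b, collapse = "")
  }
  data.frame(hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
}

#' Gibbs-sample haplotype phase for a set of ambiguity-coded genotypes
#'
#' Runs one replicate of the phase sampler. Each sweep updates every
#' multi-site heterozygote i by drawing a pair (x, complement) with
#' probability proportional to pi(x | H_-i) * pi(complement | H_-i + x),
#' where pi(. | H) is an approximate coalescent conditional: a mixture over
#' the current haplotypes of the other individuals with a geometric-in-theta
#' per-site mutation kernel, truncated at \code{trunc_steps} mutation steps.
#' Pair probabilities are posterior frequencies over the retained
#' post-burn-in samples. Homozygotes and single-site heterozygotes are
#' phase-trivial and fixed with probability 1.
#'
#' @param genotypes \code{DNAStringSet} / named character vector of consensus
#'   genotypes, or a \code{\linkS4class{TruthDataset}} (its consensus
#'   genotypes are used).
#' @param config a \code{\link{phasingRunConfig}}.
#' @param seed integer seed for this replicate.
#' @return a \code{\linkS4class{PhasingResult}}.
#' @examples
#' g <- c(i1 = "AMRT", i2 = "ACAT", i3 = "ACAT")
#' res <- gibbsPhase(g, phasingRunConfig(n_replicates = 1), seed = 1)
#' bestPairs(res)
#' @export
gibbsPhase <- function(genotypes, config = phasingRunConfig(), seed = 1L) {
  p <- .parse_genotypes(genotypes)
  N <- nrow(p$gm)
  if (N < 1L) stop("need at least one individual")
  L <- ncol(p$gm)
  V <- p$vcols
  S <- length(V)
  n2 <- 2L * N
  theta <- if (is.numeric(config$theta_mode)) config$theta_mode
           else wattersonTheta(S, n2, L)$theta_locus
  q <- theta / (n2 + theta)

  code <- function(mat) {
    out <- matrix(match(mat[, V, drop = FALSE], .BASES) - 1L, nrow = N)
    out
  }
  baseAi <- code(p$baseA)
  baseBi <- code(p$baseB)
  hetSites <- lapply(seq_len(N), function(i)
    as.integer(which(p$het[i, V]) - 1L))
  nhet <- vapply(hetSites, length, 0L)

  full_seq <- function(i, vchars) {
    s <- p$baseA[i, ]
    if (S > 0L) s[V] <- vchars
    paste(s, collapse = "")
  }

  posteriors <- vector("list", N)
  names(posteriors) <- p$individuals
  # phase-trivial individuals: the single candidate with probability 1
  for (i in which(nhet <= 1L)) {
    h1 <- paste(p$baseA[i, ], collapse = "")
    h2 <- paste(p$baseB[i, ], collapse = "")
    posteriors[[i]] <- data.frame(hap1 = min(h1, h2), hap2 = max(h1, h2),
                                  prob = 1, stringsAsFactors = FALSE)
  }

  if (any(nhet >= 2L)) {
    if (S == 0L) stop("internal error: heterozygotes without variable columns")
    set.seed(seed)
    raw <- .gibbs_phase_cpp(baseAi, baseBi, hetSites,
                            config$burn_in, config$main_iterations,
                            config$thinning, q, config$trunc_steps,
                            config$cap_pair_sampling)
    if (length(raw$ambiguous) > 0L && length(raw$samples[[1L]]$counts) == 0L)
      stop("empty retained sample")
    for (j in seq_along(raw$ambiguous)) {
      i <- raw$ambiguous[j] + 1L
      keys <- raw$samples[[j]]$keys
      counts <- raw$samples[[j]]$counts
      halves <- strsplit(keys, "|", fixed = TRUE)
      to_chars <- function(enc) .BASES[utf8ToInt(enc) - utf8ToInt("0") + 1L]
      h1 <- vapply(halves, function(kk) full_seq(i, to_chars(kk[1L])), "")
      h2 <- vapply(halves, function(kk) full_seq(i, to_chars(kk[2L])), "")
      a <- pmin(h1, h2)
      b <- pmax(h1, h2)
      df <- data.frame(hap1 = a, hap2 = b, prob = counts / sum(counts),
                       stringsAsFactors = FALSE)
      df <- df[order(-df$prob, df$hap1, df$hap2), , drop = FALSE]
      rownames(df) <- NULL
      posteriors[[i]] <- df
    }
  }

  best <- do.call(rbind, lapply(seq_len(N), function(i) {
    top <- posteriors[[i]][1L, ]
    data.frame(individual = p$individuals[i], hap1 = top$hap1,
               hap2 = top$hap2, prob = top$prob, n_het = nhet[i],
               stringsAsFactors = FALSE)
  }))
  amb <- nhet >= 2L
  goodness <- if (any(amb)) mean(best$prob[amb]) else 1
  new("PhasingResult", posteriors = posteriors, best = best,
      seed = as.integer(seed), goodness = goodness,
      nSamples = as.integer(config$main_iterations %/% config$thinning),
      theta = theta)
}

#' Run replicate phasing chains
#'
#' Convenience wrapper: runs \code{config$n_replicates} chains with seeds
#' \code{seed, seed + 1, ...} (the different-starting-seed protocol).
#'
#' @inheritParams gibbsPhase
#' @param seed base seed; replicate r uses \code{seed + r - 1}.
#' @return list of \code{\linkS4class{PhasingResult}}.
#' @export
phaseReplicates <- function(genotypes, config = phasingRunConfig(),
                            seed = 1L) {
  lapply(seq_len(config$n_replicates), function(r)
    gibbsPhase(genotypes, config, seed = seed + r - 1L))
}

#' Select the best replicate run
#'
#' Returns the replicate with the best goodness-of-fit (mean best-pair
#' posterior over multi-site heterozygotes); ties go to the lowest seed.
#' Within the selected replicate, per-individual ties among equally probable
#' best pairs are broken by a seeded random choice, so the returned best
#' pair is reproducible.
#'
#' @param replicates list of \code{\linkS4class{PhasingResult}}.
#' @param seed seed for the tie-breaking draws.
#' @return the selected \code{\linkS4class{PhasingResult}} (its \code{best}
#'   slot updated by any tie-break draws).
#' @export
selectBestReplicate <- function(replicates, seed = 1L) {
  if (length(replicates) == 0L) stop("no replicates supplied")
  good <- vapply(replicates, goodnessOfFit, 0)
  seeds <- vapply(replicates, function(r) r@seed, 0L)
  top <- which(good == max(good))
  pick <- top[which.min(seeds[top])]
  res <- replicates[[pick]]
  set.seed(seed)
  for (i in seq_along(res@posteriors)) {
    po <- res@posteriors[[i]]
    ties <- which(abs(po$prob - po$prob[1L]) < 1e-12)
    if (length(ties) > 1L) {
      j <- ties[sample.int(length(ties), 1L)]
      res@best[i, c("hap1", "hap2", "prob")] <-
        po[j, c("hap1", "hap2", "prob")]
    }
  }
  res
}

#' Numeric cross-replicate agreement report
#'
#' Fraction of multi-site heterozygotes whose best pair is identical in
#' every replicate, plus the mean absolute spread of their confidence
#' probabilities across replicates.
#'
#' @param replicates list of \code{\linkS4class{PhasingResult}}.
#' @return list with \code{agreement} and \code{mean_prob_range}.
#' @export
crossReplicateAgreement <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  bests <- lapply(replicates, bestPairs)
  amb <- bests[[1L]]$n_het >= 2L
  if (!any(amb)) return(list(agreement = 1, mean_prob_range = 0))
  keys <- vapply(bests, function(b) .pair_key(b$hap1, b$hap2)[amb],
                 character(sum(amb)))
  keys <- matrix(keys, nrow = sum(amb))
  same <- apply(keys, 1L, function(kk) length(unique(kk)) == 1L)
  probs <- vapply(bests, function(b) b$prob[amb], numeric(sum(amb)))
  probs <- matrix(probs, nrow = sum(amb))
  list(agreement = mean(same),
       mean_prob_range = mean(apply(probs, 1L, function(z) diff(range(z)))))
}

#' Partition multi-site heterozygotes at a confidence threshold
#'
#' Individuals whose best-pair posterior probability is at or above the
#' threshold are resolved; the rest are unresolved (below-threshold). The
#' boundary counts as resolved.
#'
#' @param result a \code{\linkS4class{PhasingResult}}.
#' @param threshold confidence probability in (0, 1].
#' @return a \code{\linkS4class{ThresholdedResult}}.
#' @export
applyConfidenceThreshold <- function(result, threshold) {
  stopifnot(is(result, "PhasingResult"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  b <- bestPairs(result)
  calls <- b[b$n_het >= 2L, , drop = FALSE]
  calls$resolved <- calls$prob >= threshold
  rownames(calls) <- NULL
  new("ThresholdedResult", threshold = threshold, calls = calls)
}

#' Phase one dataset end to end
#'
#' Replicate runs, best-replicate selection and thresholding in one call.
#'
#' @inheritParams gibbsPhase
#' @param seed base seed for the replicates and tie-breaks.
#' @return list with \code{result} (selected
#'   \code{\linkS4class{PhasingResult}}), \code{replicates},
#'   \code{agreement} (see \code{\link{crossReplicateAgreement}}) and
#'   \code{thresholded}: a named list of
#'   \code{\linkS4class{ThresholdedResult}}, one per configured threshold.
#' @export
phaseDataset <- function(genotypes, config = phasingRunConfig(), seed = 1L) {
  reps <- phaseReplicates(genotypes, config, seed = seed)
  sel <- selectBestReplicate(reps, seed = seed)
  thr <- lapply(config$thresholds, function(t)
    applyConfidenceThreshold(sel, t))
  names(thr) <- sprintf("%.2f", config$thresholds)
  list(result = sel, replicates = reps,
       agreement = crossReplicateAgreement(reps), thresholded = thr)
}
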