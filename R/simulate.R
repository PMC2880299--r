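# Synthetic phase-known diploid datasets: neutral Kingman coalescent trees,
# HKY85 sequence evolution, random diploid pairing and IUPAC collapse.

#' Simulation configuration
#'
#' Bundles the study-design parameters of the simulated datasets: 50 diploid
#' individuals (100 allele copies) at a 250-bp non-recombining locus sampled
#' from a single panmictic population of constant haploid effective size
#' 1,000, sequences evolved under HKY85 with base frequencies
#' A 0.30 / C 0.20 / G 0.15 / T 0.35 and a transition:transversion ratio of
#' 2.5, and datasets retained so that the segregating-site count S hits each
#' of {5, 10, 15, 20, 25, 30, 35} five times.
#'
#' @param n_individuals number of diploid individuals sampled (default 50).
#' @param locus_length alignment length in base pairs (default 250).
#' @param ne_haploid haploid effective population size in individuals;
#'   coalescence times are exponential with rate choose(k,2)/ne_haploid
#'   generations (default 1000).
#' @param age_generations nominal age of the isolated population; with the
#'   default design the expected time to the MRCA (~2 Ne) matches it, so the
#'   coalescent is run unconstrained to the root (default 2000; recorded for
#'   provenance, not enforced).
#' @param hky_freqs equilibrium/root base frequencies in A, C, G, T order.
#' @param tstv_ratio expected transition:transversion substitution count
#'   ratio at stationarity (default 2.5); the HKY85 kappa is derived from it
#'   and the base frequencies.
#' @param scaling_range bounds of the per-site per-generation rate used to
#'   convert branch lengths (generations) into expected substitutions per
#'   site. Default \code{c(1e-6, 1e-5)}, wide enough to span S = 5..35;
#'   \code{scalingRangeNarrow()} gives the narrower published preset
#'   \code{c(9e-6, 1e-5)}.
#' @param s_targets target segregating-site counts (default seq(5, 35, 5)).
#' @param replicates_per_target datasets per target S (default 5).
#' @param seed integer master seed for suite generation.
#' @param max_attempts rejection-sampling cap per dataset slot before
#'   \code{\link{generateSuite}} fails naming the unreachable target.
#' @return a validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg$n_alleles
#' @export
simulationConfig <- function(n_individuals = 50L, locus_length = 250L,
                             ne_haploid = 1000, age_generations = 2000,
                             hky_freqs = c(0.30, 0.20, 0.15, 0.35),
                             tstv_ratio = 2.5,
                             scaling_range = c(1e-6, 1e-5),
                             s_targets = seq(5L, 35L, by = 5L),
                             replicates_per_target = 5L,
                             seed = 1L, max_attempts = 20000L) {
  stopifnot(n_individuals >= 1, locus_length >= 1,
            replicates_per_target >= 0, max_attempts >= 1)
  if (ne_haploid <= 0)
    stop("ne_haploid must be positive")
  if (length(hky_freqs) != 4L || any(hky_freqs <= 0) ||
      abs(sum(hky_freqs) - 1) > 1e-12)
    stop("hky_freqs must be four positive frequencies summing to 1")
  if (tstv_ratio <= 0) stop("tstv_ratio must be positive")
  if (length(scaling_range) != 2L || any(scaling_range <= 0) ||
      scaling_range[1L] > scaling_range[2L])
    stop("scaling_range must be positive increasing bounds")
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_alleles = 2L * as.integer(n_individuals),
              locus_length = as.integer(locus_length),
              ne_haploid = ne_haploid, age_generations = age_generations,
              hky_freqs = hky_freqs, tstv_ratio = tstv_ratio,
              scaling_range = scaling_range,
              s_targets = as.integer(s_targets),
              replicates_per_target = as.integer(replicates_per_target),
              seed = as.integer(seed), max_attempts = as.integer(max_attempts))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' The narrow published scaling-factor preset
#'
#' Per-site per-generation rate bounds of 9e-6 to 1e-5. This narrow band
#' cannot plausibly yield S = 5 at the default design, so the package default
#' is wider; the preset is kept for users who want it.
#' @return numeric length-2 vector.
#' @export
scalingRangeNarrow <- function() c(9e-6, 1e-5)

# kappa such that the stationary expected transition:transversion
# substitution-count ratio equals R for frequencies pi (A,C,G,T order)
.hky_kappa <- function(R, pi) {
  R * (pi[1] + pi[3]) * (pi[2] + pi[4]) / (pi[1] * pi[3] + pi[2] * pi[4])
}

#' Simulate a neutral Kingman coalescent gene tree
#'
#' Standard neutral coalescent for \code{config$n_alleles} lineages in one
#' panmictic population of constant haploid size \code{config$ne_haploid}:
#' while k lineages remain, an exponential waiting time with rate
#' choose(k,2)/Ne (in generations) is drawn and a uniformly random pair
#' merges. The tree is run unconstrained to the MRCA.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional integer seed.
#' @return an ultrametric rooted binary \code{ape::phylo} with branch lengths
#'   in generations; tip labels \code{t1..t<2N>}.
#' @examples
#' tr <- simulateGeneTree(simulationConfig(n_individuals = 5), seed = 1)
#' ape::Ntip(tr)
#' @export
simulateGeneTree <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_alleles
  if (n < 2L) stop("need at least 2 allele copies")
  Ne <- config$ne_haploid
  if (Ne <= 0) stop("ne_haploid must be positive")

  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)          # 0 = none yet
  height <- numeric(n_nodes)          # node age in generations
  active <- seq_len(n)                # tips are nodes 1..n
  t_now <- 0
  next_node <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t_now <- t_now + rexp(1L, rate = k * (k - 1) / 2 / Ne)
    pick <- sample.int(k, 2L)
    height[next_node] <- t_now
    parent[active[pick]] <- next_node
    active <- c(active[-pick], next_node)
    next_node <- next_node + 1L
  }
  root <- n_nodes
  # ape numbering: tips 1..n, root n+1, internals n+2..2n-1.
  # our internal nodes were created in increasing age; root is the oldest.
  internal <- (n + 1L):n_nodes
  ape_id <- integer(n_nodes)
  ape_id[seq_len(n)] <- seq_len(n)
  ape_id[root] <- n + 1L
  others <- setdiff(internal, root)
  ape_id[others] <- n + 1L + seq_along(others)
  child <- which(parent > 0L)
  edge <- cbind(ape_id[parent[child]], ape_id[child])
  edge_len <- height[parent[child]] - height[child]
  tr <- list(edge = edge, edge.length = edge_len,
             Nnode = n - 1L, tip.label = paste0("t", seq_len(n)))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve an allele alignment along a gene tree under HKY85
#'
#' Sequences of \code{config$locus_length} sites are evolved from a root
#' state drawn from the stationary base frequencies, with substitutions
#' placed per site per branch under the HKY85 rate matrix. The matrix is
#' normalised to one expected substitution per site per unit time, so
#' \code{scaling} converts branch lengths in generations into expected
#' substitutions per site per generation.
#'
#' @param tree an \code{ape::phylo} with branch lengths in generations.
#' @param config a \code{\link{simulationConfig}} (frequencies, ts/tv,
#'   length).
#' @param scaling per-site per-generation substitution rate (> 0; a rate of
#'   0 is allowed and returns the root sequence at every tip).
#' @param seed optional integer seed.
#' @return \code{DNAStringSet} of one sequence per tip, named by tip label.
#' @examples
#' cfg <- simulationConfig(n_individuals = 5)
#' tr <- simulateGeneTree(cfg, seed = 1)
#' aln <- evolveAlignment(tr, cfg, scaling = 5e-6, seed = 2)
#' @export
evolveAlignment <- function(tree, config, scaling, seed = NULL) {
  if (scaling < 0) stop("scaling must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  bf <- config$hky_freqs
  if (scaling == 0) {
    root <- sample(.BASES, config$locus_length, replace = TRUE, prob = bf)
    seqs <- rep(paste(root, collapse = ""), length(tree$tip.label))
    return(Biostrings::DNAStringSet(setNames(seqs, tree$tip.label)))
  }
  kappa <- .hky_kappa(config$tstv_ratio, bf)
  Q <- c(1, kappa, 1, 1, kappa, 1)  # ac ag at cg ct gt
  sim <- phangorn::simSeq(tree, l = config$locus_length, Q = Q, bf = bf,
                          rate = scaling)
  m <- toupper(as.character(sim))
  seqs <- apply(m, 1L, paste, collapse = "")
  Biostrings::DNAStringSet(setNames(seqs, rownames(m)))
}

#' Randomly pair haploid alleles into diploid genotypes
#'
#' Draws a uniformly random perfect matching of the allele copies (random
#' mating in a sexual out-crossing species; pairing two identical sequences
#' is allowed since allele copies are distinct draws), relabels the copies
#' \code{ind<i>_a} / \code{ind<i>_b}, and collapses each pair into an IUPAC
#' ambiguity-coded consensus.
#'
#' @param alignment \code{DNAStringSet} (or character) of an even number of
#'   haploid sequences.
#' @param seed optional integer seed.
#' @return list with elements \code{alleles} (relabelled
#'   \code{DNAStringSet}), \code{pairing} (data.frame individual /
#'   allele_a / allele_b) and \code{genotypes} (consensus
#'   \code{DNAStringSet}).
#' @examples
#' ag <- assembleGenotypes(c("ACGT", "ACGA", "ACGT", "ACGT"), seed = 1)
#' ag$pairing
#' @export
assembleGenotypes <- function(alignment, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- .as_base_matrix(alignment)
  n <- nrow(m)
  if (n %% 2L != 0L) stop("odd number of allele sequences; cannot pair")
  perm <- sample.int(n)
  nind <- n %/% 2L
  ind <- paste0("ind", seq_len(nind))
  id_a <- paste0(ind, "_a")
  id_b <- paste0(ind, "_b")
  seqs <- apply(m, 1L, paste, collapse = "")
  out_seqs <- seqs[perm]             # alleles in sampled order
  names(out_seqs) <- as.vector(t(cbind(id_a, id_b)))  # ind1_a, ind1_b, ind2_a, ...
  pairing <- data.frame(individual = ind, allele_a = id_a, allele_b = id_b,
                        stringsAsFactors = FALSE)
  cons <- vapply(seq_len(nind), function(i) {
    a <- m[perm[2L * i - 1L], ]
    b <- m[perm[2L * i], ]
    paste(iupacConsensus(a, b), collapse = "")
  }, "")
  list(alleles = Biostrings::DNAStringSet(out_seqs),
       pairing = pairing,
       genotypes = Biostrings::DNAStringSet(setNames(cons, ind)))
}

# one dataset draw: tree + alignment + pairing; returns TruthDataset
.simulate_one <- function(config, seed) {
  set.seed(seed)
  scaling <- runif(1L, config$scaling_range[1L], config$scaling_range[2L])
  tree <- simulateGeneTree(config)
  aln <- evolveAlignment(tree, config, scaling)
  ag <- assembleGenotypes(aln)
  newTruthDataset(ag$alleles, ag$pairing, ag$genotypes,
                  provenance = list(seed = seed, scaling = scaling))
}

#' Generate a suite of phase-known datasets conditioned on S
#'
#' Rejection sampling over (tree, scaling) draws: datasets are simulated with
#' the branch-length scaling factor drawn uniformly from
#' \code{config$scaling_range}, one sequence dataset per coalescent tree, and
#' kept only if their realised segregating-site count equals a still-unfilled
#' target in \code{config$s_targets}. Each retained dataset records its seed
#' and scaling factor in \code{provenance}.
#'
#' @param config a \code{\link{simulationConfig}}; \code{config$seed} drives
#'   the whole suite reproducibly.
#' @param verbose print progress.
#' @return named list of \code{\linkS4class{TruthDataset}} (names
#'   \code{Sim01}, \code{Sim02}, ...), ordered by target S then replicate,
#'   with the manifest (see \code{\link{suiteManifest}}) attached as
#'   attribute \code{"manifest"}.
#' @export
generateSuite <- function(config, verbose = FALSE) {
  if (length(config$s_targets) == 0L) stop("s_targets is empty")
  quota <- setNames(rep(config$replicates_per_target,
                        length(config$s_targets)),
                    as.character(config$s_targets))
  n_total <- sum(quota)
  out <- vector("list", n_total)
  s_out <- integer(n_total)
  filled <- 0L
  set.seed(config$seed)
  attempts <- 0L
  while (filled < n_total) {
    attempts <- attempts + 1L
    if (attempts > config$max_attempts) {
      missing <- names(quota)[quota > 0L]
      stop("could not reach target S = ", paste(missing, collapse = ", "),
           " within ", config$max_attempts, " attempts")
    }
    seed_i <- sample.int(.Machine$integer.max - 1L, 1L)
    ds <- .simulate_one(config, seed_i)
    S <- .count_segregating(.as_base_matrix(alleles(ds)))
    key <- as.character(S)
    if (!is.null(quota[key][[1L]]) && !is.na(quota[key]) && quota[key] > 0L) {
      quota[key] <- quota[key] - 1L
      filled <- filled + 1L
      ds@provenance$s_target <- S
      out[[filled]] <- ds
      s_out[filled] <- S
      if (verbose)
        message("dataset ", filled, "/", n_total, ": S = ", S,
                " (attempt ", attempts, ")")
    }
  }
  ord <- order(s_out)
  out <- out[ord]
  names(out) <- sprintf("Sim%02d", seq_along(out))
  for (i in seq_along(out)) out[[i]]@provenance$dataset <- names(out)[i]
  attr(out, "manifest") <- suiteManifest(out)
  out
}

#' Suite manifest: one summary row per dataset
#'
#' Replicates the simulated-dataset summary columns of the study design
#' (dataset, N, ambiguous genotypes, S, A_N, G_N, H_O) plus the seed and
#' scaling factor each dataset was generated with.
#'
#' @param suite list of \code{\linkS4class{TruthDataset}}.
#' @return data.frame.
#' @export
suiteManifest <- function(suite) {
  rows <- lapply(seq_along(suite), function(i) {
    ds <- suite[[i]]
    s <- summarizePolymorphism(ds)
    pv <- provenance(ds)
    data.frame(dataset = if (!is.null(pv$dataset)) pv$dataset else
                 if (!is.null(names(suite)[i])) names(suite)[i] else as.character(i),
               N = nIndividuals(ds), ambiguous = s$ambiguous, S = s$S,
               A_N = s$A_N, G_N = s$G_N, H_O = s$H_O,
               seed = if (is.null(pv$seed)) NA_integer_ else pv$seed,
               scaling = if (is.null(pv$scaling)) NA_real_ else pv$scaling,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
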