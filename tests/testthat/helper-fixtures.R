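# fixtures shared across test files; everything built in code

# tiny phase-known dataset from explicit allele sequences and pairing
make_truth <- function(seqs, inds = NULL) {
  n <- length(seqs)
  stopifnot(n %% 2 == 0)
  nind <- n / 2
  if (is.null(inds)) inds <- paste0("i", seq_len(nind))
  ids_a <- paste0(inds, "_a")
  ids_b <- paste0(inds, "_b")
  names(seqs) <- as.vector(t(cbind(ids_a, ids_b)))
  newTruthDataset(seqs, data.frame(individual = inds, allele_a = ids_a,
                                   allele_b = ids_b,
                                   stringsAsFactors = FALSE))
}

# the 4-sequence worked example: AAA, AAA | AAT, ATT
truth4 <- function() make_truth(c("AAA", "AAA", "AAT", "ATT"))

# deterministic 12-sequence, 40-bp alignment with known statistics
# (independently cross-checked: S = 6, pi = 1.4090909, theta_W = 1.9868357,
# Tajima's D = -1.1089810)
fixture12 <- function() {
  base <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  seqs <- c(s1 = base, s2 = base, s3 = base, s4 = base, s5 = base,
            s6 = "ACGTACGTACGTACGTACGTACGTAGGTACGTACGTACGT",
            s7 = "ACGTACGTACGTACGTACGTACGTAGGTACGTACGTACGT",
            s8 = "ACGTACGTACGTGCGTACGTACGTACGTACGTACGTACGT",
            s9 = "ACGTACGTACGTGCGTACGTACGTACGTACGTACGTACGT",
            s10 = "GCGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
            s11 = "GCGTACGTACGTACGTACGTACGTACGTACGTACGTACGA",
            s12 = "ACGTACGTACGTACGTACGTATGTACGTAAGTACGTACGT")
  seqs
}

# a ThresholdedResult built directly from scripted calls (for evaluation
# tests that need externally controlled reconstructions)
make_calls <- function(df, threshold) {
  df$resolved <- df$prob >= threshold
  methods::new("ThresholdedResult", threshold = threshold,
               calls = df[c("individual", "hap1", "hap2", "prob", "n_het",
                            "resolved")])
}

# small simulation config for fast tests
small_sim_config <- function(n_individuals = 6L, ...) {
  simulationConfig(n_individuals = n_individuals, locus_length = 60L,
                   ne_haploid = 500, s_targets = c(2L, 4L),
                   replicates_per_target = 2L,
                   scaling_range = c(1e-6, 2e-5), ...)
}
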