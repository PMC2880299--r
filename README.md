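# phasebias

Computational haplotype phasing of diploid nuclear sequence data assigns a
posterior confidence probability to each reconstructed haplotype pair, and
standard practice is to drop individuals whose best pair falls below a
threshold (usually 0.90 or 0.60) before downstream analysis. Because the
hard-to-phase genotypes are precisely the ones carrying rare, divergent
alleles, that pruning is not random — it removes gene lineages and skews
the classical phylogeographic parameters. `phasebias` is an R package for
quantifying that effect end to end, for population geneticists and
phylogeographers who phase non-recombining nuclear loci computationally.

The package implements:

* **Synthetic phase-known datasets** — neutral Kingman coalescent gene
  trees (haploid N<sub>e</sub> = 1000, 100 allele copies), HKY85 sequence
  evolution (base frequencies 0.30/0.20/0.15/0.35, ts/tv = 2.5, 250 bp),
  random diploid pairing and IUPAC consensus collapse, with rejection
  sampling to realise segregating-site targets S ∈ {5, 10, …, 35}, five
  datasets each (`generateSuite`).
* **A Bayesian Gibbs phaser** — each multi-site heterozygote is updated by
  sampling a pair (x, y) with probability ∝ π̂(x | H₋ᵢ) · π̂(y | H₋ᵢ + x),
  where π̂ is an approximate coalescent conditional: a mixture over the
  current haplotypes with a geometric-in-θ mutation kernel
  g(d) = (1 − q)qᵈ, q = θ/(n + θ), truncated at two mutation steps. Pair
  probabilities are posterior frequencies over retained samples; three
  replicate chains, best goodness-of-fit wins (`gibbsPhase`,
  `phaseDataset`).
* **Truth-based evaluation** — the error taxonomy
  (E<sub>COR+NOV</sub> … E<sub>MIS+NOV</sub>), N<sub>ERR</sub> /
  N<sub>LCP</sub> / N<sub>LOST</sub> accounting, genotypic configurations
  of unresolved genotypes, and the divergence skew
  p<sub>LOST</sub> − p<sub>DATASET</sub> of lost alleles
  (`evaluateDataset`, `configurationProfile`, `divergenceSkew`).
* **Bias analysis** — Watterson's Θ<sub>W</sub> = S/a₁, Nei's π, Tajima's
  D, and Fu's F<sub>S</sub> = ln(S′/(1 − S′)) with
  S′ = P(K ≥ k<sub>obs</sub>) under the Ewens sampling distribution at
  θ̂ = π; signed before/after-pruning deltas, one-tailed paired t-tests
  and OLS regressions (`popGenSummary`, `computeBiasTable`).
* **Statistical parsimony networks** — 95% connection limit from a
  multiple-hit parsimony-probability model, agglomerative construction
  with inferred intermediates, outgroup-weight rooting and
  before/after-pruning root comparison (`buildNetworks`, `compareRoots`).

## Worked example

Simulate one phase-known dataset of 20 diploids with S = 12, re-phase its
ambiguity-coded genotypes, and measure what pruning the unresolved
genotypes does:

```r
library(phasebias)

cfg <- simulationConfig(n_individuals = 20, s_targets = 12L,
                        replicates_per_target = 1L, seed = 7)
ds <- generateSuite(cfg)[[1]]
ds
#> TruthDataset: 20 diploid individuals, locus length 250 bp
#>   S = 12, A_N = 10, G_N = 13, H_O = 0.85, ambiguous = 15

ph <- phaseDataset(ds, phasingRunConfig(), seed = 1)
ph$result
#> PhasingResult: 20 individuals ( 15 multi-site heterozygotes ), seed 2
#>   goodness-of-fit (mean best-pair posterior) = 0.7103

th <- ph$thresholded[["0.90"]]
evaluateDataset(ds, th)
#> EvalSummary @ 0.90: N_ERR = 0, N_LCP = 9 (6 correct / 3 incorrect), N_LOST = 6

pruned <- pruneUnresolved(ds, unresolvedIds(th))
computeBiasTable(list(popGenSummary(ds)), list(popGenSummary(pruned)),
                 threshold = 0.90, ids = "Sim01")
#>  dataset threshold n_omitted d_theta_w   d_pi d_tajima_d d_fu_fs rel_theta_reduction
#>    Sim01       0.9         9    0.0047 0.0013     1.5464   3.714              0.4166
```

Reading the output: none of the six confidently phased genotypes was wrong
(N_ERR = 0), but nine of the fifteen ambiguous genotypes stayed below the
0.90 confidence threshold, and dropping them eliminates six of the ten
distinct alleles (N_LOST = 6). The bias row shows the consequence with the
conventional orientation — positive values are bias in the expected
direction: per-site Θ<sub>W</sub> falls by 0.0047 (a 42% reduction of the
phase-known value), π falls by 0.0013, while Tajima's D and Fu's
F<sub>S</sub> are inflated by 1.55 and 3.71. This is the lost-rare-allele
mechanism at dataset scale: diversity underestimated, neutrality/growth
statistics pushed upward.

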