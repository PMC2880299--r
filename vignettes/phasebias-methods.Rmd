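---
title: "Models and methods behind phasebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

Population screens of nuclear sequence loci usually sequence diploid PCR
products directly, so individuals heterozygous at two or more positions
yield ambiguity-coded consensus sequences whose gametic phase must be
inferred computationally. Confidence-scored phasers (PHASE and its
relatives) attach a posterior probability to each reconstructed haplotype
pair, and common practice is to discard individuals whose best pair falls
below a confidence threshold (typically 0.90, sometimes 0.60) before
estimating population-genetic parameters. `phasebias` implements the whole
experimental loop needed to study what that practice does to downstream
phylogeographic inference: a coalescent simulator for phase-known diploid
datasets, a Gibbs-sampling phaser, a truth-based error taxonomy, and the
bias and haplotype-network analyses.

# Simulating phase-known datasets

`generateSuite()` regenerates the study design: 35 datasets of N = 50
diploid individuals (100 allele copies) at a 250-bp non-recombining locus,
with segregating-site counts S hitting each of {5, 10, 15, 20, 25, 30, 35}
five times.

Each dataset draws one gene tree under the standard neutral Kingman
coalescent for a single panmictic population of constant haploid effective
size N~e~ = 1000: while k lineages remain, a waiting time ~
Exp(choose(k,2)/N~e~) generations elapses and a uniformly chosen pair
merges. With n = 100 and N~e~ = 1000 the expected TMRCA is 2N~e~(1 − 1/n)
≈ 1980 generations, matching the nominal 2,000-generation age of the
isolated population, so the coalescent runs unconstrained to the MRCA and
no age truncation is imposed.

Sequences evolve along the tree under HKY85 with root and equilibrium base
frequencies A 0.30 / C 0.20 / G 0.15 / T 0.35. The transition/transversion
setting of 2.5 is interpreted as the *expected substitution count ratio*
at stationarity, so the rate-matrix kappa is derived from it and the base
frequencies (kappa ≈ 5.38); the package verifies this by counting
transitions and transversions on simulated branches. The rate matrix is
normalised to one expected substitution per site per unit time, and a
per-site per-generation scaling factor converts branch lengths in
generations to substitutions per site. Scaling factors are drawn uniformly
from 1e-6 to 1e-5 — wide enough that rejection sampling can realise every
target from S = 5 to S = 35; the narrower published band (9e-6 to 1e-5,
available as `scalingRangeNarrow()`) cannot plausibly produce the low-S
targets at this design. Datasets are retained only when their realised S
equals a still-unfilled target, one sequence dataset per tree.

Diploid genotypes come from a uniformly random perfect matching of the 100
allele copies (random mating in an out-crossing species; pairing two
identical copies is legitimate since copies are distinct draws), and each
pair is collapsed to a consensus with two-base IUPAC codes at heterozygous
positions. The collapse is lossless up to phase, and "ambiguous genotype"
means heterozygous at ≥ 2 positions — homozygotes and single-site
heterozygotes are phase-trivial.

## What the generator does and does not emulate

The simulated data satisfy every assumption of the phaser's coalescent
prior: neutrality, panmixia, constant size, no recombination, no
genotyping error. Real datasets violate several of these (the empirical
Collembola populations the design mirrors are strongly substructured, with
far lower heterozygosity), so passing tests here demonstrate behaviour
under a best-case scenario, not performance on structured or error-prone
data. One consequence of conditioning on S under unconstrained
coalescence is worth noting: the highest-S targets are preferentially
reached through genealogies with long internal branches, which carry
fewer distinct alleles (and hence more positive Fu's F~S~) than a
bounded-age scheme would produce at the same S. Suite-mean F~S~ is
therefore noticeably noisier across regenerated suites than the diversity
statistics, and comparisons for it use Monte-Carlo (3 SE) tolerances.

# The Gibbs phasing engine

For a set of ambiguity-coded genotypes, the sampler state is one haplotype
pair per individual consistent with its genotype. A sweep updates every
multi-site heterozygote i by drawing a pair (x, y) with probability
proportional to

    pi(x | H_-i) * pi(y | H_-i + x)

where H_-i are the other individuals' current haplotypes and pi(. | H) is
an approximate coalescent conditional: a mixture over the distinct
haplotypes of H, weighting a candidate at mutational distance d from an
existing haplotype by the geometric kernel g(d) = (1 − q) q^d with
q = theta / (n + theta). The kernel is truncated at `trunc_steps = 2`
mutation steps — candidates further than two steps from every existing
haplotype get zero conditional mass, and when *all* candidates are
unsupported the update falls back to a uniform draw (the posterior then
stays diffuse and the individual ends up unresolved, which is the
scientifically correct signal for an isolated pair of divergent alleles).
theta defaults to the per-locus Watterson estimate computed once from the
genotype data before sampling (`theta_mode = "watterson"`).

Individuals with up to `cap_pair_sampling + 1` heterozygous sites are
updated by enumerating all 2^(h−1) unordered decompositions; larger
individuals are updated site-by-site (Gibbs on one phase bit at a time),
which targets the same conditional. Posterior pair probabilities are
sample frequencies over the retained post-burn-in sweeps (500 burn-in +
500 main, thinning 1 by default), and the run protocol uses three
replicate chains with different seeds. Replicates are compared by a
goodness-of-fit defined operationally as the mean best-pair posterior over
multi-site heterozygotes — a deliberate, documented substitution, since
the internal measure of the software whose protocol this mirrors is not
published. Within the selected replicate, exact ties among equally
probable pairs are broken by a seeded random draw; ties among replicates
go to the lowest seed. A numeric cross-replicate agreement report
(`crossReplicateAgreement()`) replaces the original protocol's visual
consistency check.

The boundary rule is "best-pair probability ≥ threshold ⇒ resolved":
below-threshold genotypes are the unresolved pool. The sampler is
deliberately conservative relative to recombination-aware phasers — its
truncated kernel assigns no partial credit beyond two mutation steps — so
a larger share of ambiguous genotypes ends below threshold, while the
confident calls it does make are almost always correct (the pooled
confident-call error rate on regenerated suites is well under 1%).

# Scoring against truth

`classifyError()` labels each inferred haplotype of a wrong pair as
correct (member of the true pair), misidentified (an allele that exists
elsewhere in the phase-known dataset) or novel (absent from it), giving
the classes E_COR+NOV, E_COR+MIS, E_MIS+MIS, E_MIS+NOV, plus E_NOV+NOV to
make the taxonomy total for externally supplied reconstructions. For
complement-consistent pairs (all internal sampler output) the E_COR+*
classes are provably unreachable — the complement of a correct haplotype
is the other true haplotype — and this is asserted as a property test.

Per dataset and threshold, `evaluateDataset()` reports N_ERR (confident
but wrong pairs), N_LCP (unresolved; split into correct/incorrect best
pairs), and N_LOST: distinct alleles whose every copy sits in unresolved
individuals, so pruning removes the gene lineage entirely. Unresolved
genotypes get configuration records (population frequencies of their two
constituent alleles, with singleton and rare < 0.05 flags), and lost
alleles get a divergence skew: p_LOST (mean p-distance of the lost allele
to all other distinct alleles) minus p_DATASET (mean over all pairs),
with multiple losses per dataset summed first so each dataset contributes
a single signed point, positive when the lost lineages are more divergent
than average.

The heterozygosity/error relationship is summarised per het-site-count
class as the error *proportion* within the class (counts would conflate
class size with difficulty); the Pearson correlation across classes is
reported and is undefined (missing) with fewer than three classes or zero
variance.

# Bias from pruning

`pruneUnresolved()` removes unresolved individuals and both their allele
copies but keeps alignment columns, so per-site statistics stay
comparable. The four parameters are Watterson's theta (S over the
harmonic number, per locus and per site), Nei's pi (mean pairwise
differences), Tajima's D (with the standard constants; undefined and
propagated as missing when S = 0), and Fu's F~S~ computed from the Ewens
sampling distribution with theta-hat set to the mean pairwise difference:
S' = P(K ≥ k_obs), F~S~ = ln(S'/(1−S')). Unsigned Stirling numbers of the
first kind are evaluated in log space (log-sum-exp recurrence), so n = 100
is far from overflow; K ≤ 1 or theta-hat = 0 yield missing values with a
reason flag, never zeros.

Delta orientation follows the reported bias directions: positive
d_theta/d_pi mean diversity was *under*estimated after pruning, positive
d_D/d_F~S~ mean the neutrality statistics were *over*estimated. Paired
one-tailed t-tests (via `t.test`) are run on the datasets that actually
lost genotypes — the printed d.f. of 32 corresponds to 33 such datasets —
while regressions (via `lm`) default to all 35; both choices are
parameters of the reporting functions, not hard-coded.

# Statistical parsimony networks

The connection limit is the largest step count j whose estimated
probability of parsimony is ≥ 95%. The package computes it from an
explicit multiple-hit model: mutations land uniformly and independently on
the L sites, a site shows a difference iff it is hit an odd number of
times, and P_j is the posterior probability that two sequences observed to
differ at j sites are separated by exactly j mutations, under a uniform
prior on the true mutation count. This is a self-contained Bayesian
formalisation of the classic parsimony-probability argument rather than a
line-by-line port of any program's recursion; it is monotone in L and in
the confidence level, and is cross-checked against brute-force simulation
of the same model. All downstream rooting comparisons are qualitative
(changed / not changed, component counts), so they do not depend on the
exact limit value.

Networks are built agglomeratively: distinct haplotypes are linked in
increasing mutational-step order (ties by haplotype id, so construction is
deterministic), pairs beyond the limit are never joined, already-connected
pairs are skipped (the graph is loop-free by construction), and a join at
distance d inserts d − 1 inferred intermediate nodes. The outgroup weight
of an observed haplotype is its relative frequency within the component
times 1/(1 + mean graph distance to the other observed haplotypes),
normalised within the component — a documented surrogate for the original
root-probability computation, isolated in `rootByOutgroupWeight()` so it
can be swapped out. The dataset-level root is the root of the dominant
component; rooting changes are compared by haplotype *sequence*, since
pruning relabels ids.

# Numerical and design notes

* S counts segregating sites (columns with ≥ 2 states), not total
  mutations; tri-allelic columns count once. Recoded indel columns are
  ordinary characters everywhere.
* Undefined statistics propagate as `NA` with reason attributes, never as
  zeros; bias deltas involving them are missing and excluded from means.
* All user-facing coordinates (e.g. mask ranges) are 1-based inclusive;
  internal representations are 0-based where convenient.
* Suite generation, phasing, tie-breaking and network construction are
  deterministic given their seeds; the suite manifest records each
  dataset's seed and scaling factor, so any dataset is regenerable from
  the manifest alone.
* Test problem sizes: the oracle and property tests run on 4-16-sequence
  fixtures, 200-replicate calibration simulations at L = 100, and one
  full 35-dataset suite with the default 3 x (500 + 500) phasing
  protocol, which together keep the default test run within a few
  minutes on one CPU.

# Known limitations

* The phaser deliberately omits recombination; it should not be used on
  loci where intragenic recombination is plausible.
* The truncated mutation kernel makes the sampler conservative: more
  genotypes fall below threshold than recombination-aware phasers would
  leave unresolved, so absolute unresolved proportions are not comparable
  across engines — error taxonomy, lost-allele accounting and bias
  directions are.
* The outgroup-weight surrogate and the parsimony-probability model are
  principled stand-ins for program-specific computations that are not
  published in citable form; both are isolated behind single functions.
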