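#' @import methods
NULL

setOldClass("igraph")

# ---------------------------------------------------------------- TruthDataset

#' TruthDataset: a phase-known diploid sequence dataset
#'
#' Container for a population sample of N diploid individuals at one
#' non-recombining locus where gametic phase is known: the 2N haploid allele
#' sequences, the individual-to-allele pairing, and the IUPAC ambiguity-coded
#' consensus genotypes that direct sequencing of the diploid PCR products
#' would have produced.
#'
#' @slot alleles \code{DNAStringSet} of the 2N phase-known allele sequences,
#'   named \code{<individual>_a} / \code{<individual>_b}.
#' @slot pairing \code{data.frame} with columns \code{individual},
#'   \code{allele_a}, \code{allele_b}; a perfect matching of the allele ids.
#' @slot genotypes \code{DNAStringSet} of N consensus sequences with two-base
#'   IUPAC codes at heterozygous positions, named by individual.
#' @slot provenance list of free-form metadata (simulation seed, branch-length
#'   scaling factor, target segregating-site count, pruning history, ...).
#'
#' @seealso \code{\link{newTruthDataset}}, \code{\link{generateSuite}},
#'   \code{\link{summarizePolymorphism}}
#' @export
setClass("TruthDataset",
  representation(alleles = "DNAStringSet", pairing = "data.frame",
                 genotypes = "DNAStringSet", provenance = "list"))

setValidity("TruthDataset", function(object) {
  p <- object@pairing
  msg <- character()
  if (!all(c("individual", "allele_a", "allele_b") %in% names(p)))
    msg <- c(msg, "pairing must have columns individual, allele_a, allele_b")
  else {
    ids <- c(p$allele_a, p$allele_b)
    if (length(object@alleles) != length(ids))
      msg <- c(msg, "number of alleles must be 2 x number of individuals")
    if (anyDuplicated(ids) || !setequal(ids, names(object@alleles)))
      msg <- c(msg, "pairing must be a perfect matching of the allele names")
    if (anyDuplicated(p$individual))
      msg <- c(msg, "duplicate individual ids in pairing")
    if (!setequal(p$individual, names(object@genotypes)))
      msg <- c(msg, "genotype names must equal the individual ids")
  }
  if (length(unique(Biostrings::width(object@alleles))) > 1L)
    msg <- c(msg, "alleles must form an alignment (equal lengths)")
  if (length(msg)) msg else TRUE
})

#' Construct a TruthDataset
#'
#' @param alleles \code{DNAStringSet} (or named character vector) of 2N
#'   aligned allele sequences.
#' @param pairing data.frame with columns \code{individual}, \code{allele_a},
#'   \code{allele_b} referencing the allele names.
#' @param genotypes optional \code{DNAStringSet} of consensus genotypes; when
#'   omitted they are recomputed by collapsing each individual's two alleles.
#' @param provenance list of metadata carried along with the dataset.
#' @return a \code{\linkS4class{TruthDataset}}.
#' @export
newTruthDataset <- function(alleles, pairing, genotypes = NULL,
                            provenance = list()) {
  if (!is(alleles, "DNAStringSet"))
    alleles <- Biostrings::DNAStringSet(alleles)
  if (is.null(genotypes)) {
    am <- .as_base_matrix(alleles)
    cons <- vapply(seq_len(nrow(pairing)), function(i) {
      paste(iupacConsensus(am[pairing$allele_a[i], ], am[pairing$allele_b[i], ]),
            collapse = "")
    }, "")
    genotypes <- Biostrings::DNAStringSet(setNames(cons, pairing$individual))
  }
  new("TruthDataset", alleles = alleles, pairing = pairing,
      genotypes = genotypes, provenance = provenance)
}

#' @describeIn TruthDataset-accessors the 2N phase-known allele sequences.
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @describeIn TruthDataset-accessors the individual-to-allele pairing table.
#' @export
setGeneric("pairing", function(x) standardGeneric("pairing"))
#' @describeIn TruthDataset-accessors the IUPAC ambiguity-coded consensus
#'   genotypes.
#' @export
setGeneric("consensusGenotypes", function(x) standardGeneric("consensusGenotypes"))
#' @describeIn TruthDataset-accessors provenance metadata list.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @describeIn TruthDataset-accessors number of diploid individuals.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Accessors for TruthDataset
#'
#' @param x a \code{\linkS4class{TruthDataset}}.
#' @name TruthDataset-accessors
NULL

#' @rdname TruthDataset-accessors
#' @export
setMethod("alleles", "TruthDataset", function(x) x@alleles)
#' @rdname TruthDataset-accessors
#' @export
setMethod("pairing", "TruthDataset", function(x) x@pairing)
#' @rdname TruthDataset-accessors
#' @export
setMethod("consensusGenotypes", "TruthDataset", function(x) x@genotypes)
#' @rdname TruthDataset-accessors
#' @export
setMethod("provenance", "TruthDataset", function(x) x@provenance)
#' @rdname TruthDataset-accessors
#' @export
setMethod("nIndividuals", "TruthDataset", function(x) nrow(x@pairing))

setMethod("show", "TruthDataset", function(object) {
  s <- summarizePolymorphism(object)
  cat("TruthDataset:", nrow(object@pairing), "diploid individuals,",
      "locus length", Biostrings::width(object@alleles)[1L], "bp\n")
  cat(sprintf("  S = %d, A_N = %d, G_N = %d, H_O = %.2f, ambiguous = %d\n",
              s$S, s$A_N, s$G_N, s$H_O, s$ambiguous))
})

# --------------------------------------------------------------- PhasingResult

#' PhasingResult: posterior haplotype-pair reconstructions for one run
#'
#' One Gibbs-sampler replicate over a set of ambiguity-coded genotypes.
#' Homozygotes and single-site heterozygotes are phase-trivial and carry a
#' single candidate pair with probability 1; multi-site heterozygotes carry
#' the posterior over sampled pair decompositions.
#'
#' @slot posteriors named list (one element per individual) of data.frames
#'   with columns \code{hap1}, \code{hap2}, \code{prob}, sorted by
#'   decreasing probability; every candidate pair collapses back to the
#'   observed ambiguous genotype.
#' @slot best data.frame with one row per individual: \code{individual},
#'   \code{hap1}, \code{hap2}, \code{prob} (the confidence probability),
#'   \code{n_het} heterozygous-site count.
#' @slot seed integer seed of this replicate.
#' @slot goodness mean best-pair posterior probability over multi-site
#'   heterozygotes (goodness-of-fit used to pick among replicates).
#' @slot nSamples number of retained post-burn-in MCMC samples.
#' @slot theta the population mutation rate driving the proposal kernel.
#' @export
setClass("PhasingResult",
  representation(posteriors = "list", best = "data.frame", seed = "integer",
                 goodness = "numeric", nSamples = "integer", theta = "numeric"))

setValidity("PhasingResult", function(object) {
  ok <- vapply(object@posteriors, function(p)
    abs(sum(p$prob) - 1) < 1e-9, TRUE)
  if (!all(ok))
    return("candidate-pair probabilities must sum to 1 per individual")
  TRUE
})

#' @describeIn PhasingResult-accessors per-individual posterior tables.
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
#' @describeIn PhasingResult-accessors best pair per individual with its
#'   confidence probability.
#' @export
setGeneric("bestPairs", function(x) standardGeneric("bestPairs"))
#' @describeIn PhasingResult-accessors replicate goodness-of-fit.
#' @export
setGeneric("goodnessOfFit", function(x) standardGeneric("goodnessOfFit"))

#' Accessors for PhasingResult
#' @param x a \code{\linkS4class{PhasingResult}}.
#' @name PhasingResult-accessors
NULL

#' @rdname PhasingResult-accessors
#' @export
setMethod("posteriors", "PhasingResult", function(x) x@posteriors)
#' @rdname PhasingResult-accessors
#' @export
setMethod("bestPairs", "PhasingResult", function(x) x@best)
#' @rdname PhasingResult-accessors
#' @export
setMethod("goodnessOfFit", "PhasingResult", function(x) x@goodness)

setMethod("show", "PhasingResult", function(object) {
  amb <- sum(object@best$n_het >= 2L)
  cat("PhasingResult:", nrow(object@best), "individuals (", amb,
      "multi-site heterozygotes ), seed", object@seed, "\n")
  cat(sprintf("  goodness-of-fit (mean best-pair posterior) = %.4f\n",
              object@goodness))
})

# ----------------------------------------------------------- ThresholdedResult

#' ThresholdedResult: resolved/unresolved partition at a confidence threshold
#'
#' Partition of the multi-site heterozygotes of a \code{PhasingResult} by the
#' rule best-pair probability >= threshold (boundary counts as resolved).
#'
#' @slot threshold the confidence probability cut-off in (0, 1].
#' @slot calls data.frame over multi-site heterozygotes only: columns
#'   \code{individual}, \code{hap1}, \code{hap2}, \code{prob}, \code{n_het},
#'   \code{resolved}.
#' @export
setClass("ThresholdedResult",
  representation(threshold = "numeric", calls = "data.frame"))

#' @describeIn ThresholdedResult-accessors the confidence threshold.
#' @export
setGeneric("thresholdOf", function(x) standardGeneric("thresholdOf"))
#' @describeIn ThresholdedResult-accessors ids resolved at the threshold.
#' @export
setGeneric("resolvedIds", function(x) standardGeneric("resolvedIds"))
#' @describeIn ThresholdedResult-accessors ids left unresolved.
#' @export
setGeneric("unresolvedIds", function(x) standardGeneric("unresolvedIds"))
#' @describeIn ThresholdedResult-accessors the per-individual call table.
#' @export
setGeneric("phaseCalls", function(x) standardGeneric("phaseCalls"))

#' Accessors for ThresholdedResult
#' @param x a \code{\linkS4class{ThresholdedResult}}.
#' @name ThresholdedResult-accessors
NULL

#' @rdname ThresholdedResult-accessors
#' @export
setMethod("thresholdOf", "ThresholdedResult", function(x) x@threshold)
#' @rdname ThresholdedResult-accessors
#' @export
setMethod("resolvedIds", "ThresholdedResult",
          function(x) x@calls$individual[x@calls$resolved])
#' @rdname ThresholdedResult-accessors
#' @export
setMethod("unresolvedIds", "ThresholdedResult",
          function(x) x@calls$individual[!x@calls$resolved])
#' @rdname ThresholdedResult-accessors
#' @export
setMethod("phaseCalls", "ThresholdedResult", function(x) x@calls)

setMethod("show", "ThresholdedResult", function(object) {
  cat(sprintf("ThresholdedResult @ %.2f: %d resolved, %d unresolved (of %d ambiguous)\n",
              object@threshold, sum(object@calls$resolved),
              sum(!object@calls$resolved), nrow(object@calls)))
})

# ----------------------------------------------------------------- EvalSummary

#' EvalSummary: accuracy bookkeeping for one dataset at one threshold
#'
#' @slot threshold confidence threshold used.
#' @slot counts named integer vector: \code{n_ambiguous}, \code{n_err}
#'   (above-threshold pairs with errors), \code{n_lcp} (below-threshold,
#'   unresolved), \code{n_lcp_correct}, \code{n_lcp_incorrect}, \code{n_lost}
#'   (distinct alleles eliminated by pruning the unresolved individuals).
#' @slot classCounts integer matrix, error classes x pools
#'   (\code{err}, \code{lcp_incorrect}).
#' @slot lostAlleles character vector of lost allele sequences.
#' @slot perIndividual data.frame, one row per multi-site heterozygote:
#'   \code{individual}, \code{n_het}, \code{prob}, \code{resolved},
#'   \code{correct}, \code{class}.
#' @export
setClass("EvalSummary",
  representation(threshold = "numeric", counts = "integer",
                 classCounts = "matrix", lostAlleles = "character",
                 perIndividual = "data.frame"))

#' @describeIn EvalSummary-accessors named count vector.
#' @export
setGeneric("evalCounts", function(x) standardGeneric("evalCounts"))
#' @describeIn EvalSummary-accessors error-class count matrix.
#' @export
setGeneric("errorClassCounts", function(x) standardGeneric("errorClassCounts"))
#' @describeIn EvalSummary-accessors lost allele sequences.
#' @export
setGeneric("lostAlleles", function(x) standardGeneric("lostAlleles"))
#' @describeIn EvalSummary-accessors proportion of ambiguous genotypes left
#'   unresolved (N_LCP over the number of multi-site heterozygotes).
#' @export
setGeneric("proportionUnresolved", function(x) standardGeneric("proportionUnresolved"))

#' Accessors for EvalSummary
#' @param x an \code{\linkS4class{EvalSummary}}.
#' @name EvalSummary-accessors
NULL

#' @rdname EvalSummary-accessors
#' @export
setMethod("evalCounts", "EvalSummary", function(x) x@counts)
#' @rdname EvalSummary-accessors
#' @export
setMethod("errorClassCounts", "EvalSummary", function(x) x@classCounts)
#' @rdname EvalSummary-accessors
#' @export
setMethod("lostAlleles", "EvalSummary", function(x) x@lostAlleles)
#' @rdname EvalSummary-accessors
#' @export
setMethod("proportionUnresolved", "EvalSummary", function(x) {
  ct <- x@counts
  if (ct[["n_ambiguous"]] == 0L) return(NA_real_)
  ct[["n_lcp"]] / ct[["n_ambiguous"]]
})

setMethod("show", "EvalSummary", function(object) {
  ct <- object@counts
  cat(sprintf("EvalSummary @ %.2f: N_ERR = %d, N_LCP = %d (%d correct / %d incorrect), N_LOST = %d\n",
              object@threshold, ct[["n_err"]], ct[["n_lcp"]],
              ct[["n_lcp_correct"]], ct[["n_lcp_incorrect"]], ct[["n_lost"]]))
})

# ----------------------------------------------------------- HaplotypeNetwork

#' HaplotypeNetwork: one statistical-parsimony network component
#'
#' Observed haplotypes (with sample frequencies) and inferred single-step
#' intermediates, connected so that every edge spans exactly one mutational
#' step; haplotype pairs farther apart than the parsimony connection limit
#' are never joined, so a dataset may yield several disconnected networks.
#'
#' @slot graph an \code{igraph} graph; vertex attributes \code{name},
#'   \code{observed}, \code{freq}.
#' @slot observed data.frame of observed haplotypes: \code{id}, \code{seq},
#'   \code{freq}, \code{weight} (outgroup weight, normalised within the
#'   component).
#' @slot root id of the highest-outgroup-weight observed haplotype.
#' @slot limit the connection limit (mutational steps) used to build it.
#' @export
setClass("HaplotypeNetwork",
  representation(graph = "igraph", observed = "data.frame",
                 root = "character", limit = "integer"))

#' @describeIn HaplotypeNetwork-accessors the underlying igraph object.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @describeIn HaplotypeNetwork-accessors observed haplotype table with
#'   outgroup weights.
#' @export
setGeneric("observedHaplotypes", function(x) standardGeneric("observedHaplotypes"))
#' @describeIn HaplotypeNetwork-accessors id of the root haplotype.
#' @export
setGeneric("networkRoot", function(x) standardGeneric("networkRoot"))

#' Accessors for HaplotypeNetwork
#' @param x a \code{\linkS4class{HaplotypeNetwork}}.
#' @name HaplotypeNetwork-accessors
NULL

#' @rdname HaplotypeNetwork-accessors
#' @export
setMethod("networkGraph", "HaplotypeNetwork", function(x) x@graph)
#' @rdname HaplotypeNetwork-accessors
#' @export
setMethod("observedHaplotypes", "HaplotypeNetwork", function(x) x@observed)
#' @rdname HaplotypeNetwork-accessors
#' @export
setMethod("networkRoot", "HaplotypeNetwork", function(x) x@root)

setMethod("show", "HaplotypeNetwork", function(object) {
  cat("HaplotypeNetwork:", nrow(object@observed), "observed haplotypes,",
      igraph::vcount(object@graph) - nrow(object@observed), "inferred intermediates,",
      igraph::ecount(object@graph), "single-step edges\n")
  cat("  root:", object@root, "(limit", object@limit, "steps )\n")
})
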