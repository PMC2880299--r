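# Truth-vs-inference scoring: error taxonomy, unresolved-genotype
# accounting, lost alleles, genotypic configurations and divergence skew.

.ERROR_CLASSES <- c("CORRECT", "E_COR_NOV", "E_COR_MIS", "E_MIS_MIS",
                    "E_MIS_NOV", "E_NOV_NOV")

#' Classify a haplotype-pair reconstruction error
#'
#' Compares an inferred unordered haplotype pair against the true pair.
#' \code{CORRECT} when the pairs match as multisets; otherwise each inferred
#' haplotype is labelled correct (member of the true pair), misidentified
#' (an allele that exists elsewhere in the phase-known dataset but is not
#' this individual's), or novel (a sequence absent from the dataset), and
#' the label pair maps to one of \code{E_COR_NOV}, \code{E_COR_MIS},
#' \code{E_MIS_MIS}, \code{E_MIS_NOV}, \code{E_NOV_NOV}. The last class
#' closes the taxonomy for externally supplied, possibly
#' complement-inconsistent reconstructions; internal sampler output can
#' never produce \code{E_COR_*} because the complement of a correct
#' haplotype is forced to be the other true haplotype.
#'
#' @param true_pair,inferred_pair character vectors of length 2 (equal
#'   sequence lengths).
#' @param known_alleles character vector of all distinct alleles in the
#'   phase-known dataset.
#' @return one of the class labels above.
#' @examples
#' classifyError(c("AA", "TT"), c("AT", "TA"), c("AA", "TT", "AT"))
#' @export
classifyError <- function(true_pair, inferred_pair, known_alleles) {
  stopifnot(length(true_pair) == 2L, length(inferred_pair) == 2L)
  if (length(unique(nchar(c(true_pair, inferred_pair)))) != 1L)
    stop("haplotype length mismatch")
  if (identical(sort(true_pair), sort(inferred_pair))) return("CORRECT")
  remaining <- true_pair
  labels <- vapply(inferred_pair, function(h) {
    hit <- match(h, remaining)
    if (!is.na(hit)) {
      remaining[hit] <<- NA_character_
      "cor"
    } else if (h %in% known_alleles) "mis" else "nov"
  }, "")
  key <- paste(sort(labels), collapse = "+")
  switch(key,
         "cor+nov" = "E_COR_NOV",
         "cor+mis" = "E_COR_MIS",
         "mis+mis" = "E_MIS_MIS",
         "mis+nov" = "E_MIS_NOV",
         "nov+nov" = "E_NOV_NOV",
         "cor+cor" = "CORRECT")  # unreachable: both correct implies equality
}

# true pair of full sequences per individual, named by individual id
.true_pairs <- function(truth) {
  m <- .as_base_matrix(alleles(truth))
  seqs <- apply(m, 1L, paste, collapse = "")
  p <- pairing(truth)
  setNames(lapply(seq_len(nrow(p)), function(i)
    c(seqs[[p$allele_a[i]]], seqs[[p$allele_b[i]]])), p$individual)
}

#' Score a thresholded phasing result against truth
#'
#' Over the multi-site heterozygotes: N_ERR counts above-threshold
#' individuals whose best pair differs from the true pair; N_LCP counts
#' below-threshold (unresolved) individuals, split into correctly and
#' incorrectly inferred; error classes are tallied separately for the two
#' pools; N_LOST counts distinct alleles whose every copy sits in an
#' unresolved individual.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param thresholded a \code{\linkS4class{ThresholdedResult}} for the same
#'   individuals.
#' @return an \code{\linkS4class{EvalSummary}}.
#' @export
evaluateDataset <- function(truth, thresholded) {
  stopifnot(is(truth, "TruthDataset"), is(thresholded, "ThresholdedResult"))
  calls <- phaseCalls(thresholded)
  tp <- .true_pairs(truth)
  missing <- setdiff(calls$individual, names(tp))
  if (length(missing))
    stop("individuals absent from truth: ", paste(missing, collapse = ", "))
  m <- .as_base_matrix(alleles(truth))
  known <- unique(apply(m, 1L, paste, collapse = ""))

  per <- calls
  per$correct <- logical(nrow(per))
  per$class <- character(nrow(per))
  for (r in seq_len(nrow(per))) {
    inferred <- c(per$hap1[r], per$hap2[r])
    cls <- classifyError(tp[[per$individual[r]]], inferred, known)
    per$class[r] <- cls
    per$correct[r] <- cls == "CORRECT"
  }

  unres <- per$individual[!per$resolved]
  lost <- findLostAlleles(truth, unres)
  n_err <- sum(per$resolved & !per$correct)
  n_lcp <- sum(!per$resolved)
  n_lcp_cor <- sum(!per$resolved & per$correct)
  classes <- .ERROR_CLASSES[-1L]
  cc <- cbind(err = vapply(classes, function(cl)
                 sum(per$resolved & per$class == cl), 0L),
              lcp_incorrect = vapply(classes, function(cl)
                 sum(!per$resolved & per$class == cl), 0L))
  counts <- c(n_ambiguous = nrow(per), n_err = n_err, n_lcp = n_lcp,
              n_lcp_correct = n_lcp_cor,
              n_lcp_incorrect = n_lcp - n_lcp_cor, n_lost = lost$n_lost)
  new("EvalSummary", threshold = thresholdOf(thresholded),
      counts = setNames(as.integer(counts), names(counts)),
      classCounts = cc, lostAlleles = lost$lost_alleles,
      perIndividual = per)
}

#' Find alleles lost by excluding unresolved individuals
#'
#' An allele is lost when every one of its copies resides in an unresolved
#' individual, so pruning those individuals removes the gene lineage from
#' the dataset entirely.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param unresolved_ids character vector of unresolved individual ids
#'   (subset of the dataset's individuals).
#' @return list with \code{n_lost} and \code{lost_alleles} (distinct
#'   sequences).
#' @export
findLostAlleles <- function(truth, unresolved_ids) {
  p <- pairing(truth)
  if (!all(unresolved_ids %in% p$individual))
    stop("unresolved ids not in dataset")
  m <- .as_base_matrix(alleles(truth))
  seqs <- apply(m, 1L, paste, collapse = "")
  owner <- setNames(rep(p$individual, 2L), c(p$allele_a, p$allele_b))
  unres_copy <- owner[names(seqs)] %in% unresolved_ids
  lost <- setdiff(unique(seqs[unres_copy]), unique(seqs[!unres_copy]))
  list(n_lost = length(lost), lost_alleles = lost)
}

#' Genotypic configurations of unresolved genotypes
#'
#' For each unresolved genotype, the population frequencies (in the full
#' dataset, over 2N allele copies) of its two constituent alleles, ordered
#' common then rare, with indicator flags: is the rarer allele a singleton
#' (exactly one copy), is it rare (frequency < 0.05), and is the more
#' common one also rare.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param unresolved_ids character vector of unresolved individual ids.
#' @return data.frame with one row per unresolved genotype: columns
#'   \code{individual}, \code{freq_common}, \code{freq_rare},
#'   \code{rare_is_singleton}, \code{rare_is_rare}, \code{common_is_rare}.
#' @export
configurationProfile <- function(truth, unresolved_ids) {
  p <- pairing(truth)
  m <- .as_base_matrix(alleles(truth))
  seqs <- apply(m, 1L, paste, collapse = "")
  n_copies <- length(seqs)
  freq_tab <- table(seqs) / n_copies
  count_tab <- table(seqs)
  rows <- lapply(unresolved_ids, function(id) {
    i <- match(id, p$individual)
    a <- seqs[[p$allele_a[i]]]
    b <- seqs[[p$allele_b[i]]]
    fa <- as.numeric(freq_tab[a])
    fb <- as.numeric(freq_tab[b])
    common <- max(fa, fb)
    rare <- min(fa, fb)
    rare_seq <- if (fa <= fb) a else b
    data.frame(individual = id, freq_common = common, freq_rare = rare,
               rare_is_singleton = as.integer(count_tab[rare_seq]) == 1L,
               rare_is_rare = rare < 0.05,
               common_is_rare = common < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual = character(), freq_common = numeric(),
                      freq_rare = numeric(), rare_is_singleton = logical(),
                      rare_is_rare = logical(), common_is_rare = logical())
  out
}

#' Divergence skew of lost alleles
#'
#' p_LOST for a lost allele is its mean uncorrected p-distance to all other
#' distinct alleles in the dataset; p_DATASET is the mean over all pairwise
#' comparisons among distinct alleles. A dataset with one lost allele
#' contributes p_LOST - p_DATASET (positive = the lost allele is more
#' divergent than average); with several lost alleles the p_LOST values are
#' first summed and the dataset contributes sum(p_LOST) - p_DATASET, one
#' signed data point per dataset.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param lost_alleles character vector of lost allele sequences (from
#'   \code{\link{findLostAlleles}}).
#' @return list with \code{per_allele} (data.frame allele / p_lost),
#'   \code{p_dataset} and \code{difference}; \code{difference} is
#'   \code{NA} when no alleles were lost.
#' @export
divergenceSkew <- function(truth, lost_alleles) {
  m <- .as_base_matrix(alleles(truth))
  seqs <- unique(apply(m, 1L, paste, collapse = ""))
  if (length(lost_alleles) == 0L)
    return(list(per_allele = data.frame(allele = character(),
                                        p_lost = numeric()),
                p_dataset = NA_real_, difference = NA_real_))
  if (length(seqs) < 2L) stop("need >= 2 distinct alleles")
  names(seqs) <- paste0("h", seq_along(seqs))
  D <- pDistanceMatrix(seqs)
  p_dataset <- mean(D[upper.tri(D)])
  idx <- match(lost_alleles, seqs)
  if (anyNA(idx)) stop("lost allele not present in dataset")
  p_lost <- vapply(idx, function(i) mean(D[i, -i]), 0)
  list(per_allele = data.frame(allele = lost_alleles, p_lost = p_lost,
                               stringsAsFactors = FALSE),
       p_dataset = p_dataset,
       difference = sum(p_lost) - p_dataset)
}

#' Correlation between heterozygous-site count and phasing error
#'
#' Pools individuals by their number of heterozygous sites, computes the
#' proportion in error (confident errors plus incorrectly inferred
#' unresolved genotypes) per class, and returns the Pearson correlation
#' between class value and error proportion.
#'
#' @param records data.frame with columns \code{n_het} (heterozygous-site
#'   count) and \code{error} (logical: N_ERR or N_LCP-incorrect member).
#' @return list with \code{r}, \code{per_class} (data.frame n_het /
#'   n / prop_error); \code{r} is \code{NA} when fewer than 3 classes or
#'   zero variance.
#' @export
hetErrorRelationship <- function(records) {
  stopifnot(all(c("n_het", "error") %in% names(records)))
  agg <- aggregate(records$error, by = list(n_het = records$n_het),
                   FUN = function(z) c(n = length(z), prop = mean(z)))
  per <- data.frame(n_het = agg$n_het, n = agg$x[, "n"],
                    prop_error = agg$x[, "prop"])
  r <- if (nrow(per) < 3L || var(per$prop_error) == 0 || var(per$n_het) == 0)
    NA_real_ else cor(per$n_het, per$prop_error)
  list(r = r, per_class = per)
}

#' Pooled rate as a percentage
#'
#' Pooled count ratio expressed in percent, e.g. confident errors over all
#' ambiguous genotypes across a suite of datasets.
#'
#' @param events,total non-negative counts, \code{total} > 0.
#' @return percentage (numeric scalar).
#' @examples
#' pooledErrorRate(5, 1077)  # 0.46%, i.e. 0.5% at one decimal
#' @export
pooledErrorRate <- function(events, total) {
  stopifnot(total > 0, events >= 0)
  100 * events / total
}
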