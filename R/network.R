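# Statistical-parsimony haplotype networks: connection limit, agglomerative
# construction with inferred intermediates, outgroup-weight rooting, and
# before/after-pruning root comparison.

# P(J = j | M mutations, L sites) under the parity model: mutations land
# uniformly and independently on L sites; a site differs iff hit an odd
# number of times. Computed by a Markov chain on the number of odd sites.
.parity_given_m <- function(j, M, L) {
  if (M < j || ((M - j) %% 2L) != 0L) return(0)
  p <- numeric(M + 1L)       # p[o+1] = P(o odd sites) after m mutations
  p[1L] <- 1
  for (m in seq_len(M)) {
    np <- numeric(M + 1L)
    for (o in 0:(m - 1L)) {
      if (p[o + 1L] == 0) next
      np[o + 2L] <- np[o + 2L] + p[o + 1L] * (L - o) / L
      if (o > 0L) np[o] <- np[o] + p[o + 1L] * o / L
    }
    p <- np
  }
  p[j + 1L]
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j such that the estimated probability
#' of parsimony P_j is at least \code{confidence}. P_j is the posterior
#' probability that two sequences observed to differ at j of L sites are
#' separated by exactly j mutations, under a multiple-hit model in which
#' mutations land uniformly on the L sites and a site shows a difference
#' iff it was hit an odd number of times, with a uniform prior over the
#' true number of mutations.
#'
#' @param L sequence length in sites (>= 1).
#' @param confidence parsimony confidence criterion in (0, 1); default the
#'   conventional 0.95.
#' @param max_extra how many extra mutation pairs beyond j to include in
#'   the posterior normalisation (default 20; the terms decay fast).
#' @return integer connection limit (>= 0).
#' @examples
#' parsimonyConnectionLimit(250)
#' @export
parsimonyConnectionLimit <- function(L, confidence = 0.95, max_extra = 20L) {
  stopifnot(L >= 1L, confidence > 0, confidence < 1)
  pj <- function(j) {
    if (j == 0L) return(1)
    num <- .parity_given_m(j, j, L)
    den <- num
    for (extra in seq_len(max_extra)) {
      term <- .parity_given_m(j, j + 2L * extra, L)
      den <- den + term
      if (term < den * 1e-12) break
    }
    num / den
  }
  j <- 0L
  while (j < L && pj(j + 1L) >= confidence) j <- j + 1L
  j
}

# deterministic agglomerative linking: pairs of distinct haplotypes joined
# in increasing distance order (ties by id order); pairs beyond the limit
# never joined; a path of length d inserts d-1 intermediate nodes.
.build_graph <- function(seqs, freqs, limit) {
  n <- length(seqs)
  ids <- names(seqs)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids, observed = TRUE, freq = freqs)
  if (n > 1L) {
    D <- pDistanceMatrix(seqs) * nchar(seqs[[1L]])
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    steps <- round(D[upper.tri(D)])
    ord <- order(steps, pairs[, 1L], pairs[, 2L])
    comp <- seq_len(n)                 # union-find by relabel
    n_int <- 0L
    for (e in ord) {
      i <- pairs[e, 1L]; j <- pairs[e, 2L]; d <- steps[e]
      if (d > limit) break
      if (comp[i] == comp[j]) next
      comp[comp == comp[j]] <- comp[i]
      if (d <= 1L) {
        g <- igraph::add_edges(g, c(ids[i], ids[j]))
      } else {
        inter <- paste0("int", n_int + seq_len(d - 1L))
        n_int <- n_int + d - 1L
        g <- igraph::add_vertices(g, d - 1L, name = inter, observed = FALSE,
                                  freq = 0)
        path <- c(ids[i], inter, ids[j])
        for (k in seq_len(d)) g <- igraph::add_edges(g, path[k:(k + 1L)])
      }
    }
  }
  g
}

#' Build statistical-parsimony haplotype networks
#'
#' Collapses an alignment to its distinct haplotypes with sample
#' frequencies, links pairs agglomeratively in increasing mutational-step
#' order up to the connection limit (inserting d - 1 inferred intermediates
#' on a path of d steps), and returns one
#' \code{\linkS4class{HaplotypeNetwork}} per connected component, each with
#' outgroup weights and its root filled in. Components are ordered by
#' decreasing total observed frequency (ties: more observed haplotypes,
#' then smallest haplotype id).
#'
#' @param x alignment (\code{DNAStringSet}, named character vector, base
#'   matrix, or a \code{\linkS4class{TruthDataset}} whose alleles are used);
#'   duplicate sequences supply the haplotype frequencies.
#' @param limit connection limit in mutational steps; default computed by
#'   \code{\link{parsimonyConnectionLimit}} at 95\% for the alignment
#'   length.
#' @return list of \code{\linkS4class{HaplotypeNetwork}}.
#' @export
buildNetworks <- function(x, limit = NULL) {
  if (is(x, "TruthDataset")) x <- alleles(x)
  m <- .as_base_matrix(x)
  all_seqs <- apply(m, 1L, paste, collapse = "")
  tab <- table(all_seqs)
  seqs <- names(tab)
  ord <- order(-as.integer(tab), seqs)
  seqs <- seqs[ord]
  freqs <- as.integer(tab)[ord]
  names(seqs) <- paste0("H", seq_along(seqs))
  if (is.null(limit)) limit <- parsimonyConnectionLimit(ncol(m))
  g <- .build_graph(seqs, freqs, as.integer(limit))
  comp <- igraph::components(g)
  seq_by_id <- setNames(seqs, names(seqs))
  nets <- lapply(seq_len(comp$no), function(ci) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
    obs_v <- igraph::V(sub)$name[igraph::V(sub)$observed]
    obs <- data.frame(id = obs_v, seq = unname(seq_by_id[obs_v]),
                      freq = igraph::V(sub)$freq[igraph::V(sub)$observed],
                      stringsAsFactors = FALSE)
    net <- new("HaplotypeNetwork", graph = sub, observed = obs,
               root = NA_character_, limit = as.integer(limit))
    rootByOutgroupWeight(net)
  })
  totf <- vapply(nets, function(nt) sum(observedHaplotypes(nt)$freq), 0)
  nobs <- vapply(nets, function(nt) nrow(observedHaplotypes(nt)), 0L)
  first <- vapply(nets, function(nt) min(observedHaplotypes(nt)$id), "")
  nets[order(-totf, -nobs, first)]
}

#' Root a network by outgroup weight
#'
#' Outgroup weight combines haplotype frequency and topological centrality:
#' the weight of an observed haplotype is its relative frequency within the
#' component times 1 / (1 + mean graph distance to the other observed
#' haplotypes), normalised to sum to 1. The root is the highest-weight
#' haplotype; ties break by higher frequency, then lexicographic id.
#'
#' @param network a \code{\linkS4class{HaplotypeNetwork}}.
#' @return the network with \code{weight} column and \code{root} filled in.
#' @export
rootByOutgroupWeight <- function(network) {
  stopifnot(is(network, "HaplotypeNetwork"))
  obs <- network@observed
  if (nrow(obs) == 0L) stop("network has no observed haplotypes")
  relf <- obs$freq / sum(obs$freq)
  if (nrow(obs) == 1L) {
    cent <- 1
  } else {
    D <- igraph::distances(network@graph, v = obs$id, to = obs$id)
    cent <- 1 / (1 + rowMeans(D))
  }
  w <- relf * cent
  obs$weight <- w / sum(w)
  ord <- order(-obs$weight, -obs$freq, obs$id)
  network@observed <- obs
  network@root <- obs$id[ord[1L]]
  network
}

#' Compare network roots before and after pruning
#'
#' The dataset-level root is the root of the dominant network (largest
#' total observed frequency). Rooting is compared by haplotype sequence,
#' not id, since pruning relabels haplotypes. \code{changed} flags a root
#' identity change or a change in the number of network components
#' (splits).
#'
#' @param original,pruned lists of \code{\linkS4class{HaplotypeNetwork}}
#'   built at the same connection confidence from the original and pruned
#'   datasets.
#' @return list with \code{original_root}, \code{pruned_root} (sequences),
#'   \code{root_changed}, \code{components_before}, \code{components_after},
#'   \code{changed}.
#' @export
compareRoots <- function(original, pruned) {
  root_seq <- function(nets) {
    obs <- observedHaplotypes(nets[[1L]])
    obs$seq[obs$id == networkRoot(nets[[1L]])]
  }
  ro <- root_seq(original)
  rp <- root_seq(pruned)
  list(original_root = ro, pruned_root = rp,
       root_changed = !identical(ro, rp),
       components_before = length(original),
       components_after = length(pruned),
       changed = !identical(ro, rp) || length(original) != length(pruned))
}
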