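# Polymorphism measures and the four phylogeographic parameters:
# Watterson's theta, Nei's pi, Tajima's D, Fu's F_S.

#' Polymorphism summary of a phase-known dataset
#'
#' Computes the four polymorphism measures on the analysed alignment:
#' S (segregating sites), A_N (distinct alleles), G_N (distinct unordered
#' diploid genotypes), H_O (observed heterozygosity: proportion of
#' individuals whose two alleles differ), plus the number of ambiguous
#' genotypes (individuals heterozygous at two or more positions, the ones
#' whose phase is not trivially resolvable).
#'
#' @param x a \code{\linkS4class{TruthDataset}}.
#' @return list with elements \code{S}, \code{A_N}, \code{G_N}, \code{H_O},
#'   \code{ambiguous}, \code{n_sequences}, \code{length}.
#' @examples
#' ds <- newTruthDataset(
#'   c(i1_a = "AAA", i1_b = "AAA", i2_a = "AAT", i2_b = "ATT"),
#'   data.frame(individual = c("i1", "i2"), allele_a = c("i1_a", "i2_a"),
#'              allele_b = c("i1_b", "i2_b")))
#' summarizePolymorphism(ds)
#' @export
summarizePolymorphism <- function(x) {
  stopifnot(is(x, "TruthDataset"))
  m <- .as_base_matrix(alleles(x))
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  p <- pairing(x)
  seqs <- apply(m, 1L, paste, collapse = "")
  pair_seq <- cbind(seqs[p$allele_a], seqs[p$allele_b])
  gkey <- .pair_key(pair_seq[, 1L], pair_seq[, 2L])
  hets <- pair_seq[, 1L] != pair_seq[, 2L]
  ndiff <- mapply(function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
                  pair_seq[, 1L], pair_seq[, 2L])
  list(S = .count_segregating(m),
       A_N = length(unique(seqs)),
       G_N = length(unique(gkey)),
       H_O = mean(hets),
       ambiguous = sum(ndiff >= 2L),
       n_sequences = nrow(m),
       length = ncol(m))
}

#' Watterson's estimator of the population mutation rate
#'
#' theta_locus = S / sum(1/i, i = 1..n-1); theta_site divides by the locus
#' length.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (>= 2).
#' @param L locus length in base pairs.
#' @return list with \code{theta_locus} and \code{theta_site}.
#' @examples
#' wattersonTheta(S = 20, n = 100, L = 250)
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2L) stop("Watterson's estimator needs n >= 2")
  a1 <- .harmonic(n - 1L)
  theta_locus <- S / a1
  list(theta_locus = theta_locus, theta_site = theta_locus / L)
}

# total pairwise differences and number of pairs, column-count based
.pairwise_diff_total <- function(m) {
  n <- nrow(m)
  npair <- n * (n - 1) / 2
  tot <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    tot <- tot + npair - sum(tab * (tab - 1) / 2)
  }
  list(total = tot, npairs = npair)
}

#' Nucleotide diversity (Nei's pi)
#'
#' Mean number of pairwise nucleotide differences over all C(n,2) sequence
#' pairs, per locus and per site.
#'
#' @param x alignment: \code{DNAStringSet}, named character vector, or base
#'   matrix (rows = sequences). Duplicate sequences count with their
#'   multiplicity.
#' @return list with \code{pi_locus} and \code{pi_site}.
#' @examples
#' nucleotideDiversity(c("AAA", "AAA", "AAT", "ATT"))
#' @export
nucleotideDiversity <- function(x) {
  m <- .as_base_matrix(x)
  if (nrow(m) < 2L) stop("nucleotide diversity needs n >= 2")
  pd <- .pairwise_diff_total(m)
  pi_locus <- pd$total / pd$npairs
  list(pi_locus = pi_locus, pi_site = pi_locus / ncol(m))
}

#' Tajima's D
#'
#' D = (khat - S/a1) / sqrt(e1 S + e2 S (S-1)) with Tajima's constants
#' a1, a2, b1, b2, c1, c2, e1, e2 computed from the sample size. Undefined
#' (returned as \code{NA}) when S = 0.
#'
#' @param x alignment as in \code{\link{nucleotideDiversity}}.
#' @return numeric scalar, \code{NA_real_} when undefined.
#' @examples
#' tajimasD(c("AAA", "AAA", "AAT", "ATT"))
#' @export
tajimasD <- function(x) {
  m <- .as_base_matrix(x)
  n <- nrow(m)
  if (n < 2L) stop("Tajima's D needs n >= 2")
  S <- .count_segregating(m)
  if (S == 0L) return(NA_real_)
  khat <- nucleotideDiversity(m)$pi_locus
  a1 <- .harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log of unsigned Stirling numbers of the first kind |s(n, k)| for k = 1..n
.log_stirling_first <- function(n) {
  ls <- -Inf
  ls[1L] <- 0                       # |s(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in seq_len(n - 1L)) {
    # |s(m+1,k)| = |s(m,k-1)| + m * |s(m,k)|
    nxt <- numeric(m + 1L)
    prev <- c(ls, -Inf)
    shifted <- c(-Inf, ls)
    scaled <- prev + log(m)
    hi <- pmax(shifted, scaled)
    nxt <- hi + log1p(exp(pmin(shifted, scaled) - hi))
    nxt[!is.finite(hi)] <- -Inf
    ls <- nxt
  }
  ls
}

#' Ewens sampling distribution of the number of alleles
#'
#' P(K = k) = |s(n,k)| theta^k / theta^(n) for k = 1..n, where |s| are
#' unsigned Stirling numbers of the first kind and theta^(n) is the rising
#' factorial. Computed in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation rate (> 0).
#' @return numeric vector of probabilities over k = 1..n (sums to 1).
#' @examples
#' sum(ewensDistribution(10, 2.5))
#' @export
ewensDistribution <- function(n, theta) {
  stopifnot(n >= 1L, theta > 0)
  ls <- .log_stirling_first(n)
  log_rising <- sum(log(theta + 0:(n - 1L)))
  exp(ls + seq_len(n) * log(theta) - log_rising)
}

#' Fu's F_S
#'
#' With theta-hat set to the mean number of pairwise differences, S' is the
#' probability under the Ewens sampling distribution of observing at least
#' as many distinct alleles as seen; F_S = ln(S'/(1 - S')). Strongly
#' negative values indicate an excess of alleles (e.g. population growth).
#' Undefined (\code{NA}) when theta-hat = 0 or when only one allele is
#' observed (S' = 1).
#'
#' @param x alignment as in \code{\link{nucleotideDiversity}}.
#' @return numeric scalar, \code{NA_real_} when undefined (an attribute
#'   \code{"reason"} names the boundary case).
#' @examples
#' fusFS(c("AAA", "AAA", "AAT", "ATT"))
#' @export
fusFS <- function(x) {
  m <- .as_base_matrix(x)
  n <- nrow(m)
  if (n < 2L) stop("Fu's F_S needs n >= 2")
  theta <- nucleotideDiversity(m)$pi_locus
  k_obs <- length(unique(apply(m, 1L, paste, collapse = "")))
  if (theta <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "theta_hat_zero"
    return(out)
  }
  if (k_obs <= 1L) {
    out <- NA_real_
    attr(out, "reason") <- "single_allele"
    return(out)
  }
  pk <- ewensDistribution(n, theta)
  sprime <- sum(pk[k_obs:n])
  if (sprime >= 1 - 1e-15) {
    out <- NA_real_
    attr(out, "reason") <- "s_prime_one"
    return(out)
  }
  log(sprime / (1 - sprime))
}

#' Uncorrected p-distance matrix
#'
#' Proportion of differing columns for every pair of sequences.
#'
#' @param x alignment as in \code{\link{nucleotideDiversity}} (typically the
#'   distinct alleles of a dataset).
#' @return symmetric numeric matrix with zero diagonal, entries in [0, 1].
#' @examples
#' pDistanceMatrix(c(a = "AAA", b = "ATT"))
#' @export
pDistanceMatrix <- function(x) {
  m <- .as_base_matrix(x)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- mean(m[i, ] != m[j, ])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Full population-genetic summary of a dataset
#'
#' All eight statistics used throughout the bias analysis, computed on the
#' analysed alignment (original or pruned): the four polymorphism measures
#' plus Watterson's theta, pi, Tajima's D and Fu's F_S.
#'
#' @param x a \code{\linkS4class{TruthDataset}}.
#' @return one-row data.frame with columns \code{S}, \code{A_N}, \code{G_N},
#'   \code{H_O}, \code{ambiguous}, \code{theta_w_locus}, \code{theta_w_site},
#'   \code{pi_locus}, \code{pi_site}, \code{tajima_d}, \code{fu_fs},
#'   \code{n_sequences}, \code{length}.
#' @export
popGenSummary <- function(x) {
  stopifnot(is(x, "TruthDataset"))
  m <- .as_base_matrix(alleles(x))
  s <- summarizePolymorphism(x)
  th <- wattersonTheta(s$S, s$n_sequences, s$length)
  pi <- nucleotideDiversity(m)
  fs <- fusFS(m)
  data.frame(S = s$S, A_N = s$A_N, G_N = s$G_N, H_O = s$H_O,
             ambiguous = s$ambiguous,
             theta_w_locus = th$theta_locus, theta_w_site = th$theta_site,
             pi_locus = pi$pi_locus, pi_site = pi$pi_site,
             tajima_d = tajimasD(m), fu_fs = as.numeric(fs),
             n_sequences = s$n_sequences, length = s$length)
}
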