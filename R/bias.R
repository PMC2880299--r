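# Bias from omitting unresolved genotypes: pruning, signed deltas,
# one-tailed paired t-tests, simple regressions.

#' Remove unresolved individuals from a dataset
#'
#' Drops the listed individuals and both of their allele copies; alignment
#' columns are retained even if monomorphic afterwards, so per-site
#' statistics remain comparable with the original dataset.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param unresolved_ids individual ids to remove (subset of the dataset).
#' @return a pruned \code{\linkS4class{TruthDataset}} whose provenance
#'   records the removal.
#' @export
pruneUnresolved <- function(truth, unresolved_ids) {
  p <- pairing(truth)
  if (!all(unresolved_ids %in% p$individual))
    stop("unresolved ids not in dataset")
  keep <- !(p$individual %in% unresolved_ids)
  if (sum(keep) < 1L)
    stop("pruning would leave fewer than 2 sequences")
  p2 <- p[keep, , drop = FALSE]
  rownames(p2) <- NULL
  ids <- c(rbind(p2$allele_a, p2$allele_b))
  prov <- provenance(truth)
  prov$pruned <- sort(unresolved_ids)
  newTruthDataset(alleles(truth)[ids], p2,
                  consensusGenotypes(truth)[p2$individual], prov)
}

#' Signed parameter deltas from pruning, one row per dataset
#'
#' Orientation follows the reported bias directions: diversity loss is
#' positive (original minus pruned theta and pi) and neutrality-statistic
#' inflation is positive (pruned minus original D and F_S), so positive
#' values always mean bias in the expected direction. Deltas are 0 when
#' nothing was pruned and missing when a statistic is undefined on either
#' side.
#'
#' @param originals,pruned lists (or single rows) of
#'   \code{\link{popGenSummary}} data.frames, matched by position.
#' @param threshold confidence threshold the pruning was done at (recorded).
#' @param ids dataset ids (default names of \code{originals} or positions).
#' @return data.frame with columns \code{dataset}, \code{threshold},
#'   \code{n_omitted}, \code{d_theta_w} (per site), \code{d_pi} (per site),
#'   \code{d_tajima_d}, \code{d_fu_fs}, \code{rel_theta_reduction}.
#' @export
computeBiasTable <- function(originals, pruned, threshold = NA_real_,
                             ids = NULL) {
  if (is.data.frame(originals)) originals <- list(originals)
  if (is.data.frame(pruned)) pruned <- list(pruned)
  stopifnot(length(originals) == length(pruned))
  if (is.null(ids))
    ids <- if (!is.null(names(originals))) names(originals)
           else as.character(seq_along(originals))
  rows <- lapply(seq_along(originals), function(i) {
    o <- originals[[i]]
    pr <- pruned[[i]]
    n_omitted <- (o$n_sequences - pr$n_sequences) %/% 2L
    delta <- function(a, b) {
      if (is.na(a) || is.na(b)) NA_real_ else a - b
    }
    data.frame(dataset = ids[i], threshold = threshold,
               n_omitted = n_omitted,
               d_theta_w = delta(o$theta_w_site, pr$theta_w_site),
               d_pi = delta(o$pi_site, pr$pi_site),
               d_tajima_d = delta(pr$tajima_d, o$tajima_d),
               d_fu_fs = delta(pr$fu_fs, o$fu_fs),
               rel_theta_reduction =
                 delta(o$theta_w_site, pr$theta_w_site) / o$theta_w_site,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-tailed paired t-test
#'
#' Standard paired t on the differences x - y, with the one-tailed P value
#' in an a-priori direction.
#'
#' @param x,y paired numeric vectors (equal length >= 2); pairs with a
#'   missing value on either side are dropped.
#' @param direction \code{"greater"} (x tends to exceed y) or
#'   \code{"less"}.
#' @return list with \code{t}, \code{df}, \code{p} (one-tailed) and
#'   \code{degenerate} (TRUE when the differences have zero variance).
#' @examples
#' pairedOneTailedT(c(1, 2, 3), c(0, 0, 0), "greater")
#' @export
pairedOneTailedT <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  if (var(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1L,
                p = if (mean(d) == 0) 0.5 else NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Ordinary least-squares regression with F test of the slope
#'
#' @param x predictor (variance > 0), \code{y} response; length >= 3.
#' @param y response vector.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{f}, \code{df1}, \code{df2}, \code{p}.
#' @examples
#' simpleRegression(1:5, 2 * (1:5))
#' @export
simpleRegression <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("constant predictor")
  if (var(y) == 0) {
    return(list(slope = 0, intercept = y[1L], r_squared = 0, f = 0,
                df1 = 1L, df2 = length(x) - 2L, p = 1))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  if (is.null(fstat)) {            # zero residual d.f. cannot happen at n>=3
    stop("degenerate fit")
  }
  p <- pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared, f = unname(fstat[1L]),
       df1 = unname(fstat[2L]), df2 = unname(fstat[3L]), p = unname(p))
}
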