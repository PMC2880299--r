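# IUPAC ambiguity handling for diploid consensus sequences.
#
# Only the four bases and the six two-base ambiguity codes are legal in
# consensus input: a diploid individual can show at most two states per site.

.BASES <- c("A", "C", "G", "T")

# two-base code lookup, e.g. "AT" -> "W"; keys are sorted base pairs
.pair_to_code <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  two <- map[nchar(map) == 2L]
  setNames(names(two), vapply(strsplit(two, ""), function(b)
    paste(sort(b), collapse = ""), ""))
})

# code -> character vector of constituent bases ("W" -> c("A","T"))
.code_to_bases <- local({
  map <- Biostrings::IUPAC_CODE_MAP[nchar(Biostrings::IUPAC_CODE_MAP) <= 2L]
  lapply(setNames(strsplit(unname(map), ""), names(map)), sort)
})

#' Collapse two bases into their IUPAC consensus code
#'
#' Vectorised over positions: equal bases return the base itself, differing
#' bases return the two-base ambiguity code (the exact set union of the two
#' states, so the collapse is lossless up to phase).
#'
#' @param a,b character vectors of single bases in \code{A,C,G,T}.
#' @return character vector of consensus codes.
#' @examples
#' iupacConsensus(c("A", "C", "G"), c("A", "T", "G"))
#' @export
iupacConsensus <- function(a, b) {
  stopifnot(length(a) == length(b))
  bad <- !(a %in% .BASES) | !(b %in% .BASES)
  if (any(bad))
    stop("non-ACGT base at position(s): ", paste(which(bad), collapse = ", "))
  out <- a
  het <- a != b
  if (any(het)) {
    key <- ifelse(a[het] < b[het], paste0(a[het], b[het]), paste0(b[het], a[het]))
    out[het] <- .pair_to_code[key]
  }
  out
}

#' Expand an IUPAC code into its one or two constituent bases
#'
#' @param code a single-character IUPAC code; only the four bases and the six
#'   two-base codes are accepted (a diploid shows at most two states per site).
#' @return character vector of one or two bases, sorted.
#' @export
iupacBases <- function(code) {
  out <- .code_to_bases[[code]]
  if (is.null(out))
    stop("invalid diploid consensus code '", code, "'")
  out
}

# matrix of IUPAC codes (individuals x sites) -> list(baseA, baseB, het)
# baseA/baseB: base matrices with baseA <= baseB alphabetically at het sites;
# het: logical matrix of two-state positions. Errors name the offending
# individual and 1-based position for any >2-state or unknown code.
.decode_genotype_matrix <- function(gm) {
  legal <- names(.code_to_bases)
  bad <- which(matrix(!(gm %in% legal), nrow(gm)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid ambiguity code '", gm[bad[1L, 1L], bad[1L, 2L]],
         "' in individual ", rownames(gm)[bad[1L, 1L]],
         " at position ", bad[1L, 2L])
  }
  het <- matrix(gm %in% .pair_to_code, nrow(gm), ncol(gm),
                dimnames = dimnames(gm))
  baseA <- gm
  baseB <- gm
  if (any(het)) {
    codes <- gm[het]
    first <- vapply(codes, function(cd) .code_to_bases[[cd]][1L], "")
    second <- vapply(codes, function(cd) .code_to_bases[[cd]][2L], "")
    baseA[het] <- first
    baseB[het] <- second
  }
  list(baseA = baseA, baseB = baseB, het = het)
}
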