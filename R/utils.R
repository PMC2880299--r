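# shared internal helpers

# coerce DNAStringSet / named character vector / matrix to a base matrix
# (rows = sequences, columns = alignment sites)
.as_base_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is(x, "DNAStringSet") || is(x, "BStringSet"))
    x <- setNames(as.character(x), names(x))
  if (!is.character(x))
    stop("cannot interpret input as an alignment")
  if (length(unique(nchar(x))) > 1L)
    stop("ragged alignment: sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

# number of alignment columns with >= 2 states (segregating sites)
.count_segregating <- function(m) {
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

# indices of segregating columns
.which_segregating <- function(m) {
  which(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

# harmonic number sum_{i=1}^{k} 1/i
.harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))

# canonical unordered pair key for two haplotype strings
.pair_key <- function(h1, h2) {
  ifelse(h1 <= h2, paste(h1, h2, sep = "|"), paste(h2, h1, sep = "|"))
}
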