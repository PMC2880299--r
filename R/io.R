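# Readers/writers and preprocessing transforms: FASTA, genotype tables,
# PHASE-format input, indel recoding, column masking, suite manifests.

#' Read an aligned FASTA file
#'
#' @param path FASTA file; sequences must form an alignment (equal
#'   lengths). Lowercase letters are normalised to uppercase with a
#'   warning. IUPAC ambiguity letters are permitted (consensus files).
#' @return \code{DNAStringSet}.
#' @export
readFastaAlignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(raw)
  if (length(unique(w)) > 1L) {
    off <- names(raw)[w != w[1L]]
    stop("ragged alignment in ", path, "; offending ids: ",
         paste(off, collapse = ", "))
  }
  chr <- as.character(raw)
  if (any(grepl("[a-z]", chr)))
    warning("lowercase bases normalised to uppercase")
  Biostrings::DNAStringSet(setNames(toupper(chr), names(raw)))
}

#' Write an alignment to FASTA
#'
#' @param x \code{DNAStringSet} or named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFastaAlignment <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a genotype pairing table
#'
#' Tab-separated with columns \code{individual}, \code{allele_a},
#' \code{allele_b}; ids must be unique per individual.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readGenotypeTable <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "allele_a", "allele_b")
  if (!all(need %in% names(tb)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tb$individual))
    stop("duplicate individual ids in genotype table")
  tb[need]
}

#' @rdname readGenotypeTable
#' @param table data.frame to write.
#' @export
writeGenotypeTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TruthDataset to disk
#'
#' Emits the three per-dataset files: FASTA of the 2N phase-known alleles,
#' FASTA of the N ambiguity-coded consensus genotypes, and the
#' tab-separated truth pairing table.
#'
#' @param truth a \code{\linkS4class{TruthDataset}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the three paths.
#' @export
writeTruthDataset <- function(truth, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_alleles <- file.path(dir, paste0(prefix, "_alleles.fasta"))
  p_geno <- file.path(dir, paste0(prefix, "_genotypes.fasta"))
  p_tab <- file.path(dir, paste0(prefix, "_pairing.tsv"))
  writeFastaAlignment(alleles(truth), p_alleles)
  writeFastaAlignment(consensusGenotypes(truth), p_geno)
  writeGenotypeTable(pairing(truth), p_tab)
  invisible(c(alleles = p_alleles, genotypes = p_geno, pairing = p_tab))
}

#' Read a TruthDataset written by \code{\link{writeTruthDataset}}
#'
#' @param alleles_path,pairing_path paths to the allele FASTA and pairing
#'   table; consensus genotypes are recomputed from them.
#' @return a \code{\linkS4class{TruthDataset}}.
#' @export
readTruthDataset <- function(alleles_path, pairing_path) {
  newTruthDataset(readFastaAlignment(alleles_path),
                  readGenotypeTable(pairing_path))
}

#' Write PHASE-format genotype input
#'
#' Plain-text genotype format for external phasing software: line 1 the
#' number of individuals, line 2 the number of variable sites, line 3 "P"
#' followed by the 1-based positions of the variable sites, line 4 one type
#' letter per site (S biallelic, M multiallelic, including recoded indel
#' columns), then per individual an id line and two rows giving the
#' unordered allele states at each variable site (heterozygous ambiguity
#' codes expanded to their two bases; row order arbitrary).
#'
#' @param genotypes \code{DNAStringSet} / named character vector of
#'   consensus genotypes, or a \code{\linkS4class{TruthDataset}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePhaseInput <- function(genotypes, path) {
  p <- .parse_genotypes(genotypes)
  V <- p$vcols
  nstates <- vapply(V, function(j)
    length(unique(c(p$baseA[, j], p$baseB[, j]))), 0L)
  types <- ifelse(nstates > 2L, "M", "S")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(p$gm)), con)
  writeLines(as.character(length(V)), con)
  writeLines(paste(c("P", V), collapse = " "), con)
  writeLines(paste(types, collapse = ""), con)
  for (i in seq_len(nrow(p$gm))) {
    writeLines(paste0("#", p$individuals[i]), con)
    writeLines(paste(p$baseA[i, V], collapse = " "), con)
    writeLines(paste(p$baseB[i, V], collapse = " "), con)
  }
  invisible(path)
}

#' Read externally produced phase calls
#'
#' Tabular adapter so reconstructions from external phasing software can be
#' scored with \code{\link{evaluateDataset}}: tab-separated columns
#' \code{individual}, \code{hap1}, \code{hap2}, \code{prob}.
#'
#' @param path file path.
#' @param threshold confidence threshold to apply.
#' @param n_het optional named vector of heterozygous-site counts; when
#'   omitted it is recomputed from the haplotype pairs.
#' @return a \code{\linkS4class{ThresholdedResult}}.
#' @export
readExternalCalls <- function(path, threshold, n_het = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "hap1", "hap2", "prob")
  if (!all(need %in% names(tb)))
    stop("external calls need columns ", paste(need, collapse = ", "))
  if (is.null(n_het)) {
    tb$n_het <- mapply(function(a, b)
      sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]), tb$hap1, tb$hap2)
  } else {
    tb$n_het <- unname(n_het[tb$individual])
  }
  tb$resolved <- tb$prob >= threshold
  new("ThresholdedResult", threshold = threshold,
      calls = tb[c("individual", "hap1", "hap2", "prob", "n_het", "resolved")])
}

#' Recode indel columns as single presence/absence characters
#'
#' Each maximal run of gap-containing columns (union of gap coordinates
#' across sequences) is treated as one insertion/deletion event and
#' collapsed to a single column, encoded with two designated nucleotide
#' letters: \code{present} for sequences carrying the deletion (a gap
#' anywhere in the run) and \code{absent} otherwise. Discontiguous runs are
#' separate events. Non-indel columns are unchanged.
#'
#' @param x alignment possibly containing \code{-} gap characters
#'   (character vector or matrix; \code{DNAStringSet} accepted).
#' @param present,absent the two encoding letters (defaults T and A).
#' @return \code{DNAStringSet} of the recoded alignment.
#' @export
recodeIndels <- function(x, present = "T", absent = "A") {
  if (is(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  m <- if (is.matrix(x)) x else {
    if (length(unique(nchar(x))) > 1L) stop("ragged alignment")
    mm <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mm) <- names(x)
    mm
  }
  gapcol <- apply(m, 2L, function(col) any(col == "-"))
  if (!any(gapcol)) {
    return(Biostrings::DNAStringSet(setNames(apply(m, 1L, paste, collapse = ""),
                                             rownames(m))))
  }
  r <- rle(gapcol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_cols <- list()
  pos <- 1L
  out <- NULL
  for (k in seq_along(r$lengths)) {
    block <- m[, starts[k]:ends[k], drop = FALSE]
    if (r$values[k]) {
      has_gap <- apply(block, 1L, function(z) any(z == "-"))
      out <- cbind(out, ifelse(has_gap, present, absent))
    } else {
      out <- cbind(out, block)
    }
  }
  Biostrings::DNAStringSet(setNames(apply(out, 1L, paste, collapse = ""),
                                    rownames(m)))
}

#' Remove alignment columns by 1-based inclusive ranges
#'
#' @param x alignment (\code{DNAStringSet}, character vector or matrix).
#' @param ranges two-column matrix or list of \code{c(start, end)} pairs,
#'   1-based inclusive; ranges must lie within the alignment and must not
#'   overlap.
#' @return \code{DNAStringSet} with the listed columns removed.
#' @examples
#' maskColumns(c(s = "ACGTACGT"), rbind(c(3, 4)))
#' @export
maskColumns <- function(x, ranges) {
  m <- .as_base_matrix(x)
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2L)
  if (nrow(ranges) == 0L)
    return(Biostrings::DNAStringSet(setNames(apply(m, 1L, paste, collapse = ""),
                                             rownames(m))))
  if (any(ranges[, 1L] > ranges[, 2L]))
    stop("range start exceeds end")
  if (any(ranges < 1L) || any(ranges > ncol(m)))
    stop("mask range outside alignment (length ", ncol(m), ")")
  cols <- unlist(lapply(seq_len(nrow(ranges)), function(i)
    ranges[i, 1L]:ranges[i, 2L]))
  if (anyDuplicated(cols)) stop("overlapping mask ranges")
  keep <- setdiff(seq_len(ncol(m)), cols)
  Biostrings::DNAStringSet(setNames(
    apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""), rownames(m)))
}

#' Write a suite manifest to TSV
#'
#' @param manifest data.frame from \code{\link{suiteManifest}}.
#' @param path output file; a comment header records the package version
#'   and master seed so the suite is regenerable from the manifest alone.
#' @param config optional \code{\link{simulationConfig}} whose seed goes in
#'   the header.
#' @return invisibly, the path.
#' @export
writeSuiteManifest <- function(manifest, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("phasebias"))
  seed <- if (is.null(config)) NA else config$seed
  writeLines(sprintf("# phasebias %s suite manifest; master seed = %s",
                     ver, seed), con)
  suppressWarnings(write.table(manifest, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Published dataset characteristics
#'
#' Summary characteristics (sample size, ambiguous-genotype count and the
#' four polymorphism measures) reported for five experimentally phased
#' Collembola nuclear loci -- per population and pooled per locus -- and for
#' the 35 coalescent-simulated comparison datasets of the published phasing
#' assessment this package models. Useful as a reference point for the
#' simulation design and for aggregate checks.
#'
#' @return data.frame with columns \code{dataset}, \code{kind}
#'   (\code{empirical_pop}, \code{empirical_pooled}, \code{simulated}),
#'   \code{N}, \code{ambiguous}, \code{S}, \code{A_N}, \code{G_N},
#'   \code{H_O}.
#' @export
studyCharacteristics <- function() {
  path <- system.file("extdata", "dataset_characteristics.tsv",
                      package = "phasebias", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
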