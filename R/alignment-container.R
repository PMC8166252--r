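#' Codon alignment container
#'
#' A codon alignment is a taxa x codon-column character matrix whose entries
#' are 3-letter codons over `{A,C,G,T,N}` or the gap codon `"---"`. In-frame
#' stop codons are rejected (the 61-state likelihood machinery has no stop
#' state); codons containing `N` or partial gaps are treated as missing data
#' downstream, not masked.
#'
#' @param codons Character matrix (rows = taxa, with rownames) of 3-letter
#'   codons, or a named character vector of equal-length in-frame CDS strings.
#' @return An object of class `codon_aln` with fields `taxa` and `codons`.
#' @export
codon_alignment <- function(codons) {
  if (is.character(codons) && is.null(dim(codons))) {
    if (is.null(names(codons))) stop("sequences must be named by taxon")
    w <- unique(nchar(codons))
    if (length(w) != 1L || w %% 3L != 0L) {
      stop("sequences must share a length divisible by 3")
    }
    codons <- t(vapply(codons, function(s) {
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    }, character(w / 3)))
  }
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  if (any(nchar(codons) != 3L)) stop("all entries must be 3-letter codons")
  bad <- codons %in% .codon_tables$stops
  if (any(bad)) {
    stop("in-frame stop codon present (first at row ",
         rownames(codons)[row(codons)[bad][1]], ", column ",
         col(codons)[bad][1], "); curate the alignment upstream")
  }
  structure(list(taxa = rownames(codons), codons = codons),
            class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa x", ncol(x$codons),
      "codon columns\n")
  invisible(x)
}

#' Alignment width in codon columns
#' @param aln A `codon_aln`.
#' @return Integer.
#' @export
n_codons <- function(aln) ncol(aln$codons)

# integer state matrix (taxa x sites), NA for gap/N, rows ordered as `taxa`
aln_states <- function(aln, taxa = aln$taxa) {
  m <- aln$codons[taxa, , drop = FALSE]
  st <- matrix(codon_index(m), nrow = length(taxa))
  rownames(st) <- taxa
  st
}

# collapse equal site patterns; returns 0-coded missing for the C++ core
compress_patterns <- function(states) {
  st <- states
  st[is.na(st)] <- 0L
  key <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(key)
  list(states = st[, first, drop = FALSE],
       weights = as.vector(table(factor(key, levels = key[first]))),
       map = match(key, key[first]))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_aln`.
#' @param path Output file.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), path)
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of equal-length, in-frame nucleotide sequences
#'   (gap character `-`).
#' @return A `codon_aln`.
#' @export
read_codon_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)))
}
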