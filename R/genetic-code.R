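#' @useDynLib primsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Universal genetic code over the 61 sense codons. State order is fixed
# package-wide: lexicographic in (A, C, G, T) with stop codons removed.
.codon_tables <- local({
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  sense <- all64[aa != "*"]
  list(
    bases = bases,
    codons = sense,                       # 61 sense codons
    stops = all64[aa == "*"],
    aa = unname(gc[sense]),               # amino acid per sense codon
    index = stats::setNames(seq_along(sense), sense)
  )
})

#' Sense codons of the universal genetic code
#'
#' The 61 sense codons in the fixed state order used throughout the package
#' (lexicographic, stop codons removed).
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .codon_tables$codons

#' Map codon strings to state indices
#'
#' @param codons Character vector of 3-letter codons. Gap (`"---"`) and codons
#'   containing `N` (or any non-ACGT character) map to `NA`, the missing-data
#'   state.
#' @return Integer vector of indices into [sense_codons()], `NA` for missing.
#' @export
codon_index <- function(codons) {
  idx <- .codon_tables$index[codons]
  unname(idx)
}

# amino acid for each sense codon index
codon_aa <- function() .codon_tables$aa

# TRUE if single-nucleotide change i->j at position k is a transition
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Estimate equilibrium codon frequencies from a codon alignment
#'
#' `F3x4` uses position-specific nucleotide frequencies, `F1x4` a single
#' nucleotide frequency vector, `equal` the uniform distribution. Frequencies
#' of stop codons are redistributed by renormalisation over the 61 sense
#' codons. A pseudocount keeps all frequencies strictly positive on sparse
#' alignments.
#'
#' @param aln A `codon_aln` object (see [codon_alignment()]).
#' @param method One of `"F3x4"`, `"F1x4"`, `"equal"`.
#' @param pseudocount Added to every nucleotide count (default 0.5).
#' @return Numeric vector of length 61 summing to 1, strictly positive.
#' @export
codon_frequencies <- function(aln, method = c("F3x4", "F1x4", "equal"),
                              pseudocount = 0.5) {
  method <- match.arg(method)
  if (method == "equal") {
    return(rep(1 / 61, 61))
  }
  stopifnot(inherits(aln, "codon_aln"))
  mat <- aln$codons
  cods <- mat[mat != "---" & !is.na(mat)]
  chars <- matrix(unlist(strsplit(cods, "")), ncol = 3, byrow = TRUE)
  bases <- .codon_tables$bases
  count_pos <- function(x) {
    cnt <- table(factor(x[x %in% bases], levels = bases))
    as.numeric(cnt) + pseudocount
  }
  if (method == "F3x4") {
    f <- lapply(1:3, function(k) {
      v <- count_pos(chars[, k]); v / sum(v)
    })
  } else {
    v <- count_pos(as.vector(chars))
    f <- rep(list(v / sum(v)), 3)
  }
  names(f[[1]]) <- names(f[[2]]) <- names(f[[3]]) <- bases
  cod <- .codon_tables$codons
  pi <- f[[1]][substr(cod, 1, 1)] * f[[2]][substr(cod, 2, 2)] *
    f[[3]][substr(cod, 3, 3)]
  pi <- as.numeric(pi)
  if (any(pi <= 0)) stop("degenerate codon frequency vector")
  pi / sum(pi)
}
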