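# Translation, protein multiple alignment and back-translation to codons.
# The internal aligner is a deterministic progressive profile aligner
# (BLOSUM62, affine gaps) guided by the species tree; fidelity to any
# specific external aligner is not a goal, determinism is.

#' Translate a CDS to protein
#'
#' Universal genetic code; a terminal stop codon is trimmed; codons
#' containing `N` translate to `X`. An internal stop codon is an error (it
#' signals mis-annotation and the gene should be flagged upstream).
#'
#' @param cds DNA string over `{A,C,G,T,N}`, length divisible by 3.
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGTN]", cds)) stop("CDS may contain only A, C, G, T, N")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X", unname(gc[codons]))
  if (length(aa) > 1 && aa[length(aa)] == "*" && !is.na(aa[length(aa)])) {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  internal <- which(aa == "*")
  if (length(internal)) {
    stop("internal stop at codon ", internal[1])
  }
  paste(aa, collapse = "")
}

# ---- progressive profile alignment ----------------------------------------

.blosum62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# profile: list of aligned row strings (equal length); scored column-wise by
# average BLOSUM62 over residue pairs, gaps scored by affine penalties
.profile_cols <- function(rows) {
  do.call(rbind, strsplit(rows, ""))
}

# Gotoh profile-profile alignment; returns merged row strings
.align_profiles <- function(rows_a, rows_b, gap_open = 10, gap_extend = 0.5) {
  A <- .profile_cols(rows_a); B <- .profile_cols(rows_b)
  la <- ncol(A); lb <- ncol(B)
  sub <- .blosum62
  aa_levels <- rownames(sub)
  # column score: mean pairwise substitution score between non-gap residues
  col_codes <- function(M) {
    apply(M, 2, function(col) {
      r <- col[col != "-"]
      match(r, aa_levels)
    }, simplify = FALSE)
  }
  ca <- col_codes(A); cb <- col_codes(B)
  score_cols <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    ri <- ca[[i]]
    if (!length(ri)) next
    for (j in seq_len(lb)) {
      rj <- cb[[j]]
      if (!length(rj)) next
      score_cols[i, j] <- mean(sub[ri, rj, drop = FALSE])
    }
  }
  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)  # match/mismatch state
  X <- matrix(NEG, la + 1, lb + 1)  # gap in B (consume A)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in A (consume B)
  M[1, 1] <- 0
  for (i in 2:(la + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(lb + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  ptrM <- matrix(0L, la + 1, lb + 1)
  ptrX <- matrix(0L, la + 1, lb + 1)
  ptrY <- matrix(0L, la + 1, lb + 1)
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      s <- score_cols[i - 1, j - 1]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s; ptrM[i, j] <- k
      candx <- c(M[i - 1, j] - gap_open - gap_extend,
                 X[i - 1, j] - gap_extend)
      kx <- which.max(candx)
      X[i, j] <- candx[kx]; ptrX[i, j] <- kx
      candy <- c(M[i, j - 1] - gap_open - gap_extend,
                 Y[i, j - 1] - gap_extend)
      ky <- which.max(candy)
      Y[i, j] <- candy[ky]; ptrY[i, j] <- ky
    }
  }
  # traceback
  i <- la + 1; j <- lb + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  path <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1L) {
      path <- c("M", path); k <- ptrM[i, j]; i <- i - 1; j <- j - 1
      state <- k
    } else if (state == 2L) {
      path <- c("X", path); k <- ptrX[i, j]; i <- i - 1
      state <- if (k == 1L) 1L else 2L
    } else {
      path <- c("Y", path); k <- ptrY[i, j]; j <- j - 1
      state <- if (k == 1L) 1L else 3L
    }
  }
  ia <- 0L; jb <- 0L
  outA <- matrix("-", nrow(A), length(path))
  outB <- matrix("-", nrow(B), length(path))
  for (s in seq_along(path)) {
    if (path[s] != "Y") { ia <- ia + 1L; outA[, s] <- A[, ia] }
    if (path[s] != "X") { jb <- jb + 1L; outB[, s] <- B[, jb] }
  }
  c(apply(outA, 1, paste, collapse = ""),
    apply(outB, 1, paste, collapse = ""))
}

#' Progressive protein multiple alignment
#'
#' Aligns sequences progressively following the guide tree (profiles merged
#' at each internal node, deepest nodes first) with BLOSUM62 scores and
#' affine gap penalties. Deterministic for fixed inputs.
#'
#' @param seqs Named character vector of protein sequences (>= 2, non-empty),
#'   names must be tips of `guide`.
#' @param guide `phylo` guide tree whose tip set covers `names(seqs)`.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A `protein_msa`: list with `taxa` and equal-length `rows`.
#' @export
align_proteins <- function(seqs, guide, gap_open = 10, gap_extend = 0.5) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (is.null(names(seqs)) || !all(names(seqs) %in% guide$tip.label)) {
    stop("sequence labels must match guide-tree tips")
  }
  tr <- ape::keep.tip(guide, names(seqs))
  po <- stats::reorder(tr, "postorder")
  profiles <- list()
  for (tip in seq_along(po$tip.label)) {
    profiles[[tip]] <- stats::setNames(list(seqs[[po$tip.label[tip]]]),
                                       po$tip.label[tip])
  }
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    pr <- profiles[[child]]
    if (length(profiles) < parent || is.null(profiles[parent][[1]])) {
      profiles[[parent]] <- pr
    } else {
      merged <- .align_profiles(unlist(profiles[[parent]]), unlist(pr),
                                gap_open, gap_extend)
      profiles[[parent]] <- stats::setNames(
        as.list(merged), c(names(profiles[[parent]]), names(pr)))
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  rows <- unlist(profiles[[root]])
  structure(list(taxa = names(rows), rows = unname(rows)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein MSA:", length(x$taxa), "taxa x", nchar(x$rows[1]),
      "columns\n")
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino acid is replaced by its source codon from the taxon's CDS and
#' each protein gap by `"---"`; output width is three times the protein
#' width. Every row's ungapped translation must equal the translation of its
#' CDS.
#'
#' @param msa A `protein_msa`.
#' @param cds_by_taxon Named character vector of CDS.
#' @return A `codon_aln`.
#' @export
back_translate <- function(msa, cds_by_taxon) {
  rows <- lapply(seq_along(msa$taxa), function(i) {
    taxon <- msa$taxa[i]
    cds <- cds_by_taxon[[taxon]]
    if (is.null(cds)) stop("no CDS for taxon ", taxon)
    prot <- translate_cds(cds)
    row <- strsplit(msa$rows[i], "")[[1]]
    ungapped <- paste(row[row != "-"], collapse = "")
    if (ungapped != prot) {
      first <- which(strsplit(ungapped, "")[[1]] !=
                       strsplit(prot, "")[[1]])[1]
      stop("translation mismatch for ", taxon, " at position ", first)
    }
    codons <- substring(cds, seq(1, nchar(prot) * 3, 3),
                        seq(3, nchar(prot) * 3, 3))
    out <- rep("---", length(row))
    out[row != "-"] <- codons
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- msa$taxa
  codon_alignment(m)
}

#' Column mask for codon alignments
#'
#' @param drop_columns Integer vector of 1-based codon-column indices.
#' @param reason Character reasons (recycled).
#' @return A `column_mask`.
#' @export
column_mask <- function(drop_columns = integer(0), reason = "masked") {
  structure(list(drop_columns = as.integer(drop_columns),
                 reason = rep_len(reason, length(drop_columns))),
            class = "column_mask")
}

#' Apply a column mask to a codon alignment
#'
#' Removes the masked codon columns from all rows. A stand-in for manual
#' alignment curation; masks should be logged by the caller.
#'
#' @param aln A `codon_aln`.
#' @param mask A [column_mask()].
#' @return Masked `codon_aln`.
#' @export
apply_mask <- function(aln, mask) {
  if (!length(mask$drop_columns)) return(aln)
  if (any(mask$drop_columns < 1 | mask$drop_columns > n_codons(aln))) {
    stop("mask indices outside alignment width")
  }
  codon_alignment(aln$codons[, -mask$drop_columns, drop = FALSE])
}

#' Automatic gap-fraction mask
#'
#' Flags codon columns in which fewer than `min_nongap_fraction` of taxa
#' have a non-gap codon.
#'
#' @param aln A `codon_aln`.
#' @param min_nongap_fraction Default 0.5.
#' @return A [column_mask()] of the flagged columns.
#' @export
auto_mask <- function(aln, min_nongap_fraction = 0.5) {
  nongap <- colMeans(aln$codons != "---")
  column_mask(which(nongap < min_nongap_fraction),
              "gap fraction above threshold")
}

#' Map alignment columns to human codon coordinates
#'
#' @param aln A `codon_aln`.
#' @param human Taxon label of the human row (default `"Hsap"`).
#' @return Integer vector per alignment column: 1-based codon index in the
#'   ungapped human sequence, `NA` where human is gapped.
#' @export
human_codon_coordinates <- function(aln, human = "Hsap") {
  if (!human %in% aln$taxa) stop("human row not found")
  row <- aln$codons[human, ]
  idx <- cumsum(row != "---")
  idx[row == "---"] <- NA_integer_
  as.integer(idx)
}
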