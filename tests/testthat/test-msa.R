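test_that("CDS translation follows the universal code conventions", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("AGT"), "S")
  expect_equal(translate_cds("AGA"), "R")
  expect_equal(translate_cds("ATGAAATAA"), "MK") # terminal stop trimmed
  expect_equal(translate_cds("ATGANAAAA"), "MXK")
  expect_error(translate_cds("ATGTAAAAA"), "internal stop at codon 2")
  expect_error(translate_cds("ATGA"), "divisible by 3")
})

test_that("progressive alignment is deterministic and gap-free for equal rows", {
  guide <- toy_tree3()
  seqs <- c(A = "MKVLH", B = "MKVLH", C = "MKVLH")
  msa <- align_proteins(seqs, guide)
  expect_false(any(grepl("-", msa$rows)))
  expect_identical(align_proteins(seqs, guide)$rows, msa$rows)
  expect_error(align_proteins(c(A = "MK"), guide), "at least 2")
  expect_error(align_proteins(c(A = "MK", B = ""), guide), "empty")
  expect_error(align_proteins(c(A = "MK", Z = "MK"), guide), "labels")
})

test_that("two-sequence alignment achieves the optimal affine-gap score", {
  guide <- ape::read.tree(text = "(A:1,B:1);")
  sub <- primsel:::.blosum62
  set.seed(9)
  for (i in 1:4) {
    a <- random_protein(sample(8:20, 1), seed = 100 + i)
    b <- random_protein(sample(8:20, 1), seed = 200 + i)
    msa <- align_proteins(c(A = a, B = b), guide)
    got <- score_aligned_pair(msa$rows[msa$taxa == "A"],
                              msa$rows[msa$taxa == "B"], sub, 10, 0.5)
    expect_equal(got, gotoh_score(a, b, sub, 10, 0.5), tolerance = 1e-9)
  }
})

test_that("back-translation round-trips every CDS", {
  guide <- toy_tree3()
  cds <- c(A = random_cds(12, 1), B = random_cds(10, 2), C = random_cds(11, 3))
  prot <- vapply(cds, translate_cds, character(1))
  msa <- align_proteins(prot, guide)
  aln <- back_translate(msa, cds)
  expect_equal(n_codons(aln) * 3, nchar(msa$rows[1]) * 3)
  for (tx in aln$taxa) {
    row <- aln$codons[tx, ]
    expect_identical(paste(row[row != "---"], collapse = ""),
                     unname(cds[tx]))
  }
  # forced mapping example
  msa1 <- structure(list(taxa = c("x", "y"), rows = c("M-K", "MEK")),
                    class = "protein_msa")
  bt <- back_translate(msa1, c(x = "ATGAAA", y = "ATGGAGAAG"))
  expect_identical(unname(bt$codons["x", ]), c("ATG", "---", "AAA"))
  # mismatch reporting
  expect_error(back_translate(msa1, c(x = "ATGCCC", y = "ATGGAGAAG")),
               "mismatch for x at position 2")
})

test_that("masking removes columns and auto-mask flags gappy ones", {
  m <- matrix(c("ATG", "AAA", "CCC",
                "ATG", "---", "CCC",
                "ATG", "---", "CCA"), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), NULL))
  aln <- codon_alignment(m)
  expect_identical(apply_mask(aln, column_mask()), aln)
  masked <- apply_mask(aln, column_mask(1))
  expect_equal(n_codons(masked), 2)
  expect_identical(masked$codons, aln$codons[, 2:3])
  am <- auto_mask(aln, 0.5)
  expect_identical(am$drop_columns, 2L)
  expect_error(apply_mask(aln, column_mask(9)), "outside")

  # masking commutes with row re-ordering
  perm <- c("C", "A", "B")
  aln_perm <- codon_alignment(m[perm, ])
  expect_identical(apply_mask(aln_perm, column_mask(1))$codons,
                   apply_mask(aln, column_mask(1))$codons[perm, ])
})

test_that("human codon coordinates skip human gaps", {
  m <- matrix(c("ATG", "---", "AAA",
                "ATG", "CCC", "AAA"), nrow = 2, byrow = TRUE,
              dimnames = list(c("Hsap", "Ptro"), NULL))
  aln <- codon_alignment(m)
  expect_identical(human_codon_coordinates(aln), c(1L, NA_integer_, 2L))
})
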