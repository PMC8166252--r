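test_that("gene-set filter drops flagged genes and reconciles", {
  df <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   read_through = c(rep(TRUE, 2), rep(FALSE, 8)),
                   human_lineage_duplicate = c(rep(FALSE, 9), TRUE),
                   mane_isoform_id = "x")
  out <- filter_gene_set(df)
  expect_equal(nrow(out$retained), 7)
  expect_equal(nrow(out$excluded), 3)
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(df))
  expect_setequal(out$log$reason,
                  c("read_through", "human_lineage_duplicate"))

  clean <- df; clean$read_through <- FALSE; clean$human_lineage_duplicate <- FALSE
  out2 <- filter_gene_set(clean)
  expect_identical(out2$retained, clean)
  expect_equal(nrow(out2$excluded), 0)
})

test_that("pairwise identity follows its definition and an alignment oracle", {
  expect_equal(pairwise_identity("MKV", "MKV"), 1)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 5 / 6)
  expect_error(pairwise_identity("", "MK"), "empty")

  set.seed(31)
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "K")
  sub <- diag(1, length(alpha)); dimnames(sub) <- list(alpha, alpha)
  for (i in 1:6) {
    a <- paste(sample(alpha, sample(5:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(5:12, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-12)
    # the alignment underlying the identity achieves the optimal affine score
    al <- Biostrings::pairwiseAlignment(
      Biostrings::BString(a), Biostrings::BString(b), type = "global",
      substitutionMatrix = sub, gapOpening = 2, gapExtension = 0.5)
    expect_equal(Biostrings::score(al),
                 gotoh_score(a, b, sub, 2, 0.5), tolerance = 1e-9)
  }
})

test_that("human cluster selection keeps one isoform per close species", {
  h <- gene_record("g1", "Hsap",
                   c(hs1 = "MKVLLAGHTREW", hs2 = "MKVL"),
                   mane_isoform_id = "hs1")
  near <- function(sp, id, seq) gene_record("g1", sp, setNames(seq, id))
  orth <- list(
    near("Ptro", "pt1", "MKVLLAGHTREW"),
    near("Ptro", "pt2", "MKVLLAGHTREW"),   # duplicate isoform, same species
    near("Ggor", "gg1", "MKVLLAGHTKEW"),   # 11/12 identical
    near("Mmul", "mm1", "WWWWPPPPGGGG"))   # unrelated
  sel <- select_isoform_cluster(h, orth)
  expect_setequal(sel$species, c("Hsap", "Ptro", "Ggor"))
  expect_false("Mmul" %in% sel$species)
  expect_equal(sum(sel$species == "Ptro"), 1)
  expect_equal(sel$isoform_id[sel$species == "Hsap"], "hs1")
  expect_error(select_isoform_cluster(
    gene_record("g1", "Hsap", c(hs1 = "MKV")), orth), "MANE")
})

test_that("human-cluster membership matches the identity-graph oracle", {
  # two well-separated families of sequences: membership of the human
  # cluster must equal the connected component of the >= 0.8 identity graph
  base1 <- "MKVLLAGHTREWQSDF"
  base2 <- "GGPPWWNNCCYYHHII"
  mut <- function(s, k, seed) {
    set.seed(seed)
    x <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(x), k)
    x[pos] <- sample(c("A", "S", "T", "V"), k, replace = TRUE)
    paste(x, collapse = "")
  }
  seqs <- c(h = base1, a = mut(base1, 1, 1), b = mut(base1, 2, 2),
            c = base2, d = mut(base2, 1, 3), e = mut(base2, 2, 4))
  h <- gene_record("g", "Hsap", c(hs1 = seqs[["h"]]), mane_isoform_id = "hs1")
  orth <- lapply(names(seqs)[-1], function(nm)
    gene_record("g", paste0("sp_", nm), setNames(seqs[nm], nm)))
  sel <- select_isoform_cluster(h, orth)

  ids <- outer(seqs, seqs, Vectorize(function(x, y) pairwise_identity(x, y)))
  adj <- ids >= 0.8
  # connected component containing the human sequence (BFS)
  comp <- "h"; repeat {
    nxt <- unique(c(comp, names(seqs)[apply(
      adj[comp, , drop = FALSE], 2, any)]))
    if (setequal(nxt, comp)) break
    comp <- nxt
  }
  oracle_species <- c("Hsap", paste0("sp_", setdiff(comp, "h")))
  expect_setequal(sel$species, oracle_species)
})
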