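# shared small fixtures, built in code

toy_tree3 <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
}

toy_tree4 <- function(fg = "A") {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.2,D:0.15):0.2);")
  mark_foreground(tr, fg)
}

# 10-taxon catarrhine subtree of the default tree, human foreground
small_primate_tree <- function(scale = 0.05) {
  tr <- build_default_tree(scale, "Hominina")
  prune_tree(tr, c("Hsap", "Ptro", "Ppan", "Ggor", "Ppyg", "Nleu",
                   "Mmul", "Csab", "Cjac", "Tsyr"))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(rownames(primsel:::.blosum62)[1:20], n, replace = TRUE),
        collapse = "")
}

random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}
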