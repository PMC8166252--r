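# End-to-end orchestration: curation -> alignment -> dual gene-level tests
# -> site detection -> consensus -> population verification -> dating, with
# deterministic outputs under a fixed seed and a reconciling run report.

#' Pipeline configuration
#'
#' @param genes_dir Directory of per-gene FASTA files (`<gene>.fasta`,
#'   headers `species|gene|isoform`, unaligned CDS).
#' @param metadata Path to gene metadata TSV: gene_id, read_through,
#'   human_lineage_duplicate, mane_isoform_id.
#' @param tree Path to a Newick species tree (or `NULL` for the default
#'   tree at `default_branch_length`).
#' @param foreground Foreground label (`"Hominina"`, `"Hominidae"` or a tip).
#' @param variants,haplotypes,archaic Optional TSV paths for the
#'   verification stage (long variant table; haplotype 0/1 matrix with
#'   `gene:codon` columns; archaic genotypes).
#' @param alpha Gene-level significance threshold per method.
#' @param beb_threshold BEB flagging threshold.
#' @param meme_alpha Site-test flagging threshold.
#' @param null_dist Branch-site null distribution (`"mixture"`/`"chisq1"`).
#' @param min_species Minimum taxa per gene after curation (default 3).
#' @param thresholds [verification_thresholds()].
#' @param default_branch_length Used when `tree` is `NULL`.
#' @param nstarts Optimizer starts per model fit.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(genes_dir, metadata, out_dir, tree = NULL,
                            foreground = "Hominina", variants = NULL,
                            haplotypes = NULL, archaic = NULL,
                            alpha = 0.05, beb_threshold = 0.95,
                            meme_alpha = 0.05, null_dist = "mixture",
                            min_species = 3,
                            thresholds = verification_thresholds(),
                            default_branch_length = 0.05, nstarts = 1,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a small study (input files for the pipeline)
#'
#' Writes per-gene FASTA files of unaligned CDS simulated on the species
#' tree, a metadata table, the tree, and empty-by-default verification
#' tables. One or more genes can be simulated with foreground selection
#' (`omega2 > 1`), the rest under the null.
#'
#' @param out_dir Directory to create.
#' @param tree Foreground-marked `phylo` tree with branch lengths.
#' @param n_genes Number of genes.
#' @param selected Integer indices of genes simulated under positive
#'   selection.
#' @param n_codons Codons per gene.
#' @param mixture_null,mixture_alt Site-class mixtures for null/selected
#'   genes.
#' @param seed Integer seed.
#' @return Invisibly, the paths written (named list).
#' @export
simulate_study <- function(out_dir, tree, n_genes = 5, selected = 1,
                           n_codons = 150,
                           mixture_null = site_class_mixture(
                             0.5, 0.4, omega0 = 0.1, omega2 = 1),
                           mixture_alt = site_class_mixture(
                             0.45, 0.4, omega0 = 0.1, omega2 = 8),
                           seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes_dir <- file.path(out_dir, "genes")
  dir.create(genes_dir, showWarnings = FALSE)
  genes <- sprintf("gene%02d", seq_len(n_genes))
  meta <- data.frame(gene_id = genes, read_through = FALSE,
                     human_lineage_duplicate = FALSE,
                     mane_isoform_id = paste0(genes, "_hs1"))
  truth <- list()
  for (i in seq_len(n_genes)) {
    mix <- if (i %in% selected) mixture_alt else mixture_null
    sim <- simulate_codon_alignment(
      simulation_config(tree, n_codons, mix, seed = seed * 1000L + i))
    truth[[genes[i]]] <- list(selected = i %in% selected,
                              classes = sim$classes)
    seqs <- apply(sim$aln$codons, 1, paste, collapse = "")
    iso <- ifelse(names(seqs) == "Hsap", paste0(genes[i], "_hs1"),
                  paste0(genes[i], "_", names(seqs), "1"))
    writeLines(as.vector(rbind(
      paste0(">", names(seqs), "|", genes[i], "|", iso), unname(seqs))),
      file.path(genes_dir, paste0(genes[i], ".fasta")))
  }
  tree_path <- file.path(out_dir, "tree.nwk")
  ape::write.tree(tree, tree_path)
  meta_path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, selected = selected,
         foreground = attr(tree, "foreground")$label),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  invisible(list(genes_dir = genes_dir, metadata = meta_path,
                 tree = tree_path, truth = truth))
}

.read_gene_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(species = vapply(parts, `[`, "", 1),
             gene = vapply(parts, `[`, "", 2),
             isoform = vapply(parts, `[`, "", 3),
             cds = as.character(x))
}

#' Run the full pipeline
#'
#' Executes curation, alignment, both gene-level tests, site detection on
#' candidate genes, the two-method consensus, and (when variant tables are
#' supplied) PSS verification and archaic dating. A failing gene is logged
#' and skipped; the run continues. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (also written to `out_dir` by
#'   [write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  tree <- if (is.null(config$tree)) {
    build_default_tree(config$default_branch_length)
  } else {
    ape::read.tree(config$tree)
  }
  tree <- mark_foreground(tree, config$foreground)

  meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  filt <- filter_gene_set(meta)
  failures <- list()
  aligned <- list()
  curated_species <- list()

  for (g in filt$retained$gene_id) {
    res <- tryCatch({
      tab <- .read_gene_fasta(file.path(config$genes_dir,
                                        paste0(g, ".fasta")))
      mane <- filt$retained$mane_isoform_id[filt$retained$gene_id == g]
      prots <- vapply(tab$cds, translate_cds, character(1),
                      USE.NAMES = FALSE)
      recs <- lapply(split(seq_len(nrow(tab)), tab$species), function(ii) {
        gene_record(g, tab$species[ii[1]],
                    stats::setNames(prots[ii], tab$isoform[ii]),
                    mane_isoform_id = if (tab$species[ii[1]] == "Hsap")
                      mane else NULL)
      })
      if (!"Hsap" %in% names(recs)) stop("no human sequence for ", g)
      sel <- select_isoform_cluster(recs$Hsap, recs[names(recs) != "Hsap"])
      if (nrow(sel) < config$min_species) {
        stop("fewer than ", config$min_species, " species after curation")
      }
      sub <- prune_tree(tree, sel$species)
      cds <- stats::setNames(
        tab$cds[match(sel$isoform_id, tab$isoform)], sel$species)
      prot <- stats::setNames(
        vapply(cds, translate_cds, character(1)), sel$species)
      msa <- align_proteins(prot, sub)
      aln <- back_translate(msa, cds)
      aln <- apply_mask(aln, auto_mask(aln))
      list(aln = aln, tree = sub)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[g]] <- conditionMessage(res)
    } else {
      aligned[[g]] <- res
      curated_species[[g]] <- res$aln$taxa
    }
  }

  # stage outputs: curated codon alignments and pruned trees, re-loadable
  aln_dir <- file.path(config$out_dir, "alignments")
  dir.create(aln_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(aligned)) {
    write_codon_fasta(aligned[[g]]$aln,
                      file.path(aln_dir, paste0(g, ".codon.fasta")))
    ape::write.tree(aligned[[g]]$tree,
                    file.path(aln_dir, paste0(g, ".nwk")))
  }

  # gene-level tests
  gene_rows <- list()
  fits <- list()
  for (g in names(aligned)) {
    a <- aligned[[g]]
    res <- tryCatch({
      bs <- branch_site_lrt(a$aln, a$tree, gene = g,
                            nstarts = config$nstarts,
                            null_dist = config$null_dist,
                            seed = config$seed)
      ab <- absrel_like_branch_test(a$aln, a$tree, gene = g,
                                    seed = config$seed)
      list(bs = bs, ab = ab)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[g]] <- conditionMessage(res)
      next
    }
    fits[[g]] <- res
    gene_rows[[g]] <- data.frame(
      gene = g, lnL0_bs = res$bs$lnL0, lnL1_bs = res$bs$lnL1,
      p_bs = res$bs$p, lnL0_ab = res$ab$lnL0, lnL1_ab = res$ab$lnL1,
      p_ab = res$ab$p)
  }
  gene_tab <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene = character(0), p_bs = numeric(0), p_ab = numeric(0))
  rownames(gene_tab) <- NULL
  if (nrow(gene_tab)) {
    gene_tab$q_bs <- bh_adjust(gene_tab$p_bs)
    gene_tab$q_ab <- bh_adjust(gene_tab$p_ab)
  }

  # site-level detection on candidate genes (both raw p below alpha)
  cand_genes <- gene_tab$gene[gene_tab$p_bs < config$alpha &
                                gene_tab$p_ab < config$alpha]
  site_rows <- list()
  for (g in cand_genes) {
    a <- aligned[[g]]
    beb <- beb_posteriors(a$aln, a$tree, fits[[g]]$bs$fit1$mix,
                          scale = fits[[g]]$bs$scale,
                          flag_threshold = config$beb_threshold)
    meme <- meme_like_site_test(a$aln, a$tree, alpha = config$meme_alpha)
    hcoord <- human_codon_coordinates(a$aln)
    site_rows[[g]] <- data.frame(
      gene = g, site = beb$site, human_codon = hcoord,
      beb_posterior = beb$beb_posterior, beb_flag = beb$flagged,
      meme_p = meme$p, meme_flag = meme$flagged)
  }
  site_tab <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  if (!is.null(site_tab)) rownames(site_tab) <- NULL

  cons <- consensus(
    data.frame(gene = gene_tab$gene, p = gene_tab$p_bs),
    data.frame(gene = gene_tab$gene, p = gene_tab$p_ab),
    if (!is.null(site_tab)) data.frame(gene = site_tab$gene,
                                       site = site_tab$site,
                                       flagged = site_tab$beb_flag),
    if (!is.null(site_tab)) data.frame(gene = site_tab$gene,
                                       site = site_tab$site,
                                       flagged = site_tab$meme_flag),
    alpha = config$alpha)

  # verification (codon coordinates relative to the human isoform)
  decisions <- NULL
  if (!is.null(cons$sites) && nrow(cons$sites)) {
    cand_sites <- cons$sites
    cand_sites$codon_index <- vapply(seq_len(nrow(cand_sites)), function(i) {
      st <- site_tab[site_tab$gene == cand_sites$gene[i] &
                       site_tab$site == cand_sites$site[i], ]
      as.integer(st$human_codon[1])
    }, integer(1))
    variants <- if (!is.null(config$variants)) {
      utils::read.delim(config$variants, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(0), codon_index = integer(0),
                 snp_id = character(0), pop = character(0),
                 derived_freq = numeric(0))
    }
    ld <- NULL
    if (!is.null(config$haplotypes)) {
      hap <- as.matrix(utils::read.delim(config$haplotypes,
                                         check.names = FALSE))
      ld <- r2_matrix(hap)
    }
    decisions <- classify_pss(
      cand_sites[!is.na(cand_sites$codon_index), , drop = FALSE],
      variants, ld, config$thresholds)
    if (!is.null(config$archaic)) {
      arch <- utils::read.delim(config$archaic, stringsAsFactors = FALSE)
      decisions <- archaic_dating(decisions, arch)
    } else {
      decisions$dating <- ifelse(decisions$call == "TRUE_PSS", "UNDATED",
                                 NA_character_)
    }
  }

  report <- structure(list(
    config = config,
    counts = list(
      genes_in = nrow(meta), genes_excluded = nrow(filt$excluded),
      genes_curated = length(aligned), genes_failed = length(failures),
      genes_tested = nrow(gene_tab),
      candidates_bs = sum(gene_tab$p_bs < config$alpha),
      candidates_ab = sum(gene_tab$p_ab < config$alpha),
      candidates_consensus = nrow(cons$genes),
      sites_consensus = if (is.null(cons$sites)) 0L else nrow(cons$sites)),
    exclusions = filt$log, failures = failures,
    genes = gene_tab, sites = site_tab, consensus = cons,
    decisions = decisions, seed = config$seed),
    class = "run_report")
  write_report(report, config$out_dir)
  report
}

#' Write a run report to disk
#'
#' TSV tables plus a JSON summary and a plain-text log; all codon
#' coordinates are 1-based in the human representative isoform; content is
#' deterministic (no timestamps) so reruns under the same seed are
#' byte-identical.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(out_dir, f)
  }
  paths <- list(genes = wt(report$genes, "genes.tsv"))
  if (!is.null(report$sites)) paths$sites <- wt(report$sites, "sites.tsv")
  if (!is.null(report$decisions)) {
    paths$decisions <- wt(report$decisions, "decisions.tsv")
  }
  if (nrow(report$exclusions)) {
    paths$exclusions <- wt(report$exclusions, "exclusions.tsv")
  }
  summary <- c(report$counts,
               list(seed = report$seed,
                    failures = if (length(report$failures))
                      report$failures else NULL,
                    decisions = if (!is.null(report$decisions))
                      as.list(table(report$decisions$call)) else NULL))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$summary <- file.path(out_dir, "summary.json")
  log_lines <- c(
    sprintf("genes in: %d", report$counts$genes_in),
    sprintf("excluded by flags: %d", report$counts$genes_excluded),
    sprintf("curated: %d (failed: %d)", report$counts$genes_curated,
            report$counts$genes_failed),
    sprintf("candidates (branch-site / absrel-like / consensus): %d / %d / %d",
            report$counts$candidates_bs, report$counts$candidates_ab,
            report$counts$candidates_consensus),
    sprintf("consensus sites: %d", report$counts$sites_consensus))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  paths$log <- file.path(out_dir, "run.log")
  invisible(paths)
}
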