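# Synthetic-data generators: codon alignments evolved under branch-site
# mixtures on the species tree, population variant tables with controlled
# allele frequencies and LD blocks, and archaic / great-ape genotype tables.
# Codon evolution samples from the exact per-branch transition matrices of
# the likelihood engine, so simulator and model are consistent by
# construction.

#' Configuration for codon-alignment simulation
#'
#' @param tree Foreground-marked `phylo` tree with branch lengths.
#' @param n_codons Number of codon sites (>= 1).
#' @param mixture A [site_class_mixture()]; site classes are drawn from it
#'   and each class's branch-specific dN/dS map drives evolution.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` object.
#' @export
simulation_config <- function(tree, n_codons, mixture, seed = 1L) {
  stopifnot(inherits(mixture, "site_class_mixture"),
            n_codons >= 1, is.numeric(seed))
  w <- mixture_weights(mixture)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) stop("invalid mixture")
  if (is.null(attr(tree, "foreground"))) {
    stop("tree must carry a foreground mark")
  }
  structure(list(tree = tree, n_codons = as.integer(n_codons),
                 mixture = mixture, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a codon alignment under the branch-site mixture
#'
#' Each site draws a latent class from the mixture; the ancestral codon is
#' drawn from `pi`; codons then evolve along each branch by sampling from the
#' exact transition matrix `P(t)` with the class's branch-specific dN/dS
#' (foreground vs background). Returns the tip alignment plus the latent
#' class labels.
#'
#' @param config A [simulation_config()].
#' @return List with `aln` (a `codon_aln`) and `classes` (integer 0, 1, 2, 3
#'   for classes 0/1/2a/2b per site).
#' @export
simulate_codon_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mix <- config$mixture
  tree <- config$tree
  set.seed(config$seed)
  n <- config$n_codons
  w <- mixture_weights(mix)
  classes <- sample.int(4, n, replace = TRUE, prob = w) - 1L
  maps <- mixture_omega_maps(mix)
  fg_child <- tree$edge[foreground_edge(tree), 2]

  # preorder traversal (root to tips)
  tr <- stats::reorder(tree, "postorder")
  edges <- nrow(tr$edge):1
  n_tip <- ape::Ntip(tr)
  root <- tr$edge[nrow(tr$edge), 1]

  omegas <- sort(unique(c(maps$background, maps$foreground)))
  eds <- lapply(omegas, function(om) {
    eigen_decompose_Q(build_rate_matrix(codon_params(mix$kappa, om, mix$pi)),
                      mix$pi)
  })
  names(eds) <- as.character(omegas)
  P_of <- function(om, t) {
    ed <- eds[[as.character(om)]]
    P <- ed$A %*% (exp(ed$lambda * t * relative_rate(mix$kappa, om, mix$pi))
                   * ed$B)
    P[P < 0] <- 0
    P / rowSums(P)
  }

  n_node <- max(tr$edge)
  states <- matrix(NA_integer_, n_node, n)
  states[root, ] <- sample.int(61, n, replace = TRUE, prob = mix$pi)
  for (e in edges) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    fg <- child == fg_child
    for (cl in 0:3) {
      idx <- which(classes == cl)
      if (!length(idx)) next
      om <- if (fg) maps$foreground[cl + 1] else maps$background[cl + 1]
      P <- P_of(om, tr$edge.length[e])
      ps <- states[parent, idx]
      # vectorised categorical draw per site from the parent-state row
      u <- stats::runif(length(idx))
      cp <- t(apply(P[ps, , drop = FALSE], 1, cumsum))
      states[child, idx] <- max.col(cp >= u, ties.method = "first")
    }
  }
  codons <- matrix(.codon_tables$codons[states[seq_len(n_tip), ]],
                   nrow = n_tip, dimnames = list(tr$tip.label, NULL))
  list(aln = codon_alignment(codons), classes = classes)
}

#' Configuration for population-variant simulation
#'
#' @param sites Integer vector of candidate codon positions.
#' @param freq Named list (per population) of numeric vectors (per site) of
#'   target derived-allele frequencies in `[0,1]`.
#' @param panel_sizes Named integer vector of haplotype counts per population.
#' @param ld_blocks Optional list of blocks, each `list(sites=, r2=)`; a site
#'   may belong to at most one block.
#' @param seed Integer seed.
#' @return A `variant_sim_config` object.
#' @export
variant_sim_config <- function(sites, freq, panel_sizes, ld_blocks = list(),
                               seed = 1L) {
  stopifnot(length(sites) >= 1, all(panel_sizes > 0),
            all(names(freq) %in% names(panel_sizes) |
                  names(panel_sizes) %in% names(freq)))
  for (p in names(freq)) {
    f <- freq[[p]]
    if (length(f) != length(sites) || any(f < 0 | f > 1)) {
      stop("frequencies must be in [0,1], one per site, for population ", p)
    }
  }
  in_block <- unlist(lapply(ld_blocks, `[[`, "sites"))
  if (anyDuplicated(in_block)) stop("each site may be in at most one LD block")
  if (!all(in_block %in% sites)) stop("LD block sites must be among sites")
  structure(list(sites = as.integer(sites), freq = freq,
                 panel_sizes = panel_sizes, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "variant_sim_config")
}

# Sample nhap haplotypes over block sites with target pairwise r2, using a
# two-background mixture: a fraction c = sqrt(r2 / r2max) of haplotypes is
# drawn comonotonically (shared uniform), the rest independently. For equal
# site frequencies r2max = 1 and the realized r2 targets c^2 = r2 exactly.
.sim_block_haplotypes <- function(nhap, freqs, r2) {
  k <- length(freqs)
  if (k == 1) {
    return(matrix(stats::rbinom(nhap, 1, freqs), ncol = 1))
  }
  r2max <- 1
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pa <- freqs[i]; pb <- freqs[j]
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
    D <- min(pa, pb) - pa * pb
    r2max <- min(r2max, D^2 / (pa * (1 - pa) * pb * (1 - pb)))
  }
  if (r2 > r2max + 1e-9) {
    stop(sprintf("target r2 %.2f unattainable for these frequencies (max %.3f)",
                 r2, r2max))
  }
  cc <- sqrt(r2 / r2max)
  coupled <- stats::runif(nhap) < cc
  u <- stats::runif(nhap)
  H <- matrix(0L, nhap, k)
  for (s in seq_len(k)) {
    ind <- stats::rbinom(nhap, 1, freqs[s])
    H[, s] <- ifelse(coupled, as.integer(u < freqs[s]), ind)
  }
  H
}

#' Simulate a population variant table with LD structure
#'
#' Draws phased haplotype panels per population; sites inside an LD block
#' share haplotype background so that pairwise r-squared lands near the
#' block's target, off-block sites are independent. Realized derived-allele
#' frequencies are the haplotype-panel means (binomial sampling around the
#' targets). A site with target frequency 0 or 1 is monomorphic and gets no
#' polymorphism record.
#'
#' @param config A [variant_sim_config()].
#' @return List with `table` (data.frame: site, pop, target_freq,
#'   derived_freq, n_hap) and `haplotypes` (list per population of 0/1
#'   matrices, columns named by site).
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "variant_sim_config"))
  set.seed(config$seed)
  sites <- config$sites
  blocks <- config$ld_blocks
  blocked <- unlist(lapply(blocks, `[[`, "sites"))
  singles <- setdiff(sites, blocked)
  haps <- list(); rows <- list()
  for (p in names(config$panel_sizes)) {
    nhap <- config$panel_sizes[[p]]
    f <- stats::setNames(config$freq[[p]], sites)
    H <- matrix(0L, nhap, length(sites), dimnames = list(NULL, sites))
    for (b in blocks) {
      bs <- as.character(b$sites)
      H[, bs] <- .sim_block_haplotypes(nhap, f[bs], b$r2)
    }
    for (s in as.character(singles)) {
      H[, s] <- stats::rbinom(nhap, 1, f[s])
    }
    haps[[p]] <- H
    rows[[p]] <- data.frame(site = sites, pop = p,
                            target_freq = as.numeric(f),
                            derived_freq = as.numeric(colMeans(H)),
                            n_hap = nhap)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[!(tab$target_freq %in% c(0, 1)) |
               !(tab$derived_freq %in% c(0, 1)) , , drop = FALSE]
  list(table = tab, haplotypes = haps)
}

#' Simulate archaic-human and great-ape panel genotypes
#'
#' Archaic genotypes are generated for the named high-coverage individuals
#' (Vindija and Altai Neanderthals, Denisova); the great-ape panel defaults
#' to 111 chimpanzees, 17 bonobos, 42 gorillas and 10 orangutans (180
#' individuals).
#'
#' @param sites Integer vector of codon positions (non-empty).
#' @param archaic_state Either a single state recycled to all sites or a
#'   vector per site, from `c("derived", "ancestral", "heterozygous",
#'   "missing")`.
#' @param ape_variation Per site (or recycled): `"none"` (all individuals
#'   ancestral), `"variable"` (polymorphic within at least one taxon) or
#'   `"missing"`.
#' @param panel_sizes Named vector of ape panel sizes.
#' @param missing_rate Probability of replacing an archaic genotype with
#'   `"missing"`.
#' @param seed Integer seed.
#' @return List with `archaic` (data.frame site x individual states) and
#'   `ape` (data.frame: site, taxon columns of genotype strings).
#' @export
simulate_archaic_and_ape_genotypes <- function(
    sites, archaic_state = "derived", ape_variation = "none",
    panel_sizes = c(chimpanzee = 111, bonobo = 17, gorilla = 42,
                    orangutan = 10),
    missing_rate = 0, seed = 1L) {
  if (!length(sites)) stop("sites must be non-empty")
  set.seed(as.integer(seed))
  ns <- length(sites)
  archaic_state <- rep(archaic_state, length.out = ns)
  ape_variation <- rep(ape_variation, length.out = ns)
  indivs <- c("Vindija", "Altai", "Denisova")
  arch <- matrix(rep(archaic_state, times = length(indivs)), nrow = ns,
                 dimnames = list(NULL, indivs))
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(ns * length(indivs)) < missing_rate,
                   nrow = ns)
    arch[drop] <- "missing"
  }
  archaic <- data.frame(site = sites, arch, check.names = FALSE)

  cols <- list(site = sites)
  for (taxon in names(panel_sizes)) {
    m <- matrix("A", ns, panel_sizes[[taxon]])
    for (i in seq_len(ns)) {
      if (ape_variation[i] == "variable") {
        k <- max(1, stats::rbinom(1, panel_sizes[[taxon]], 0.2))
        m[i, sample.int(panel_sizes[[taxon]], k)] <- "D"
      } else if (ape_variation[i] == "missing") {
        m[i, ] <- NA_character_
      }
    }
    colnames(m) <- paste0(taxon, "_", seq_len(panel_sizes[[taxon]]))
    cols[[taxon]] <- m
  }
  ape_tab <- do.call(data.frame,
                     c(cols, list(check.names = FALSE,
                                  stringsAsFactors = FALSE)))
  list(archaic = archaic, ape = ape_tab)
}
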