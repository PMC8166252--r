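# Verification of candidate positively selected sites (PSS) against modern
# human polymorphism, linkage disequilibrium, archaic genomes and great-ape
# panels. Every candidate receives exactly one call:
#   TRUE_PSS       - fixed (or nearly fixed) derived state, no haplo-block
#   MINOR_ALLELE   - the "selected" allele is a minor allele of a standing
#                    polymorphism (reference-genome artifact)
#   FALSE_POSITIVE - ancestral standing variation / shared haplo-block
# plus UNRESOLVED when a SNP is recorded but frequency data are absent.

#' Thresholds for PSS verification
#'
#' @param rare_backvariant_max Maximum per-population ancestral-allele
#'   frequency still treated as a rare independent back-variant (default
#'   0.10).
#' @param minor_allele_min_ancestral Minimum ancestral-allele frequency at
#'   which the derived allele counts as the minor allele (default 0.50).
#' @param common_ancestral_min Ancestral frequency in at least one population
#'   above which the site is standing variation (default 0.50).
#' @param ld_r2_min Minimum r-squared for haplo-block membership (default
#'   0.5).
#' @return A `verification_thresholds` object.
#' @export
verification_thresholds <- function(rare_backvariant_max = 0.10,
                                    minor_allele_min_ancestral = 0.50,
                                    common_ancestral_min = 0.50,
                                    ld_r2_min = 0.5) {
  v <- list(rare_backvariant_max = rare_backvariant_max,
            minor_allele_min_ancestral = minor_allele_min_ancestral,
            common_ancestral_min = common_ancestral_min,
            ld_r2_min = ld_r2_min)
  stopifnot(all(unlist(v) >= 0), all(unlist(v) <= 1))
  structure(v, class = "verification_thresholds")
}

#' Linkage disequilibrium r-squared between two sites
#'
#' `r2 = D^2 / (pA pa pB pb)` with `D = f(AB) - pA pB`, computed from phased
#' 0/1 haplotype columns. Returns 0 (with a `"note"` attribute) when either
#' site is monomorphic.
#'
#' @param a,b Equal-length 0/1 haplotype vectors.
#' @return r-squared in `[0,1]`.
#' @export
compute_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("haplotype columns differ in length")
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    out <- 0
    attr(out, "note") <- "monomorphic site"
    return(out)
  }
  D <- mean(a == 1 & b == 1) - pa * pb
  unname(D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Pairwise r-squared matrix over haplotype columns
#'
#' @param hap 0/1 matrix, one column per site (column names become the
#'   matrix dimnames).
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
r2_matrix <- function(hap) {
  k <- ncol(hap)
  m <- diag(1, k)
  dimnames(m) <- list(colnames(hap), colnames(hap))
  if (k < 2) return(m)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- as.numeric(compute_r2(hap[, i], hap[, j]))
  }
  m
}

.site_key <- function(gene, codon) paste0(gene, ":", codon)

#' Classify candidate positively selected sites against population variation
#'
#' Rules, applied in order per candidate site:
#' 1. no recorded modern-human polymorphism at the codon: `TRUE_PSS`;
#' 2. ancestral allele present but rare in every population (maximum
#'    ancestral frequency at or below `rare_backvariant_max`) and the site is in no
#'    haplo-block: `TRUE_PSS` ("rare independent back-variant");
#' 3. the derived allele is the minor allele (ancestral frequency at or above
#'    `minor_allele_min_ancestral`) with no haplo-block evidence:
#'    `MINOR_ALLELE`;
#' 4. ancestral allele common in at least one population and/or the site
#'    belongs to a haplo-block of candidates (any r-squared at or above
#'    `ld_r2_min`): `FALSE_POSITIVE`.
#' A candidate whose SNP id is recorded without any frequency data is
#' reported `UNRESOLVED`, never guessed.
#'
#' @param candidates data.frame with columns `gene`, `codon_index` (the
#'   consensus candidate sites).
#' @param variants Long data.frame of modern-human variation with columns
#'   `gene`, `codon_index`, `snp_id`, `pop`, `derived_freq` (`NA` frequency
#'   allowed). Sites absent from the table are unpolymorphic.
#' @param ld Optional symmetric r-squared matrix whose dimnames are
#'   `"gene:codon"` keys; may include non-candidate partner sites.
#' @param thresholds A [verification_thresholds()].
#' @return data.frame: gene, codon_index, call, reason, max_ancestral_freq,
#'   max_r2.
#' @export
classify_pss <- function(candidates, variants,
                         ld = NULL,
                         thresholds = verification_thresholds()) {
  th <- thresholds
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene[i]; cod <- candidates$codon_index[i]
    key <- .site_key(g, cod)
    v <- variants[variants$gene == g & variants$codon_index == cod, ,
                  drop = FALSE]
    # LD only among sites of the same gene (blocks are intragenic)
    max_r2 <- 0
    if (!is.null(ld) && key %in% rownames(ld)) {
      same_gene <- grepl(paste0("^", g, ":"), colnames(ld))
      others <- setdiff(colnames(ld)[same_gene], key)
      if (length(others)) max_r2 <- max(ld[key, others])
    }
    in_block <- max_r2 >= th$ld_r2_min
    row <- function(call, reason, maf = NA_real_) {
      data.frame(gene = g, codon_index = cod, call = call, reason = reason,
                 max_ancestral_freq = maf, max_r2 = max_r2)
    }
    if (nrow(v) == 0L) {
      return(row("TRUE_PSS", "no_modern_polymorphism"))
    }
    if (all(is.na(v$derived_freq))) {
      return(row("UNRESOLVED", "snp_recorded_without_frequency"))
    }
    anc <- 1 - v$derived_freq[!is.na(v$derived_freq)]
    max_anc <- max(anc)
    if (max_anc <= th$rare_backvariant_max && !in_block) {
      return(row("TRUE_PSS", "rare_independent_backvariant", max_anc))
    }
    if (max_anc >= th$minor_allele_min_ancestral && !in_block) {
      return(row("MINOR_ALLELE", "reference_allele_artifact", max_anc))
    }
    if (max_anc >= th$common_ancestral_min || in_block) {
      return(row("FALSE_POSITIVE",
                 if (in_block) "ancestral_standing_variation_haploblock"
                 else "ancestral_standing_variation", max_anc))
    }
    # intermediate frequency, no block: treat as unfixed standing variation
    row("MINOR_ALLELE", "unfixed_intermediate_variant", max_anc)
  })
  do.call(rbind, out)
}

#' Date true PSS against archaic-human genotypes
#'
#' A site whose every non-missing archaic genotype (Vindija, Altai, Denisova)
#' is the derived state predates the split from archaic humans
#' (`PRE_ARCHAIC_SPLIT`); any ancestral or heterozygous archaic genotype
#' flags a post-split candidate; all-missing data leave the site `UNDATED`.
#' Only `TRUE_PSS` calls receive a dating label.
#'
#' @param decisions Output of [classify_pss()].
#' @param archaic data.frame with columns `gene`, `codon_index` and one
#'   column per archaic individual with states in
#'   `c("derived","ancestral","heterozygous","missing")`.
#' @return `decisions` with a `dating` column added.
#' @export
archaic_dating <- function(decisions, archaic) {
  if (nrow(decisions) == 0L) {
    decisions$dating <- character(0)
    return(decisions)
  }
  indiv_cols <- setdiff(colnames(archaic), c("gene", "codon_index"))
  decisions$dating <- NA_character_
  for (i in seq_len(nrow(decisions))) {
    if (decisions$call[i] != "TRUE_PSS") next
    a <- archaic[archaic$gene == decisions$gene[i] &
                   archaic$codon_index == decisions$codon_index[i],
                 indiv_cols, drop = FALSE]
    states <- unlist(a, use.names = FALSE)
    states <- states[!is.na(states) & states != "missing"]
    decisions$dating[i] <- if (!length(states)) {
      "UNDATED"
    } else if (all(states == "derived")) {
      "PRE_ARCHAIC_SPLIT"
    } else {
      "POST_ARCHAIC_SPLIT"
    }
  }
  decisions
}

#' Summarise great-ape panel variation at a candidate site
#'
#' @param gene,codon_index Site identifier.
#' @param ape_tab data.frame from [simulate_archaic_and_ape_genotypes()]'s
#'   `ape` element (a `site` column plus genotype columns named
#'   `taxon_<i>`), or any table with `gene`/`codon_index` columns.
#' @return Named character vector per taxon:
#'   `"monomorphic-ancestral"`, `"polymorphic"`, `"monomorphic-other"` or
#'   `"missing"`, with attribute `"note"` set to
#'   `"no incomplete lineage sorting signal"` when every covered taxon is
#'   monomorphic-ancestral.
#' @export
ape_panel_summary <- function(gene = NULL, codon_index, ape_tab) {
  sel <- if ("gene" %in% colnames(ape_tab) && !is.null(gene)) {
    ape_tab$gene == gene & ape_tab$codon_index == codon_index
  } else {
    ape_tab$site == codon_index
  }
  taxa <- unique(sub("_[0-9]+$", "",
                     grep("_[0-9]+$", colnames(ape_tab), value = TRUE)))
  if (!any(sel)) {
    out <- stats::setNames(rep("missing", length(taxa)), taxa)
    return(out)
  }
  rowx <- ape_tab[which(sel)[1], , drop = FALSE]
  out <- vapply(taxa, function(tx) {
    g <- unlist(rowx[grep(paste0("^", tx, "_[0-9]+$"), colnames(rowx))])
    g <- g[!is.na(g)]
    if (!length(g)) return("missing")
    al <- unique(g)
    if (length(al) > 1) "polymorphic"
    else if (al == "A") "monomorphic-ancestral"
    else "monomorphic-other"
  }, character(1))
  covered <- out[out != "missing"]
  if (length(covered) && all(covered == "monomorphic-ancestral")) {
    attr(out, "note") <- "no incomplete lineage sorting signal"
  }
  out
}
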