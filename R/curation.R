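# Gene- and sequence-level curation: exclusion filters, representative
# isoform selection, identity-based ortholog clustering.

#' Gene record
#'
#' One gene in one species, possibly with several isoform CDS.
#'
#' @param gene_id Gene identifier.
#' @param species Taxon label (should match a tree tip).
#' @param sequences Named character vector of CDS (names = isoform ids).
#' @param read_through,human_lineage_duplicate Exclusion flags.
#' @param mane_isoform_id Representative isoform id (human records only).
#' @return A `gene_record`.
#' @export
gene_record <- function(gene_id, species, sequences,
                        read_through = FALSE,
                        human_lineage_duplicate = FALSE,
                        mane_isoform_id = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  structure(list(gene_id = gene_id, species = species,
                 sequences = sequences, read_through = read_through,
                 human_lineage_duplicate = human_lineage_duplicate,
                 mane_isoform_id = mane_isoform_id),
            class = "gene_record")
}

#' Filter a gene set on exclusion flags
#'
#' Drops genes flagged as read-through transcripts or as recent human-lineage
#' duplicates; never adds or modifies records.
#'
#' @param records List of [gene_record()]s (or a data.frame with `gene_id`,
#'   `read_through`, `human_lineage_duplicate` columns).
#' @return List with `retained` and `excluded` (the latter carrying a
#'   `reason` attribute per record) -- retained plus excluded equals input.
#' @export
filter_gene_set <- function(records) {
  if (is.data.frame(records)) {
    drop <- records$read_through | records$human_lineage_duplicate
    reason <- ifelse(records$read_through, "read_through",
                     ifelse(records$human_lineage_duplicate,
                            "human_lineage_duplicate", ""))
    log <- data.frame(gene_id = records$gene_id[drop],
                      reason = reason[drop])
    return(list(retained = records[!drop, , drop = FALSE],
                excluded = records[drop, , drop = FALSE], log = log))
  }
  drop <- vapply(records, function(r)
    isTRUE(r$read_through) || isTRUE(r$human_lineage_duplicate), logical(1))
  reason <- vapply(records, function(r) {
    if (isTRUE(r$read_through)) "read_through"
    else if (isTRUE(r$human_lineage_duplicate)) "human_lineage_duplicate"
    else ""
  }, character(1))
  list(retained = records[!drop], excluded = records[drop],
       log = data.frame(
         gene_id = vapply(records[drop], `[[`, character(1), "gene_id"),
         reason = reason[drop]))
}

#' Pairwise protein identity after global affine-gap alignment
#'
#' Aligns globally (match +1, mismatch 0, affine gap penalties) via
#' `Biostrings::pairwiseAlignment`, then returns identical positions divided
#' by aligned columns, excluding dual-gap columns (which a global pairwise
#' alignment does not produce). Symmetric, in `[0,1]`.
#'
#' @param a,b Non-empty protein sequences (character scalars).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Identity fraction.
#' @export
pairwise_identity <- function(a, b, gap_open = 2, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  alpha <- unique(strsplit(paste0(a, b), "")[[1]])
  submat <- diag(1, length(alpha))
  dimnames(submat) <- list(alpha, alpha)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cols <- !(pa == "-" & pb == "-")
  sum(pa[cols] == pb[cols] & pa[cols] != "-") / sum(cols)
}

#' Clustering configuration
#' @param min_identity Minimum within-cluster identity to the centroid
#'   (default 0.80).
#' @return A `cluster_config`.
#' @export
cluster_config <- function(min_identity = 0.80) {
  stopifnot(min_identity > 0, min_identity <= 1)
  structure(list(min_identity = min_identity), class = "cluster_config")
}

#' Select the human-containing isoform cluster
#'
#' Fixes the human representative isoform (the MANE transcript) as the first
#' centroid, then clusters all non-human isoforms by deterministic greedy
#' centroid clustering (longest sequence first): a sequence joins the first
#' centroid it matches at `min_identity` protein identity, otherwise founds
#' a new cluster. From the human-containing cluster one sequence per species
#' is returned; ties are broken by identity to the human sequence, then
#' length, then lexicographic isoform id. Species with no isoform in the
#' human cluster are absent from the output.
#'
#' @param human A human [gene_record()] carrying `mane_isoform_id` (protein
#'   sequences).
#' @param orthologs List of non-human [gene_record()]s (protein sequences).
#' @param cfg A [cluster_config()].
#' @return data.frame: species, isoform_id, sequence, identity_to_human.
#' @export
select_isoform_cluster <- function(human, orthologs,
                                   cfg = cluster_config()) {
  if (is.null(human$mane_isoform_id) ||
      !human$mane_isoform_id %in% names(human$sequences)) {
    stop("human record must carry a MANE isoform id")
  }
  hseq <- human$sequences[[human$mane_isoform_id]]
  pool <- do.call(rbind, lapply(orthologs, function(r) {
    data.frame(species = r$species, isoform_id = names(r$sequences),
               sequence = unname(r$sequences))
  }))
  if (is.null(pool) || nrow(pool) == 0L) {
    return(data.frame(species = human$species,
                      isoform_id = human$mane_isoform_id,
                      sequence = hseq, identity_to_human = 1))
  }
  pool <- pool[order(-nchar(pool$sequence), pool$isoform_id), , drop = FALSE]
  centroids <- list(list(seq = hseq, members = integer(0)))
  assign_to <- integer(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(centroids[[ci]]$seq, pool$sequence[i]) >=
          cfg$min_identity) {
        centroids[[ci]]$members <- c(centroids[[ci]]$members, i)
        assign_to[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <-
        list(seq = pool$sequence[i], members = i)
      assign_to[i] <- length(centroids)
    }
  }
  inhuman <- pool[assign_to == 1L, , drop = FALSE]
  out <- data.frame(species = human$species,
                    isoform_id = human$mane_isoform_id,
                    sequence = hseq, identity_to_human = 1)
  if (nrow(inhuman)) {
    inhuman$identity_to_human <- vapply(inhuman$sequence, function(s)
      pairwise_identity(hseq, s), numeric(1), USE.NAMES = FALSE)
    for (sp in unique(inhuman$species)) {
      cand <- inhuman[inhuman$species == sp, , drop = FALSE]
      cand <- cand[order(-cand$identity_to_human, -nchar(cand$sequence),
                         cand$isoform_id), , drop = FALSE]
      out <- rbind(out, cand[1, c("species", "isoform_id", "sequence",
                                  "identity_to_human")])
    }
  }
  rownames(out) <- NULL
  out
}
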