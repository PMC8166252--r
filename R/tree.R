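#' @importFrom ape read.tree write.tree keep.tip getMRCA Ntip
NULL

# Great-ape leaves of the default tree; the great-ape stem ("Hominidae")
# foreground is the branch subtending their most recent common ancestor.
.great_apes <- c("Ppyg", "Ggor", "Ptro", "Ppan", "Hsap")

.default_topology <- paste0(
  "((Ogar,(Mmur,(Pcoq,Psim))),",
  "(Tsyr,((Anan,(Cjac,(Ccap,Sbbo))),",
  "(((((Rbie,Rrox),(Ptep,Capa)),",
  "(Csab,(((Mmul,Mfas),Mnem),((Panu,Tgel),(Mleu,Caty))))),",
  "(Nleu,(Ppyg,(Ggor,((Ptro,Ppan),Hsap))))))",
  ")));"
)

#' Default primate species tree
#'
#' A fixed 27-leaf primate topology spanning strepsirrhines, tarsier, New
#' World monkeys, Old World monkeys and hominoids, with leaf labels as
#' four-letter species abbreviations (human is `"Hsap"`). Branch lengths are
#' not part of the topology definition: every edge gets a uniform length
#' `branch_length_scale` (a full Newick with lengths can be supplied anywhere
#' a tree is accepted). The foreground branch for selection tests can be
#' marked as the human terminal branch (`"Hominina"`) or the great-ape stem
#' (`"Hominidae"`).
#'
#' @param branch_length_scale Positive uniform branch length.
#' @param foreground Optional foreground label, `"Hominina"` or `"Hominidae"`.
#' @return An `ape::phylo` tree, with a `"foreground"` attribute when marked.
#' @export
build_default_tree <- function(branch_length_scale = 0.05, foreground = NULL) {
  stopifnot(is.numeric(branch_length_scale), branch_length_scale > 0)
  tr <- ape::read.tree(text = .default_topology)
  tr$edge.length <- rep(branch_length_scale, nrow(tr$edge))
  if (!is.null(foreground)) tr <- mark_foreground(tr, foreground)
  tr
}

#' Mark the foreground branch of a tree
#'
#' The mark is stored symbolically (as the foreground label plus the clade's
#' defining tip set) so it survives [prune_tree()]; the concrete edge is
#' resolved on demand by [foreground_edge()].
#'
#' @param tree `phylo` tree.
#' @param foreground `"Hominina"` (terminal branch to `Hsap`), `"Hominidae"`
#'   (stem of the great-ape clade), or the name of any single tip in the tree
#'   (that tip's terminal branch).
#' @return The tree with a `"foreground"` attribute.
#' @export
mark_foreground <- function(tree, foreground) {
  tips <- if (identical(foreground, "Hominina")) {
    "Hsap"
  } else if (identical(foreground, "Hominidae")) {
    .great_apes
  } else if (foreground %in% tree$tip.label) {
    foreground
  } else {
    stop("unknown foreground label: ", foreground)
  }
  if (!any(tips %in% tree$tip.label)) {
    stop("foreground clade has no representative in the tree")
  }
  attr(tree, "foreground") <- list(label = foreground, tips = tips)
  tree
}

#' Resolve the marked foreground branch to an edge index
#'
#' @param tree A tree marked with [mark_foreground()].
#' @return Row index into `tree$edge` of the foreground branch.
#' @export
foreground_edge <- function(tree) {
  fg <- attr(tree, "foreground")
  if (is.null(fg)) stop("tree has no foreground mark")
  present <- intersect(fg$tips, tree$tip.label)
  if (length(present) == 0L) {
    stop("foreground branch no longer definable: no marked taxa remain")
  }
  node <- if (length(present) == 1L) {
    match(present, tree$tip.label)
  } else {
    ape::getMRCA(tree, present)
  }
  e <- which(tree$edge[, 2] == node)
  if (length(e) != 1L) stop("foreground branch is the root; cannot mark")
  e
}

#' Prune a species tree to the taxa present in a gene
#'
#' Thin wrapper over `ape::keep.tip` (the `drop.tip` machinery): leaves not in
#' `present_taxa` are removed, unary internal nodes are collapsed with their
#' branch lengths summed, and any foreground marking is re-attached to the
#' surviving clade stem.
#'
#' @param tree `phylo` tree, possibly foreground-marked.
#' @param present_taxa Character vector of tip labels to keep (>= 2).
#' @return Pruned `phylo` tree.
#' @export
prune_tree <- function(tree, present_taxa) {
  if (!all(present_taxa %in% tree$tip.label)) {
    stop("present_taxa must be a subset of the tree's tips")
  }
  if (length(present_taxa) < 2L) stop("need at least 2 taxa after pruning")
  fg <- attr(tree, "foreground")
  out <- ape::keep.tip(tree, present_taxa)
  if (!is.null(fg)) {
    if (!any(fg$tips %in% out$tip.label)) {
      stop("foreground branch no longer definable after pruning")
    }
    attr(out, "foreground") <- fg
    foreground_edge(out) # validates resolvability (errors at root)
  }
  out
}

# postorder edge matrix plus convenience lookups used by the likelihood core
tree_postorder <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(tree = tr, edge = tr$edge, lengths = tr$edge.length,
       n_tip = ape::Ntip(tr), labels = tr$tip.label)
}
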