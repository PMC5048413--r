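#' Branch identifiers of a phylogeny
#'
#' Every branch is named after the node it leads to: the tip label for
#' terminal branches, the node label (when present) or `"node<k>"` for
#' internal branches. These ids key `omega_map`s, foreground designations
#' and all per-branch output tables.
#'
#' @param tree An [ape::phylo] object.
#' @return Character vector, one id per row of `tree$edge`.
#' @export
branch_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  ids <- character(length(child))
  tipedge <- child <= ntip
  ids[tipedge] <- tree$tip.label[child[tipedge]]
  inner <- child[!tipedge]
  lab <- rep("", length(inner))
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[inner - ntip]
    lab[is.na(lab)] <- ""
  }
  ids[!tipedge] <- ifelse(nzchar(lab), lab, paste0("node", inner))
  ids
}

#' Extract a CODEML-style foreground mark from branch labels
#'
#' Tip or node labels ending in `#1` designate foreground branches (the
#' branch leading to the marked node). The mark is stripped from the
#' returned tree.
#'
#' @param tree An [ape::phylo] object, possibly with `#1` marks.
#' @return List with elements `tree` (marks stripped) and `foreground`
#'   (character vector of branch ids, possibly empty).
#' @export
parse_foreground <- function(tree) {
  strip <- function(x) sub("\\s*#1$", "", x)
  marked_tip <- grepl("#1$", tree$tip.label)
  marked_node <- if (!is.null(tree$node.label)) grepl("#1$", tree$node.label) else logical(0)
  tree$tip.label <- strip(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- strip(tree$node.label)
  ids <- branch_ids(tree)
  ntip <- length(tree$tip.label)
  fg_nodes <- c(which(marked_tip), ntip + which(marked_node))
  fg <- ids[match(fg_nodes, tree$edge[, 2])]
  list(tree = tree, foreground = fg[!is.na(fg)])
}

#' Example five-taxon phylogeny
#'
#' A tree with the shape typical of two-lineage high/low-altitude contrasts:
#' two congeneric pairs (a toad pair and a frog pair) plus a distant
#' outgroup. Branch lengths are in expected substitutions per codon and are
#' plausible for deeply diverged amphibian transcriptomes.
#'
#' @return An [ape::phylo] object with tips `bufo_high`, `bufo_low`,
#'   `rana_high`, `rana_low`, `xenopus`.
#' @export
example_phylogeny <- function() {
  ape::read.tree(text = paste0(
    "((bufo_high:0.15,bufo_low:0.15):0.35,",
    "(rana_high:0.15,rana_low:0.15):0.35,xenopus:0.9);"))
}

# Postorder tree data shared by the simulator and the likelihood kernel.
prepare_tree <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  tr <- ape::reorder.phylo(tree, "postorder")
  if (!is.null(taxa)) {
    if (!setequal(tr$tip.label, taxa))
      stop("alignment taxa and tree tips do not match")
  }
  list(tree = tr, edge = tr$edge, edge_length = tr$edge.length,
       ids = branch_ids(tr), ntip = length(tr$tip.label))
}

# Resolve a per-branch omega map (named vector, or scalar recycled) into a
# vector parallel to the postorder edges.
resolve_omega_map <- function(omega_map, ids) {
  if (length(omega_map) == 1L && is.null(names(omega_map)))
    return(rep(unname(omega_map), length(ids)))
  missing <- setdiff(ids, names(omega_map))
  if (length(missing))
    stop("omega_map missing entries for branch(es): ",
         paste(missing, collapse = ", "))
  unname(omega_map[ids])
}
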