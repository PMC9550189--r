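# Dated phylogeny handling. Trees are ape "phylo" objects with unique tip
# and internal-node labels and strictly positive branch lengths in My; the
# helpers below add label-based lookups used across the pipeline.

#' Validate a dated phylogeny
#'
#' Checks that a tree is rooted and binary, that every branch length is
#' present and strictly positive, and that tip and internal-node labels are
#' unique. Internal nodes without labels are given stable generated labels
#' (`node<k>`).
#'
#' @param tree an `ape::phylo` object.
#' @return the (possibly relabelled) tree, invisibly usable downstream.
#' @export
dated_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("need an ape 'phylo' tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("every branch needs a length (My)")
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be > 0")
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    gen <- paste0("node", seq_len(tree$Nnode) + ape::Ntip(tree))
    if (is.null(tree$node.label)) tree$node.label <- gen
    else tree$node.label[tree$node.label == ""] <- gen[tree$node.label == ""]
  }
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs)) {
    stop("duplicate node label(s): ", paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  tree
}

#' Read a dated tree from a newick file
#'
#' @param path newick file with branch lengths (My) and, ideally, internal
#'   node labels.
#' @return a validated `phylo` tree (see [dated_tree()]).
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  dated_tree(tr)
}

# node number for a label (tip or internal)
node_number <- function(tree, label) {
  labs <- c(tree$tip.label, tree$node.label)
  k <- match(label, labs)
  if (is.na(k)) stop("unknown node label: ", label)
  k
}

node_label <- function(tree, number) c(tree$tip.label, tree$node.label)[number]

# tip labels descending from an internal node (or the tip itself)
descendant_tips <- function(tree, label) {
  k <- node_number(tree, label)
  ntip <- ape::Ntip(tree)
  if (k <= ntip) return(tree$tip.label[k])
  desc <- integer(0)
  stack <- k
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    desc <- c(desc, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[sort(desc)]
}

# labels of the two children of an internal node
child_labels <- function(tree, label) {
  k <- node_number(tree, label)
  node_label(tree, tree$edge[tree$edge[, 1L] == k, 2L])
}

# parent label, or NA for the root
parent_label <- function(tree, label) {
  k <- node_number(tree, label)
  e <- tree$edge[tree$edge[, 2L] == k, 1L]
  if (!length(e)) return(NA_character_)
  node_label(tree, e)
}

root_label <- function(tree) node_label(tree, ape::Ntip(tree) + 1L)

# branch table: one row per edge, child label, parent label, length in My
branch_table <- function(tree) {
  data.frame(branch = node_label(tree, tree$edge[, 2L]),
             parent = node_label(tree, tree$edge[, 1L]),
             dt = tree$edge.length)
}

# patristic distance (My) between two labelled nodes
patristic_distance <- function(tree, a, b, dmat = NULL) {
  if (is.null(dmat)) dmat <- ape::dist.nodes(tree)
  dmat[node_number(tree, a), node_number(tree, b)]
}

# labels on the root-to-node path, in order, including both ends
root_path <- function(tree, label) {
  k <- node_number(tree, label)
  path <- k
  repeat {
    e <- tree$edge[tree$edge[, 2L] == k, 1L]
    if (!length(e)) break
    k <- e
    path <- c(k, path)
  }
  node_label(tree, path)
}

# TRUE if node `a` lies on the root path of node `b` (a strictly above b)
is_ancestor_of <- function(tree, a, b) {
  if (a == b) return(FALSE)
  a %in% root_path(tree, b)[-length(root_path(tree, b))]
}

# branches (child labels) are on independent lineages iff neither lies on
# the other's root path
independent_branches <- function(tree, a, b) {
  if (a == b) return(FALSE)
  !is_ancestor_of(tree, a, b) && !is_ancestor_of(tree, b, a)
}
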