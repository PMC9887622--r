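#' @keywords internal
"_PACKAGE"

#' @importFrom ape read.tree write.tree is.rooted getMRCA keep.tip Ntip Nnode
#' @importFrom stats runif rpois median setNames
#' @importFrom utils read.delim write.table
NULL

## Internal helpers over ape "phylo" trees. Nodes are addressed by ape's
## integer numbering (tips 1..Ntip, internals Ntip+1..Ntip+Nnode); node *keys*
## are the stable string ids used in all user-facing tables: tip label for a
## tip, the node label for an internal node, or "node<N>" when unlabeled.

n_nodes_total <- function(tree) length(tree$tip.label) + tree$Nnode

node_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  keys <- character(n_nodes_total(tree))
  keys[seq_len(ntip)] <- tree$tip.label
  lab <- tree$node.label
  for (i in seq_len(tree$Nnode)) {
    node <- ntip + i
    if (!is.null(lab) && !is.na(lab[i]) && nzchar(lab[i])) {
      keys[node] <- lab[i]
    } else {
      keys[node] <- paste0("node", node)
    }
  }
  keys
}

## resolve a vector of node keys or numbers to node numbers
resolve_nodes <- function(tree, nodes) {
  if (is.numeric(nodes)) return(as.integer(nodes))
  keys <- node_keys(tree)
  idx <- match(nodes, keys)
  if (anyNA(idx)) {
    stop("node(s) not found in tree: ", paste(nodes[is.na(idx)], collapse = ", "))
  }
  idx
}

root_node <- function(tree) length(tree$tip.label) + 1L

## parent[node] = parent node number, NA for the root
parent_vector <- function(tree) {
  p <- rep(NA_integer_, n_nodes_total(tree))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

## children[[node]] = integer vector of child node numbers
children_list <- function(tree) {
  ch <- vector("list", n_nodes_total(tree))
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    ch[[a]] <- c(ch[[a]], tree$edge[i, 2])
  }
  ch
}

## edge length of the branch above each node (NA for root)
branch_above <- function(tree) {
  bl <- rep(NA_real_, n_nodes_total(tree))
  len <- tree$edge.length
  if (is.null(len)) len <- rep(0, nrow(tree$edge))
  bl[tree$edge[, 2]] <- len
  bl
}

## order nodes so every child precedes its parent, root last
postorder_simple <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  seen <- logical(n_nodes_total(tree))
  out <- integer(0)
  for (i in seq_len(nrow(po$edge))) {
    child <- po$edge[i, 2]
    if (!seen[child]) { out <- c(out, child); seen[child] <- TRUE }
  }
  c(out, root_node(tree))
}

## preorder: every parent precedes its children
preorder_simple <- function(tree) rev(postorder_simple(tree))

## list per node of descendant tip numbers (tips: themselves)
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  out <- vector("list", n_nodes_total(tree))
  for (node in postorder_simple(tree)) {
    if (node <= ntip) {
      out[[node]] <- node
    } else {
      out[[node]] <- unlist(lapply(ch[[node]], function(c) out[[c]]))
    }
  }
  out
}

## all ancestors of a node (parent, grandparent, ..., root)
ancestor_nodes <- function(tree, node, parents = parent_vector(tree)) {
  out <- integer(0)
  p <- parents[node]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parents[p]
  }
  out
}

## all descendants of a node including itself
descendant_nodes <- function(tree, node) {
  ch <- children_list(tree)
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, ch[[v]])
  }
  out
}

## sum of branch lengths on the path from an ancestor down to a descendant
path_length_down <- function(tree, from, to) {
  parents <- parent_vector(tree)
  bl <- branch_above(tree)
  total <- 0
  v <- to
  while (!is.na(v) && v != from) {
    total <- total + bl[v]
    v <- parents[v]
  }
  if (is.na(v)) stop("node ", to, " is not a descendant of node ", from)
  total
}

## ensure every internal node carries a unique, stable label
label_internal_nodes <- function(tree, prefix = "N") {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  empty <- is.na(lab) | !nzchar(lab)
  lab[empty] <- paste0(prefix, which(empty) + ntip)
  tree$node.label <- lab
  tree
}
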