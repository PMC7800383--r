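# Fitch parsimony and derived-clade counting on rooted binary trees.

#' Fitch parsimony score for a binary character
#'
#' Standard bottom-up Fitch pass on a rooted binary tree: each tip carries
#' state {1} (derived) or {0}; at each internal node the state set is the
#' intersection of the child sets when non-empty, otherwise their union, and
#' each union counts one transition.  The returned score is the minimum
#' number of character-state changes.
#'
#' @param tree A rooted, binary `phylo` object.
#' @param derived_taxa Tips carrying the derived state.
#' @return Integer: the minimum number of transitions.
#' @examples
#' fitch_parsimony(ape::read.tree(text = "((A:1,B:1):1,C:2);"), c("B", "C"))
#' @export
fitch_parsimony <- function(tree, derived_taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (max(tabulate(tree$edge[, 1])) > 2)
    stop("tree contains polytomies; resolve them before Fitch counting")
  n_tip <- length(tree$tip.label)
  miss <- setdiff(derived_taxa, tree$tip.label)
  if (length(miss) > 0)
    stop("derived taxa not in the tree: ", paste(miss, collapse = ", "))
  # state sets encoded as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- integer(n_tip + tree$Nnode)
  sets[seq_len(n_tip)] <- ifelse(tree$tip.label %in% derived_taxa, 2L, 1L)
  score <- 0L
  edge <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    s_child <- sets[edge[e, 2]]
    if (sets[p] == 0L) {
      sets[p] <- s_child
    } else {
      s <- bitwAnd(sets[p], s_child)
      if (s == 0L) {
        s <- bitwOr(sets[p], s_child)
        score <- score + 1L
      }
      sets[p] <- s
    }
  }
  score
}

#' Number of maximal derived clades on a gene tree
#'
#' Counts the maximal clades whose tip sets contain only derived taxa and
#' that jointly cover the derived set; a value of 1 means the derived taxa
#' are monophyletic.
#'
#' @inheritParams fitch_parsimony
#' @return Integer count of clades.
#' @export
derived_clade_count <- function(tree, derived_taxa) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  miss <- setdiff(derived_taxa, tree$tip.label)
  if (length(miss) > 0)
    stop("derived taxa not in the tree: ", paste(miss, collapse = ", "))
  pure <- rep(NA, n_tip + tree$Nnode)
  pure[seq_len(n_tip)] <- tree$tip.label %in% derived_taxa
  edge <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    pure[p] <- if (is.na(pure[p])) pure[edge[e, 2]] else
      pure[p] && pure[edge[e, 2]]
  }
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[edge[, 2]] <- edge[, 1]
  sum(vapply(which(pure), function(v) {
    is.na(parent[v]) || !pure[parent[v]]
  }, logical(1)))
}
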