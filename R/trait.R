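# Binary-trait evolution along a gene tree with explicit mutation events.
# A two-state symmetric Poisson process: events occur independently on each
# branch at a constant rate per coalescent unit and each event flips the
# current state; the root state is 0 (ancestral).

#' Evolve a binary trait along a gene tree
#'
#' @param tree A rooted `phylo` object with branch lengths in coalescent
#'   units.
#' @param rate Mutation rate per 2N generations (events per coalescent unit
#'   of branch length).
#' @param seed Optional random seed.
#' @return An object of class `trait_realization`: a list with
#'   `tip_states` (named 0/1 vector), `events` (a tibble with one row per
#'   mutation: `branch` (child node id), `time` (backward time of the
#'   event), `direction` (`"0->1"` or `"1->0"`), `branch_class`
#'   (`"tip"`/`"internal"`)) and `root_state` (always 0).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' evolve_trait(tr, rate = 0.5, seed = 1)
#' @export
evolve_trait <- function(tree, rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths[seq_len(n_tip)]) - depths
  n_events <- rpois(nrow(tree$edge), rate * tree$edge.length)
  # preorder over edges so parent states are known
  ord <- order(ages[tree$edge[, 1]], decreasing = TRUE)
  state <- integer(max(tree$edge))
  state[root] <- 0L
  ev <- list()
  for (e in ord) {
    par <- tree$edge[e, 1]
    chd <- tree$edge[e, 2]
    k <- n_events[e]
    s <- state[par]
    if (k > 0) {
      # event ages, ordered from the rootward end of the branch downwards
      t_ev <- sort(runif(k, min = ages[chd], max = ages[par]),
                   decreasing = TRUE)
      dirs <- ifelse((s + seq_len(k) - 1L) %% 2L == 0L, "0->1", "1->0")
      ev[[length(ev) + 1]] <- tibble::tibble(
        branch = chd, time = t_ev, direction = dirs,
        branch_class = if (chd <= n_tip) "tip" else "internal"
      )
    }
    state[chd] <- (s + k) %% 2L
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(branch = integer(), time = numeric(),
                   direction = character(), branch_class = character())
  structure(
    list(
      tip_states = setNames(state[seq_len(n_tip)], tree$tip.label),
      events = events, root_state = 0L, tree = tree
    ),
    class = "trait_realization"
  )
}

#' @export
print.trait_realization <- function(x, ...) {
  cat("Binary trait realization:", nrow(x$events), "mutation event(s)\n")
  cat("tip states:",
      paste(names(x$tip_states), x$tip_states, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Does a trait realization match an observed pattern?
#'
#' A simulated locus is focal when the set of tips carrying the derived
#' state equals the observed derived set exactly (state matching; loci whose
#' derived set arises via back-mutations still count).
#'
#' @param realization A [evolve_trait()] result.
#' @param derived_taxa Character vector of derived tip labels.
#' @return Logical.
#' @export
is_focal <- function(realization, derived_taxa) {
  stopifnot(inherits(realization, "trait_realization"))
  tips <- names(realization$tip_states)
  miss <- setdiff(derived_taxa, tips)
  if (length(miss) > 0)
    stop("derived taxa not among the tips: ", paste(miss, collapse = ", "))
  setequal(tips[realization$tip_states == 1], derived_taxa)
}
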