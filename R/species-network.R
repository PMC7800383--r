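# Species networks for simulation: a rooted ultrametric tree (ape phylo,
# branch lengths in coalescent units) plus instantaneous introgression pulses.

#' Build a species network for coalescent simulation
#'
#' @param tree A rooted, ultrametric `phylo` object or a Newick string.
#'   Branch lengths are in coalescent units (2N generations).
#' @param pulses Optional data frame of introgression pulses with columns
#'   `donor`, `recipient` (tip labels, forward-time direction), `time`
#'   (coalescent units before present) and `probability`.
#' @param outgroup Optional tip label used for trait polarization.
#' @return An object of class `species_network`.
#' @examples
#' net <- species_network("((A:1,B:1):2.5,C:3.5);")
#' @export
species_network <- function(tree, pulses = NULL, outgroup = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  depths <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  tip_depths <- depths[seq_len(n_tip)]
  if (max(tip_depths) - min(tip_depths) > 1e-6)
    stop("species tree must be ultrametric (tolerance 1e-6): ",
         "root-to-tip path lengths differ by ",
         format(max(tip_depths) - min(tip_depths)))
  ages <- max(tip_depths) - depths
  ages[seq_len(n_tip)] <- 0
  if (any(ages[-seq_len(n_tip)] <= 0))
    stop("internal node ages must be strictly positive")
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  net <- structure(
    list(tree = tree, ages = ages, pulses = NULL, outgroup = outgroup),
    class = "species_network"
  )
  if (!is.null(pulses) && nrow(as.data.frame(pulses)) > 0) {
    pulses <- tibble::as_tibble(pulses)
    stopifnot(all(c("donor", "recipient", "time", "probability")
                  %in% names(pulses)))
    if (any(pulses$probability <= 0 | pulses$probability > 1))
      stop("pulse probabilities must be in (0, 1]")
    if (any(pulses$time <= 0)) stop("pulse times must be > 0")
    for (i in seq_len(nrow(pulses))) {
      pd <- .pop_at(net, pulses$donor[i], pulses$time[i])
      pr <- .pop_at(net, pulses$recipient[i], pulses$time[i])
      if (pd == pr)
        stop("pulse ", i, " (", pulses$donor[i], " -> ",
             pulses$recipient[i], " at ", pulses$time[i],
             "): donor and recipient lineages have already merged at ",
             "the pulse time")
    }
    by_time <- tapply(pulses$probability, pulses$time, sum)
    if (any(by_time > 1))
      stop("pulses sharing one time are exclusive alternatives; their ",
           "probabilities must sum to at most 1")
    net$pulses <- pulses[order(pulses$time), ]
  }
  net
}

#' @export
print.species_network <- function(x, ...) {
  cat("Species network:", length(x$tree$tip.label), "taxa, height",
      format(max(x$ages)), "coalescent units\n")
  if (!is.null(x$pulses)) {
    cat(nrow(x$pulses), "introgression pulse(s):\n")
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  %s -> %s at %g with probability %g\n",
                  x$pulses$donor[i], x$pulses$recipient[i],
                  x$pulses$time[i], x$pulses$probability[i]))
  }
  if (!is.null(x$outgroup)) cat("outgroup:", x$outgroup, "\n")
  invisible(x)
}

# population (labelled by the smallest tip index of its clade) that contains
# the lineage of `taxon` at backward time t
.pop_at <- function(net, taxon, t) {
  tree <- net$tree
  n_tip <- length(tree$tip.label)
  tip <- match(taxon, tree$tip.label)
  if (is.na(tip)) stop("unknown taxon in pulse specification: ", taxon)
  node <- tip
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0 || net$ages[parent] >= t) break
    node <- parent
  }
  clade_tips <- if (node <= n_tip) node else
    ape::prop.part(tree)[[node - n_tip]]
  min(clade_tips)
}

# encode merge + pulse events for the C++ core
.encode_events <- function(net) {
  tree <- net$tree
  n_tip <- length(tree$tip.label)
  parts <- ape::prop.part(tree) # tip sets per internal node, node n_tip+1 ..
  int_nodes <- seq_len(tree$Nnode) + n_tip
  ev <- tibble::tibble(
    time = net$ages[int_nodes],
    type = 0L,
    a = NA_integer_, b = NA_integer_,
    prob = 0, id = 0L
  )
  for (j in seq_along(int_nodes)) {
    children <- tree$edge[tree$edge[, 1] == int_nodes[j], 2]
    pops <- vapply(children, function(ch) {
      if (ch <= n_tip) ch else min(parts[[ch - n_tip]])
    }, integer(1))
    ev$a[j] <- min(pops)
    ev$b[j] <- max(pops)
  }
  if (!is.null(net$pulses)) {
    p <- net$pulses
    for (i in seq_len(nrow(p))) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        time = p$time[i], type = 1L,
        a = .pop_at(net, p$recipient[i], p$time[i]),
        b = .pop_at(net, p$donor[i], p$time[i]),
        prob = p$probability[i], id = i - 1L
      ))
    }
  }
  # pulses fire before a merge at the same instant
  ev[order(ev$time, -ev$type), ]
}

.msnc_call <- function(net, n_loci, mut_rate = 0, stem_height = 0,
                       derived = NULL, want_trees = FALSE,
                       want_topologies = FALSE, want_focal = TRUE) {
  tree <- net$tree
  n_tip <- length(tree$tip.label)
  ev <- .encode_events(net)
  dmask <- rep(FALSE, n_tip)
  if (!is.null(derived)) {
    idx <- match(derived, tree$tip.label)
    if (anyNA(idx))
      stop("derived taxa not in the tree: ",
           paste(derived[is.na(idx)], collapse = ", "))
    dmask[idx] <- TRUE
  }
  msnc_sim_cpp(n_tip, tree$tip.label, ev$time, ev$type, ev$a - 1L,
               ev$b - 1L, ev$prob, ev$id, as.integer(n_loci), mut_rate,
               stem_height, dmask, want_trees, want_topologies, want_focal)
}

#' Simulate gene trees under the multispecies network coalescent
#'
#' Draws genealogies for unlinked loci under the structured coalescent on
#' the species network: lineages coalesce at rate k(k-1)/2 per coalescent
#' unit within a population, populations merge at species-tree nodes, and at
#' each pulse time every lineage in the recipient population independently
#' follows the reticulation edge into the donor population with the pulse
#' probability.
#'
#' @param net A [species_network()].
#' @param n_trees Number of gene trees to simulate.
#' @param seed Random seed (the stream is reproducible for a fixed seed).
#' @return A tibble with columns `locus`, `newick` (branch lengths in
#'   coalescent units) and `origin` (`"species"` or a comma-separated list
#'   of the pulses whose reticulation edge the locus followed, as
#'   `"pulse<i>"`).
#' @examples
#' net <- species_network("((A:1,B:1):2.5,C:3.5);")
#' simulate_gene_trees(net, 3, seed = 1)
#' @export
simulate_gene_trees <- function(net, n_trees, seed = NULL) {
  stopifnot(inherits(net, "species_network"), n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- .msnc_call(net, n_trees, want_trees = TRUE, want_focal = FALSE)
  origin <- vapply(res$tree_origin, function(m) {
    if (m == 0) return("species")
    paste0("pulse", which(bitwAnd(m, 2^(0:30)) != 0), collapse = ",")
  }, character(1))
  tibble::tibble(locus = seq_len(n_trees), newick = res$trees,
                 origin = origin)
}

#' Parse simulated gene trees into a multiPhylo object
#'
#' @param sims A tibble from [simulate_gene_trees()].
#' @return An `ape` multiPhylo object.
#' @export
as_multiphylo <- function(sims) {
  ape::read.tree(text = paste(sims$newick, collapse = "\n"))
}

#' Prune a species network to the smallest clade spanning the derived taxa
#'
#' Returns the smallest clade that contains all taxa carrying the derived
#' state, with the specified outgroup re-grafted at its original divergence
#' time from that clade.  Pulses whose donor or recipient falls outside the
#' retained taxa are dropped with a warning.
#'
#' @param net A [species_network()].
#' @param derived_taxa Character vector of derived tip labels.
#' @param outgroup Tip label of the outgroup; must lie outside the minimal
#'   clade.
#' @return A pruned [species_network()] with `outgroup` set.
#' @export
prune_to_focal_clade <- function(net, derived_taxa, outgroup) {
  stopifnot(inherits(net, "species_network"))
  tree <- net$tree
  miss <- setdiff(derived_taxa, tree$tip.label)
  if (length(miss) > 0)
    stop("derived taxa not in the tree: ", paste(miss, collapse = ", "))
  if (!outgroup %in% tree$tip.label) stop("unknown outgroup: ", outgroup)
  n_tip <- length(tree$tip.label)
  mrca <- if (length(derived_taxa) == 1) {
    match(derived_taxa, tree$tip.label)
  } else {
    ape::getMRCA(tree, derived_taxa)
  }
  clade_tips <- if (mrca <= n_tip) tree$tip.label[mrca] else
    tree$tip.label[ape::prop.part(tree)[[mrca - n_tip]]]
  if (outgroup %in% clade_tips)
    stop("outgroup '", outgroup,
         "' lies inside the minimal clade containing the derived taxa")
  keep <- union(clade_tips, outgroup)
  join_age <- net$ages[ape::getMRCA(tree, c(clade_tips[1], outgroup))]
  sub <- ape::keep.tip(tree, keep)
  # keep.tip preserves the path lengths, so the outgroup still attaches at
  # its original divergence time from the clade
  pulses <- net$pulses
  if (!is.null(pulses)) {
    ok <- pulses$donor %in% keep & pulses$recipient %in% keep
    if (any(!ok))
      warning(sum(!ok), " pulse(s) referencing pruned taxa were dropped")
    pulses <- if (any(ok)) pulses[ok, ] else NULL
  }
  out <- species_network(sub, pulses = pulses, outgroup = outgroup)
  stopifnot(abs(max(out$ages) - join_age) < 1e-6)
  out
}
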