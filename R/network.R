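#' Root depth used for ancestral-branch bookkeeping
#'
#' Total height, in coalescent units (2N generations), of the three-taxon
#' model's bookkeeping box.  The ancestral branch of a gene tree (the branch
#' subtending its root, on which a mutation followed by a tip reversal is one
#' of the two routes to homoplasy) extends from the gene-tree root up to this
#' height.  The default is calibrated so that the ILS-only model reproduces a
#' hemiplasy/homoplasy ratio of 0.818 at `t1 = 1`, `t2 = 3.5`,
#' `theta = 0.002`, the published baseline for this parameterization.
#'
#' @export
default_root_depth <- 16.94052077

#' Three-taxon introgression network for the analytic model
#'
#' Parameterizes a rooted three-taxon species network ((A,B),C) with an
#' instantaneous introgression pulse between B and C.  All times are in
#' coalescent units (2N generations), measured backwards from the tips.
#'
#' @param t1 Time of the A/B split.
#' @param t2 Time of the split between C and the ancestor of A and B;
#'   must exceed `t1`.
#' @param tm Time of the introgression pulse; must satisfy `0 < tm < t1`.
#'   May be `NULL` when `delta2 = delta3 = 0`.
#' @param delta2 Probability that a locus follows the C-to-B introgressed
#'   history (parent tree 2).
#' @param delta3 Probability that a locus follows the B-to-C introgressed
#'   history (parent tree 3).
#' @param theta Population-scaled trait mutation rate.  The per-lineage
#'   event rate per 2N generations used throughout is `theta / 2`.
#' @param root_depth Total bookkeeping height for the ancestral branch; see
#'   [default_root_depth].
#'
#' @return An object of class `three_taxon_network`.
#' @examples
#' net <- three_taxon_network(t1 = 1, t2 = 3.5, theta = 0.002)
#' parent_tree_probabilities(net)
#' @export
three_taxon_network <- function(t1, t2, tm = NULL, delta2 = 0, delta3 = 0,
                                theta, root_depth = default_root_depth) {
  if (!is.numeric(t1) || t1 <= 0) stop("invalid network: t1 must be > 0")
  if (!is.numeric(t2) || t2 <= t1)
    stop("invalid network: need t1 < t2 (speciation order)")
  if (delta2 < 0 || delta3 < 0 || delta2 + delta3 > 1)
    stop("invalid network: need 0 <= delta2, delta3 and delta2 + delta3 <= 1")
  if (is.null(tm)) {
    if (delta2 + delta3 > 0)
      stop("invalid network: tm required when delta2 + delta3 > 0")
    tm <- t1 / 2 # placeholder, unused when no introgression
  }
  if (tm <= 0 || tm >= t1)
    stop("invalid network: need 0 < tm < t1 (pulse precedes the A/B split)")
  if (!is.numeric(theta) || theta <= 0)
    stop("invalid network: theta must be > 0")
  if (root_depth <= t2 + 1)
    stop("invalid network: root_depth must exceed t2 + 1")
  structure(
    list(t1 = t1, t2 = t2, tm = tm, delta2 = delta2, delta3 = delta3,
         theta = theta, root_depth = root_depth),
    class = "three_taxon_network"
  )
}

#' @export
print.three_taxon_network <- function(x, ...) {
  cat("Three-taxon network ((A,B),C), coalescent units\n")
  cat(sprintf("  t1 = %g, t2 = %g, tm = %g\n", x$t1, x$t2, x$tm))
  cat(sprintf("  delta2 (C->B) = %g, delta3 (B->C) = %g\n",
              x$delta2, x$delta3))
  cat(sprintf("  theta = %g, root depth = %g\n", x$theta, x$root_depth))
  invisible(x)
}

#' Parent-tree probabilities of a three-taxon network
#'
#' A locus follows the species history (parent tree 1) with probability
#' `1 - (delta2 + delta3)`, the C-to-B history (parent tree 2) with
#' probability `delta2`, and the B-to-C history (parent tree 3) with
#' probability `delta3`.
#'
#' @param net A [three_taxon_network()].
#' @return A tibble with columns `parent_tree` and `probability`.
#' @export
parent_tree_probabilities <- function(net) {
  stopifnot(inherits(net, "three_taxon_network"))
  tibble::tibble(
    parent_tree = 1:3,
    history = c("species", "C->B introgression", "B->C introgression"),
    probability = c(1 - (net$delta2 + net$delta3), net$delta2, net$delta3)
  )
}
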