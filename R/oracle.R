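# Simulation cross-check of the analytic three-taxon model: the same
# quantities Pe and Po, estimated by simulating genealogies (with the
# ancestral-branch bookkeeping up to root_depth) and overlaying trait
# mutations at rate theta/2 per coalescent unit.

#' Simulate hemiplasy and homoplasy probabilities for a three-taxon network
#'
#' Builds the explicit species network for a [three_taxon_network()]
#' (tips A, B, C; pulses according to `delta2`/`delta3`), simulates
#' `n_loci` genealogies with the trait overlay, and counts loci whose tip
#' pattern is exactly \{B, C\} derived with one mutation (the hemiplasy
#' event of the analytic model) or two mutations (the homoplasy event).
#' Mutations are also laid on the ancestral branch between the gene-tree
#' root and `root_depth`, matching the analytic bookkeeping.
#'
#' @param net A [three_taxon_network()].
#' @param n_loci Number of simulated loci.
#' @param seed Random seed.
#' @return A one-row tibble with `p_e`, `p_o`, their binomial standard
#'   errors, and the event counts.
#' @examples
#' net <- three_taxon_network(t1 = 1, t2 = 3.5, theta = 0.02)
#' simulate_pepo(net, n_loci = 5e4, seed = 1)
#' @export
simulate_pepo <- function(net, n_loci, seed = NULL) {
  stopifnot(inherits(net, "three_taxon_network"))
  pulses <- NULL
  rows <- list()
  if (net$delta2 > 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      donor = "C", recipient = "B", time = net$tm,
      probability = net$delta2)
  if (net$delta3 > 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      donor = "B", recipient = "C", time = net$tm,
      probability = net$delta3)
  if (length(rows)) pulses <- dplyr::bind_rows(rows)
  nwk <- sprintf("((A:%.10g,B:%.10g):%.10g,C:%.10g);",
                 net$t1, net$t1, net$t2 - net$t1, net$t2)
  snet <- species_network(nwk, pulses = pulses)
  if (!is.null(seed)) set.seed(seed)
  res <- .msnc_call(snet, n_loci, mut_rate = net$theta / 2,
                    stem_height = net$root_depth,
                    derived = c("B", "C"))
  k <- res$focal$n_mutations
  n_pe <- sum(k == 1)
  n_po <- sum(k == 2)
  tibble::tibble(
    n_loci = n_loci, n_hemiplasy = n_pe, n_homoplasy = n_po,
    p_e = n_pe / n_loci, p_o = n_po / n_loci,
    se_e = sqrt(pmax(n_pe, 1)) / n_loci,
    se_o = sqrt(pmax(n_po, 1)) / n_loci
  )
}
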