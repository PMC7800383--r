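# The inference core: simulate gene trees, overlay a binary trait, keep the
# loci whose tip states match the observed pattern, and summarize how many
# transitions (and of what kind) explain the pattern, against a
# Fitch-parsimony baseline computed on the species tree.

#' Classify a focal mutation count against the parsimony baseline
#'
#' @param n_mutations Number of mutations on a focal gene tree.
#' @param fitch_score Fitch parsimony score of the trait pattern on the
#'   species tree.
#' @return `"hemiplasy-only"` for a single mutation, `"mixed"` for counts
#'   between 1 and the parsimony score (some transitions must then involve
#'   discordant branches), `"parsimony-equivalent"` for counts at or above
#'   it.
#' @export
classify_mutation_count <- function(n_mutations, fitch_score) {
  stopifnot(all(n_mutations >= 1), fitch_score >= 1)
  dplyr::case_when(
    n_mutations == 1 ~ "hemiplasy-only",
    n_mutations < fitch_score ~ "mixed",
    TRUE ~ "parsimony-equivalent"
  )
}

#' Run the hemiplasy inference pipeline
#'
#' Simulates `n_trees` gene trees under the species network, evolves a
#' binary trait (rate per 2N generations, root state 0) along each, filters
#' to the focal loci whose derived tip set matches `derived_taxa` exactly
#' (the outgroup, if any, must carry the ancestral state), and summarizes
#' mutation counts, branch classes, derived-clade structure and locus
#' origins against the Fitch-parsimony baseline.
#'
#' Loci are processed in a single streaming pass, so memory use does not
#' grow with `n_trees`.  Larger totals can be accumulated by running
#' several chunks with distinct seeds and pooling the tidied records.
#'
#' @param net A [species_network()].
#' @param derived_taxa Tips observed in the derived state.
#' @param rate Trait mutation rate per 2N generations.
#' @param n_trees Number of simulated loci.
#' @param seed Random seed.
#' @param outgroup Outgroup label (defaults to the network's outgroup, if
#'   any); required when `prune = TRUE`.
#' @param prune Prune the network to the smallest clade containing the
#'   derived taxa plus the outgroup before simulating (default `TRUE` when
#'   an outgroup is available).
#' @return An object of class `hemiplasy_fit`; see [tidy.hemiplasy_fit()]
#'   and [glance.hemiplasy_fit()].
#' @examples
#' net <- species_network("((A:1,B:1):2.5,C:3.5);")
#' fit <- run_hemiplasy(net, derived_taxa = c("B", "C"), rate = 0.05,
#'                      n_trees = 2000, seed = 1)
#' glance(fit)
#' @export
run_hemiplasy <- function(net, derived_taxa, rate, n_trees, seed = NULL,
                          outgroup = net$outgroup,
                          prune = !is.null(outgroup)) {
  stopifnot(inherits(net, "species_network"), rate > 0, n_trees >= 1)
  if (length(derived_taxa) == 0)
    stop("derived_taxa must be non-empty")
  if (setequal(derived_taxa, net$tree$tip.label))
    stop("derived_taxa must be a proper subset of the taxa")
  if (prune) {
    if (is.null(outgroup)) stop("prune = TRUE requires an outgroup")
    net <- prune_to_focal_clade(net, derived_taxa, outgroup)
  }
  if (!is.null(outgroup) && outgroup %in% derived_taxa)
    stop("the outgroup must carry the ancestral state")
  fitch <- fitch_parsimony(net$tree, derived_taxa)
  if (!is.null(seed)) set.seed(seed)
  res <- .msnc_call(net, n_trees, mut_rate = rate, derived = derived_taxa)
  focal <- tibble::as_tibble(res$focal)
  n_pulses <- if (is.null(net$pulses)) 0L else nrow(net$pulses)
  focal$origin <- vapply(focal$origin_mask, function(m) {
    if (m == 0) "species" else
      paste0("pulse", which(bitwAnd(m, 2^(0:30)) != 0), collapse = ",")
  }, character(1))
  focal$class <- if (nrow(focal)) {
    classify_mutation_count(focal$n_mutations, fitch)
  } else {
    character(0)
  }
  if (nrow(focal) == 0)
    warning("no simulated locus matched the trait pattern; ",
            "increase n_trees or reconsider the mutation rate")
  structure(
    list(
      network = net, derived_taxa = derived_taxa, rate = rate,
      n_simulated = res$n_loci, n_focal = res$n_focal,
      n_introgressed = res$n_introgressed,
      pulse_taken = res$pulse_taken,
      fitch_score = fitch, focal = focal
    ),
    class = "hemiplasy_fit"
  )
}

#' Per-focal-locus records of a hemiplasy fit
#'
#' @param x A [run_hemiplasy()] result.
#' @param ... Unused.
#' @return A tibble with one row per focal locus: mutation counts split by
#'   branch class and direction, the number of maximal derived clades on
#'   the gene tree, the locus origin and a canonical topology string.
#' @export
tidy.hemiplasy_fit <- function(x, ...) {
  dplyr::select(x$focal, "locus", "n_mutations", "class", "tip_mutations",
                "internal_mutations", "forward", "reversal",
                "derived_clades", "origin", "topology")
}

#' One-row summary of a hemiplasy fit
#'
#' `cond_hemiplasy` is the single-mutation fraction among focal loci with
#' one or two mutations (`hemi / (hemi + homo)`), mirroring the
#' hemiplasy-vs-homoplasy comparison at the parsimony scale of a
#' three-taxon pattern; `pepo` is `cond_hemiplasy / cond_homoplasy`.
#'
#' @inheritParams tidy.hemiplasy_fit
#' @return A one-row tibble.
#' @export
glance.hemiplasy_fit <- function(x, ...) {
  hemi <- sum(x$focal$n_mutations == 1)
  homo <- sum(x$focal$n_mutations == 2)
  tibble::tibble(
    n_simulated = x$n_simulated, n_focal = x$n_focal,
    fitch_score = x$fitch_score,
    hemi_count = hemi, homo_count = homo,
    cond_hemi = hemi / (hemi + homo), cond_homo = homo / (hemi + homo),
    raw_hemi = hemi / x$n_simulated, raw_homo = homo / x$n_simulated,
    pepo = hemi / homo,
    monophyly_fraction = mean(x$focal$derived_clades == 1),
    introgressed_focal_fraction = mean(x$focal$origin != "species"),
    introgressed_locus_fraction = x$n_introgressed / x$n_simulated
  )
}

#' Mutation-count distribution among focal loci
#'
#' @param x A [run_hemiplasy()] result.
#' @return A tibble with `n_mutations`, `class`, `count` and `frequency`
#'   (conditional on being focal).
#' @export
mutation_count_distribution <- function(x) {
  stopifnot(inherits(x, "hemiplasy_fit"))
  out <- dplyr::count(x$focal, .data$n_mutations, .data$class,
                      name = "count")
  out$frequency <- out$count / sum(out$count)
  out
}

#' @export
print.hemiplasy_fit <- function(x, ...) {
  cat("Hemiplasy inference fit\n")
  cat(sprintf("  %s loci simulated, %d focal (matching the trait pattern)\n",
              format(x$n_simulated, big.mark = ","), x$n_focal))
  cat(sprintf("  Fitch parsimony baseline on the species tree: %d\n",
              x$fitch_score))
  if (nrow(x$focal) > 0) {
    print(mutation_count_distribution(x))
    g <- glance(x)
    cat(sprintf("  conditional hemiplasy (1 vs 2 mutations): %.3f\n",
                g$cond_hemi))
    cat(sprintf("  derived taxa monophyletic on %.1f%% of focal trees\n",
                100 * g$monophyly_fraction))
    if (!is.null(x$network$pulses))
      cat(sprintf("  focal loci with an introgressed history: %.3f\n",
                  g$introgressed_focal_fraction))
  }
  invisible(x)
}

#' @export
summary.hemiplasy_fit <- function(object, ...) print(object, ...)

#' Plot the focal mutation-count distribution
#'
#' @param object A [run_hemiplasy()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of the conditional mutation-count
#'   distribution, coloured by classification against the parsimony
#'   baseline.
#' @export
autoplot.hemiplasy_fit <- function(object, ...) {
  d <- mutation_count_distribution(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_mutations),
                                  y = .data$frequency,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mutations on focal gene tree",
                  y = "conditional frequency", fill = NULL)
}
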