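# Closed-form hemiplasy / homoplasy probabilities under the multispecies
# network coalescent, three taxa, one introgression pulse.
#
# Per parent tree (inner join s_in, outer join s_out) there are four gene-tree
# classes: one from lineage sorting of the sister pair inside (s_in, s_out)
# and three equiprobable classes from incomplete lineage sorting above s_out.
# Each class carries five branches: tips lambda1..3 (A, B, C), the internal
# branch lambda4, and the ancestral branch lambda5 which runs from the
# gene-tree root up to the bookkeeping height `root_depth`.
#
# nu(lambda, class) = P(at least one mutation) is obtained by integrating the
# Poisson no-event probability (rate theta/2 per coalescent unit) over the
# exact marginal coalescent density of the branch length, not by plugging in
# the expected length.

# (1 - exp(-a * x)) / a, stable near a = 0
.em1 <- function(x, a) ifelse(abs(a) < 1e-12, x, -expm1(-a * x) / a)

# nu vectors for the four classes of one parent tree; s_in/s_out may be
# vectors (vectorized over the grid).  Returns a list of class entries.
.pt_classes <- function(s_in, s_out, cc, H, parent, sister_ls) {
  D <- s_out - s_in
  h <- pmax(H - s_out, 0)
  p_ls <- -expm1(-D)
  p_ils <- exp(-D) / 3

  # lineage-sorting class
  nu_ls_sis <- 1 - exp(-cc * s_in) * .em1(D, 1 + cc) / .em1(D, 1)
  nu_ls_out <- 1 - exp(-cc * s_out) / (1 + cc)
  nu_ls_int <- 1 - exp(-cc * D) * .em1(D, 1 - cc) / .em1(D, 1) / (1 + cc)
  nu_ls_anc <- 1 - (exp(-cc * h) * .em1(h, 1 - cc) + exp(-h))

  # incomplete-lineage-sorting classes (first coalescence Exp(3) above s_out,
  # internal branch Exp(1), ancestral branch to the bookkeeping height)
  nu_i_sis <- 1 - exp(-cc * s_out) * 3 / (3 + cc)
  nu_i_out <- 1 - exp(-cc * s_out) * 3 / ((3 + cc) * (1 + cc))
  nu_i_int <- cc / (1 + cc)
  nu_i_anc <- 1 - (1.5 * exp(-cc * h) * (.em1(h, 1 - cc) - .em1(h, 3 - cc)) +
                     1.5 * (exp(-h) - exp(-3 * h) / 3))

  tip_nu <- function(sister, nus, nuo) {
    # order: lambda1 (A), lambda2 (B), lambda3 (C)
    switch(sister,
      AB = list(nus, nus, nuo),
      AC = list(nus, nuo, nus),
      BC = list(nuo, nus, nus)
    )
  }
  mk <- function(label, pathway, sister, prob, tips, nu4, nu5) {
    list(label = label, parent_tree = parent, pathway = pathway,
         sister = sister, prob = prob,
         nu1 = tips[[1]], nu2 = tips[[2]], nu3 = tips[[3]],
         nu4 = nu4, nu5 = nu5)
  }
  suffix <- if (parent == 1) "_1" else paste0("_", parent)
  ils_sisters <- c("AB", "AC", "BC")
  out <- list(mk(
    if (parent == 1) "AB1_1" else paste0(sister_ls, "1", suffix),
    "lineage sorting", sister_ls, p_ls,
    tip_nu(sister_ls, nu_ls_sis, nu_ls_out), nu_ls_int, nu_ls_anc
  ))
  for (s in ils_sisters) {
    lab <- if (s == sister_ls) paste0(s, "2", suffix) else paste0(s, suffix)
    out[[length(out) + 1]] <- mk(lab, "incomplete lineage sorting", s, p_ils,
                                 tip_nu(s, nu_i_sis, nu_i_out),
                                 nu_i_int, nu_i_anc)
  }
  out
}

# all 12 classes, probabilities weighted by parent tree; vectorized over tm
.all_classes <- function(t1, t2, tm, delta2, delta3, theta, H) {
  cc <- theta / 2
  w <- function(cls, wt) {
    lapply(cls, function(x) { x$prob <- x$prob * wt; x })
  }
  c(
    w(.pt_classes(t1, t2, cc, H, 1L, "AB"), 1 - (delta2 + delta3)),
    w(.pt_classes(tm, t2, cc, H, 2L, "BC"), delta2),
    w(.pt_classes(tm, t1, cc, H, 3L, "BC"), delta3)
  )
}

.pepo <- function(t1, t2, tm, delta2, delta3, theta, H) {
  cls <- .all_classes(t1, t2, tm, delta2, delta3, theta, H)
  pe <- 0
  po <- 0
  for (x in cls) {
    if (all(x$prob == 0)) next
    if (x$sister == "BC") {
      pe <- pe + x$prob * x$nu4 *
        (1 - x$nu1) * (1 - x$nu2) * (1 - x$nu3) * (1 - x$nu5)
    }
    po <- po + x$prob *
      (x$nu2 * x$nu3 * (1 - x$nu1) * (1 - x$nu4) * (1 - x$nu5) +
         x$nu5 * x$nu1 * (1 - x$nu2) * (1 - x$nu3) * (1 - x$nu4))
  }
  list(pe = pe, po = po)
}

#' Gene-tree classes and their branch mutation probabilities
#'
#' Enumerates the twelve gene-tree classes of the three-taxon network (four
#' per parent tree) with their probabilities and the per-branch mutation
#' probabilities nu(lambda_i, class) for the five branches: tips to A, B and
#' C (`nu_lambda1..3`), the internal branch (`nu_lambda4`) and the ancestral
#' branch (`nu_lambda5`).
#'
#' @param net A [three_taxon_network()].
#' @return A tibble, one row per class.  `probability` is conditional on the
#'   network (weighted by parent-tree probability); within a parent tree the
#'   conditional class probabilities sum to one.
#' @export
gene_tree_classes <- function(net) {
  stopifnot(inherits(net, "three_taxon_network"))
  cls <- .all_classes(net$t1, net$t2, net$tm, net$delta2, net$delta3,
                      net$theta, net$root_depth)
  purrr::map_dfr(cls, function(x) {
    tibble::tibble(
      class = x$label, parent_tree = x$parent_tree, pathway = x$pathway,
      sister = x$sister, probability = x$prob,
      nu_lambda1 = x$nu1, nu_lambda2 = x$nu2, nu_lambda3 = x$nu3,
      nu_lambda4 = x$nu4, nu_lambda5 = x$nu5
    )
  })
}

#' Branch mutation probabilities for one gene-tree class
#'
#' @param net A [three_taxon_network()].
#' @param class A class label as given by [gene_tree_classes()], e.g.
#'   `"BC_1"` or `"BC1_2"`.
#' @return A named numeric vector `c(lambda1, ..., lambda5)` of
#'   probabilities of at least one mutation on each branch.
#' @export
branch_mutation_profile <- function(net, class) {
  tab <- gene_tree_classes(net)
  row <- tab[tab$class == class, ]
  if (nrow(row) != 1)
    stop("unknown gene-tree class label: ", class,
         " (see gene_tree_classes(net)$class)")
  setNames(
    as.numeric(row[1, paste0("nu_lambda", 1:5)]),
    paste0("lambda", 1:5)
  )
}

#' Probability of hemiplasy
#'
#' The probability that the incongruent pattern (B and C derived, A
#' ancestral) arises from a single transition on the internal branch of a
#' discordant gene tree, with no other mutations, summed over all gene-tree
#' classes in which B and C are sister and weighted by parent-tree
#' probability.
#'
#' @param net A [three_taxon_network()].
#' @return A probability.
#' @seealso [prob_homoplasy()], [pepo_ratio()]
#' @export
prob_hemiplasy <- function(net) {
  stopifnot(inherits(net, "three_taxon_network"))
  .pepo(net$t1, net$t2, net$tm, net$delta2, net$delta3,
        net$theta, net$root_depth)$pe
}

#' Probability of homoplasy
#'
#' The probability of true convergence: either parallel forward mutations on
#' the tip branches leading to B and C, or a forward mutation on the
#' ancestral branch followed by a reversal on the tip branch leading to A,
#' in each case with no other mutations.  Both routes are available on every
#' gene-tree class; the sum is weighted by class probability.
#'
#' @inheritParams prob_hemiplasy
#' @return A probability.
#' @export
prob_homoplasy <- function(net) {
  stopifnot(inherits(net, "three_taxon_network"))
  .pepo(net$t1, net$t2, net$tm, net$delta2, net$delta3,
        net$theta, net$root_depth)$po
}

#' Hemiplasy-to-homoplasy ratio
#'
#' @inheritParams prob_hemiplasy
#' @return `prob_hemiplasy(net) / prob_homoplasy(net)`.
#' @export
pepo_ratio <- function(net) {
  prob_hemiplasy(net) / prob_homoplasy(net)
}

#' Hemiplasy/homoplasy ratio over a grid of introgression settings
#'
#' Scans the ratio P_e/P_o over admixture proportions and pulse timings for
#' one or more direction conventions, holding the species-tree times and the
#' mutation rate fixed.  For `direction = "both"` the total admixture
#' proportion is split evenly, `delta2 = delta3 = delta / 2`, so the three
#' panels share an x-axis scale; set `split_both = FALSE` to use
#' `delta2 = delta3 = delta` instead.
#'
#' @param t1,t2,theta,root_depth Base network parameters (see
#'   [three_taxon_network()]).
#' @param delta Admixture proportions (total probability of introgression).
#' @param tm Pulse times, in coalescent units before the present; must lie
#'   strictly between 0 and `t1`.
#' @param direction Subset of `"CtoB"`, `"BtoC"`, `"both"`.
#' @param split_both Split the total `delta` evenly across directions in the
#'   `"both"` panel (default) or apply `delta` per direction.
#' @return A tibble with columns `direction`, `delta`, `tm`,
#'   `time_since_speciation` (`t1 - tm`), `p_e`, `p_o` and `ratio`.
#' @examples
#' grid <- pepo_grid(delta = c(0, 0.05), tm = c(0.25, 0.75))
#' grid
#' @export
pepo_grid <- function(t1 = 1, t2 = 3.5, theta = 0.002,
                      root_depth = default_root_depth,
                      delta = seq(0, 0.1, length.out = 101),
                      tm = seq(0.01, 0.99, length.out = 99),
                      direction = c("both", "CtoB", "BtoC"),
                      split_both = TRUE) {
  direction <- match.arg(direction, several.ok = TRUE)
  stopifnot(all(tm > 0), all(tm < t1), all(delta >= 0), all(delta <= 1))
  grids <- lapply(direction, function(dir) {
    g <- tidyr::expand_grid(delta = delta, tm = tm)
    d2 <- switch(dir, CtoB = g$delta, BtoC = 0,
                 both = if (split_both) g$delta / 2 else g$delta)
    d3 <- switch(dir, CtoB = 0, BtoC = g$delta,
                 both = if (split_both) g$delta / 2 else g$delta)
    res <- .pepo(t1, t2, g$tm, rep_len(d2, nrow(g)), rep_len(d3, nrow(g)),
                 theta, root_depth)
    tibble::tibble(direction = dir, delta = g$delta, tm = g$tm,
                   time_since_speciation = t1 - g$tm,
                   p_e = res$pe, p_o = res$po, ratio = res$pe / res$po)
  })
  dplyr::bind_rows(grids)
}

# .pepo vectorizes over tm/delta except that .pt_classes branches on scalar
# delta weights; make the weighted combination vector-safe:
#  - handled because prob entries are plain numeric vectors multiplied by
#    scalar or vector weights of compatible length.

#' Contour plot of a hemiplasy/homoplasy grid
#'
#' @param grid A tibble from [pepo_grid()].
#' @return A ggplot object (filled contours of the ratio, one facet per
#'   direction).
#' @export
plot_pepo_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$delta, y = .data$time_since_speciation, z = .data$ratio)) +
    ggplot2::geom_contour_filled() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "admixture proportion",
                  y = "time between speciation and introgression (2N gen)",
                  fill = expression(P[e] / P[o]))
}
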