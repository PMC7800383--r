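# subs2coal: convert a substitutions/site phylogeny with concordance-factor
# node labels into an ultrametric tree in coalescent units.
#
# Under the multispecies coalescent, the concordance factor of an internal
# branch of length T coalescent units has quartet expectation
# CF(T) = 1 - (2/3) exp(-T).  Inverting gives internal branch lengths in
# coalescent units; an OLS regression of those lengths on the same branches'
# substitutions/site lengths then predicts the tip branches, and the tree is
# smoothed to ultrametry.

#' Convert a concordance factor to an internal branch length
#'
#' Inverts `CF(T) = 1 - (2/3) exp(-T)`: `T = -log((3/2) (1 - cf))`,
#' with `T` in coalescent units (2N generations).
#'
#' @param cf Concordance factors, as fractions in (1/3, 1) or percentages in
#'   (33.3, 100); values greater than 1 are treated as percentages and
#'   divided by 100.  Values at or below 1/3 yield `NA` with a warning
#'   (star-tree or worse); values at or above 1 are clamped just below 1
#'   with a warning.
#' @return Branch lengths in coalescent units.
#' @examples
#' cf_to_coalescent_length(1 - 2 / (3 * exp(1))) # = 1 coalescent unit
#' @export
cf_to_coalescent_length <- function(cf) {
  cf <- as.numeric(cf)
  if (any(cf > 1, na.rm = TRUE)) {
    warning("concordance factors > 1 treated as percentages and divided ",
            "by 100")
    cf <- ifelse(cf > 1, cf / 100, cf)
  }
  if (any(cf >= 1, na.rm = TRUE)) {
    warning("concordance factors at 1 clamped to 1 - 1e-9")
    cf <- pmin(cf, 1 - 1e-9)
  }
  bad <- !is.na(cf) & cf <= 1 / 3
  if (any(bad))
    warning(sum(bad), " concordance factor(s) at or below 1/3 ",
            "(star-tree or worse) excluded")
  out <- rep(NA_real_, length(cf))
  ok <- !is.na(cf) & !bad
  out[ok] <- -log(1.5 * (1 - cf[ok]))
  out
}

#' Read a Newick tree whose node labels are concordance factors
#'
#' @param x A `phylo` object, a Newick string, or a path to a Newick file.
#' @return A `phylo` object with numeric node labels.
#' @export
read_cf_tree <- function(x) {
  tree <- if (inherits(x, "phylo")) x
  else if (grepl("\\(", x)) ape::read.tree(text = x)
  else ape::read.tree(x)
  if (is.null(tree$node.label))
    stop("tree has no node labels; concordance factors are required")
  tree
}

#' Fit the substitutions-to-coalescent-units conversion
#'
#' Ordinary least squares of internal branch lengths in coalescent units
#' (from [cf_to_coalescent_length()] of the node labels) on the same
#' branches' lengths in substitutions per site.  Branches without a usable
#' concordance factor, or with non-positive length, are excluded.
#'
#' @param tree A `phylo` with substitutions/site branch lengths and
#'   concordance-factor node labels (see [read_cf_tree()]).
#' @return An object of class `cf_conversion_fit`, with `tidy()` and
#'   `glance()` methods.
#' @export
fit_conversion <- function(tree) {
  tree <- read_cf_tree(tree)
  n_tip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > n_tip)
  nodes <- tree$edge[internal_edges, 2]
  cf_raw <- suppressWarnings(as.numeric(tree$node.label[nodes - n_tip]))
  subs <- tree$edge.length[internal_edges]
  Tcoal <- cf_to_coalescent_length(cf_raw)
  use <- !is.na(Tcoal) & !is.na(subs) & subs > 0
  pts <- tibble::tibble(node = nodes[use], subs = subs[use],
                        coal = Tcoal[use])
  if (nrow(pts) < 3)
    stop("need at least 3 internal branches with usable concordance ",
         "factors and positive lengths; got ", nrow(pts))
  if (stats::var(pts$subs) == 0)
    stop("zero variance in substitutions/site predictor")
  fit <- lm(coal ~ subs, data = pts)
  structure(
    list(lm = fit, points = pts,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$adj.r.squared, n_points = nrow(pts),
         excluded = sum(!use)),
    class = "cf_conversion_fit"
  )
}

#' @export
print.cf_conversion_fit <- function(x, ...) {
  cat(sprintf(
    "subs2coal conversion fit: y = %.4f + %.2f x (n = %d, adj R^2 = %.3f)\n",
    x$intercept, x$slope, x$n_points, x$r_squared))
  if (x$excluded > 0)
    cat(" ", x$excluded, "internal branch(es) excluded\n")
  invisible(x)
}

#' @rdname fit_conversion
#' @param x,... A `cf_conversion_fit` and unused arguments.
#' @export
tidy.cf_conversion_fit <- function(x, ...) {
  tibble::as_tibble(cbind(
    term = c("intercept", "slope"),
    as.data.frame(summary(x$lm)$coefficients, row.names = FALSE)
  ))[, 1:3] |>
    setNames(c("term", "estimate", "std.error"))
}

#' @rdname fit_conversion
#' @export
glance.cf_conversion_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 adj_r_squared = x$r_squared, n_points = x$n_points,
                 excluded = x$excluded)
}

#' Predict tip branch lengths in coalescent units
#'
#' Applies the conversion regression to the tip branches.  Tip branches
#' whose substitutions/site length falls outside the range of the internal
#' branches used in the fit require extrapolation and are flagged with a
#' warning.  Negative predictions are floored at a small positive value
#' with a warning.
#'
#' @param tree The `phylo` used for (or compatible with) the fit.
#' @param fit A [fit_conversion()] result.
#' @param bound `"point"` for the regression prediction, or `"lower95"` /
#'   `"upper95"` for the bounds of the 95% prediction interval.
#' @return A tibble with `tip`, `subs`, `coal` (chosen bound), `lower95`,
#'   `upper95`, `extrapolated`.
#' @export
predict_tips <- function(tree, fit, bound = c("point", "lower95",
                                              "upper95")) {
  bound <- match.arg(bound)
  stopifnot(inherits(fit, "cf_conversion_fit"))
  tree <- read_cf_tree(tree)
  n_tip <- length(tree$tip.label)
  tip_edges <- match(seq_len(n_tip), tree$edge[, 2])
  subs <- tree$edge.length[tip_edges]
  pr <- predict(fit$lm, newdata = data.frame(subs = subs),
                interval = "prediction", level = 0.95)
  extrap <- subs < min(fit$points$subs) | subs > max(fit$points$subs)
  if (any(extrap))
    warning(sum(extrap), " tip branch(es) outside the fitted internal-",
            "branch range; prediction requires extrapolation")
  out <- tibble::tibble(
    tip = tree$tip.label, subs = subs,
    coal = switch(bound, point = pr[, "fit"], lower95 = pr[, "lwr"],
                  upper95 = pr[, "upr"]),
    lower95 = pr[, "lwr"], upper95 = pr[, "upr"], extrapolated = extrap
  )
  if (any(out$coal <= 0)) {
    warning(sum(out$coal <= 0), " non-positive predicted tip length(s) ",
            "floored at 1e-6 coalescent units")
    out$coal <- pmax(out$coal, 1e-6)
  }
  out
}

# node ages (backward time) of a rooted tree with edge lengths
.node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Smooth a tree to ultrametry
#'
#' `"redistribute"` rescales node ages so that every root-to-tip path has
#' the same length, allocating each path's span evenly over its node count
#' (top-down: the edge from a node to a child spans
#' `age(node) / (levels(child) + 1)`, where `levels` is the maximum number
#' of edges from the child down to any tip).  `"extend"` lengthens each tip
#' branch by the difference between the maximum root-to-tip depth and its
#' own depth, preserving every internal branch length exactly.
#'
#' @param tree A rooted `phylo` with positive branch lengths.
#' @param method `"redistribute"` or `"extend"`.
#' @return An ultrametric `phylo`.
#' @examples
#' smooth_ultrametric(ape::read.tree(text = "((A:1,B:2):1,C:4);"), "extend")
#' @export
smooth_ultrametric <- function(tree, method = c("redistribute", "extend")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  if (method == "extend") {
    out <- tree
    tip_edges <- match(seq_len(n_tip), tree$edge[, 2])
    out$edge.length[tip_edges] <- out$edge.length[tip_edges] +
      max(depths[seq_len(n_tip)]) - depths[seq_len(n_tip)]
    return(out)
  }
  # redistribute: even spacing of levels along each path
  edge <- tree$edge
  nlev <- integer(n_tip + tree$Nnode) # max edges down to a tip
  po <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    nlev[po[e, 1]] <- max(nlev[po[e, 1]], nlev[po[e, 2]] + 1L)
  root <- n_tip + 1L
  age <- numeric(n_tip + tree$Nnode)
  age[root] <- max(depths[seq_len(n_tip)])
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  out <- tree
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]
    ch <- pre[e, 2]
    len <- age[p] / (nlev[ch] + 1L)
    age[ch] <- age[p] - len
    out$edge.length[which(edge[, 1] == p & edge[, 2] == ch)] <- len
  }
  out$edge.length[match(seq_len(n_tip), edge[, 2])] <-
    out$edge.length[match(seq_len(n_tip), edge[, 2])] +
    age[seq_len(n_tip)] # close any numerical remainder at the tips
  out
}

#' Convert a substitutions/site tree with concordance factors to
#' coalescent units
#'
#' The full `subs2coal` procedure: invert the concordance factors on
#' internal branches, regress coalescent lengths on substitutions/site
#' lengths, predict tip branches (optionally at a prediction-interval
#' bound), and smooth the resulting tree to ultrametry.  Optionally the
#' outgroup is excluded from smoothing and re-grafted afterwards at a depth
#' proportional to its original substitutions/site attachment (scaled by
#' the fitted slope).
#'
#' @param tree A `phylo`, Newick string or file path (see [read_cf_tree()]).
#' @param smoothing Smoothing method, see [smooth_ultrametric()].
#' @param tip_bound Which regression bound to use for tip predictions.
#' @param exclude_outgroup Optional outgroup tip label to re-graft after
#'   smoothing.
#' @return A list of class `subs2coal` with elements `tree` (ultrametric,
#'   coalescent units), `fit` (the [fit_conversion()] object) and `tips`
#'   (the [predict_tips()] table).
#' @export
subs2coal <- function(tree, smoothing = c("redistribute", "extend"),
                      tip_bound = c("point", "lower95", "upper95"),
                      exclude_outgroup = NULL) {
  smoothing <- match.arg(smoothing)
  tip_bound <- match.arg(tip_bound)
  tree <- read_cf_tree(tree)
  fit <- fit_conversion(tree)
  tips <- predict_tips(tree, fit, tip_bound)
  n_tip <- length(tree$tip.label)
  coal <- tree
  # internal branches: inverted CFs where usable, else regression prediction
  internal_edges <- which(tree$edge[, 2] > n_tip)
  nodes <- tree$edge[internal_edges, 2]
  Tcoal <- rep(NA_real_, length(nodes))
  m <- match(nodes, fit$points$node)
  Tcoal[!is.na(m)] <- fit$points$coal[m[!is.na(m)]]
  pred <- predict(fit$lm,
                  newdata = data.frame(subs = tree$edge.length[internal_edges]))
  Tcoal[is.na(Tcoal)] <- pmax(pred[is.na(Tcoal)], 1e-6)
  coal$edge.length[internal_edges] <- Tcoal
  coal$edge.length[match(seq_len(n_tip), tree$edge[, 2])] <- tips$coal
  if (!is.null(exclude_outgroup)) {
    if (!exclude_outgroup %in% coal$tip.label)
      stop("unknown outgroup: ", exclude_outgroup)
    og_subs <- tree$edge.length[match(match(exclude_outgroup,
                                            tree$tip.label),
                                      tree$edge[, 2])]
    ingroup <- ape::drop.tip(coal, exclude_outgroup)
    sm <- smooth_ultrametric(ingroup, smoothing)
    h <- max(ape::node.depth.edgelength(sm))
    og_len <- max(og_subs * fit$slope, h * 1.05)
    txt <- ape::write.tree(sm)
    merged <- ape::read.tree(text = sprintf(
      "(%s:%.10g,%s:%.10g);", sub(";$", "", txt), og_len - h,
      exclude_outgroup, og_len))
    out_tree <- merged
  } else {
    out_tree <- smooth_ultrametric(coal, smoothing)
  }
  structure(list(tree = out_tree, fit = fit, tips = tips,
                 smoothing = smoothing, tip_bound = tip_bound),
            class = "subs2coal")
}

#' @export
print.subs2coal <- function(x, ...) {
  print(x$fit)
  cat("smoothing:", x$smoothing, "; tip bound:", x$tip_bound, "\n")
  cat("converted tree height:",
      format(max(ape::node.depth.edgelength(x$tree))),
      "coalescent units\n")
  invisible(x)
}

#' Generate a concordance-factor fixture from a known coalescent tree
#'
#' Builds a substitutions/site tree whose internal-branch concordance
#' factors encode the true coalescent lengths through `CF(T)`, with
#' substitutions/site lengths generated as
#' `subs = (coal - intercept) / slope` plus optional Gaussian noise.  Used
#' to exercise the conversion end to end without external tree inference.
#'
#' @param tree An ultrametric `phylo` in coalescent units.
#' @param slope,intercept The linear map from substitutions/site to
#'   coalescent units to emulate.
#' @param noise_sd Standard deviation of Gaussian noise added to the
#'   substitutions/site lengths (0 for an exact linear fixture).
#' @param seed Optional seed.
#' @return A `phylo` with substitutions/site lengths and CF node labels.
#' @export
make_cf_fixture <- function(tree, slope = 150, intercept = 0.3,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  out <- tree
  subs <- (tree$edge.length - intercept) / slope
  if (noise_sd > 0) subs <- subs + stats::rnorm(length(subs), 0, noise_sd)
  out$edge.length <- pmax(subs, 1e-8)
  labs <- rep("", tree$Nnode)
  internal_edges <- which(tree$edge[, 2] > n_tip)
  for (e in internal_edges) {
    node <- tree$edge[e, 2]
    labs[node - n_tip] <- format(1 - (2 / 3) * exp(-tree$edge.length[e]),
                                 digits = 10)
  }
  out$node.label <- labs
  out
}
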