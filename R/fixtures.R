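# Synthetic stand-ins for the two empirical case studies, plus the plain-
# text input dialect.  The stand-in trees are constructed, not estimated
# from data: they mirror the published structure (taxon counts, derived-
# state distributions, parsimony scores, pulse probabilities) so the
# pipeline can be exercised end to end without any downloads.

#' Synthetic 15-taxon skink tree
#'
#' A constructed stand-in for the green-blooded-lizard analysis: 15 taxa in
#' coalescent units with six derived (green-blooded) tips distributed so
#' that Fitch parsimony requires four independent transitions on the
#' species tree, plus an outgroup.  Internal branches inside the focal
#' clade are short, so discordance is extensive.  The derived taxa fall
#' into two natural groups (four and two tips), mirroring the subclade
#' structure reported for the empirical system.
#'
#' @param internal Internal branch length inside the focal clade
#'   (coalescent units).
#' @param tip Age of the shallowest cherries (coalescent units).
#' @param stem Stem length separating the focal clade from the outgroup.
#' @return A [species_network()] with attributes `derived_taxa`, `rate`
#'   and `outgroup`.
#' @export
synthetic_lizard_network <- function(internal = 0.005, tip = 0.05,
                                     stem = 1.0) {
  # greens: g1..g6; reds: r1..r8; outgroup Scincella_lateralis
  # pattern on the species tree: (g1,g2) | g3 | g4 | (g5,g6) separated by
  # red lineages -> Fitch = 4.  Internal branches inside the focal clade
  # are a two-hundredth of a coalescent unit, approaching the star-tree
  # discordance the empirical clade's concordance factors indicate.
  ib <- internal
  a1 <- tip
  A <- sprintf("((g1:%g,g2:%g):%g,r1:%g)", a1, a1, ib, a1 + ib)
  B <- sprintf("(g3:%g,r2:%g)", a1 + ib, a1 + ib)
  AB <- sprintf("(%s:%g,%s:%g)", A, ib, B, ib)
  C <- sprintf("(g4:%g,r3:%g)", a1 + 2 * ib, a1 + 2 * ib)
  D <- sprintf("(r4:%g,r5:%g)", a1 + 2 * ib, a1 + 2 * ib)
  CD <- sprintf("(%s:%g,%s:%g)", C, ib, D, ib)
  ABCD <- sprintf("(%s:%g,%s:%g)", AB, 2 * ib, CD, ib)
  E <- sprintf("((g5:%g,g6:%g):%g,r6:%g)", a1, a1, ib, a1 + ib)
  Fc <- sprintf("(r7:%g,r8:%g)", a1 + ib, a1 + ib)
  EF <- sprintf("(%s:%g,%s:%g)", E, ib, Fc, ib)
  ing <- sprintf("(%s:%g,%s:%g)", ABCD, ib, EF, 3 * ib)
  h <- a1 + 5 * ib
  nwk <- sprintf("(%s:%g,Scincella_lateralis:%g);", ing, stem, h + stem)
  net <- species_network(nwk, outgroup = "Scincella_lateralis")
  attr(net, "derived_taxa") <- paste0("g", 1:6)
  attr(net, "rate") <- 0.03
  net
}

#' Synthetic Heliconius-like network
#'
#' A constructed stand-in for the butterfly-inversion analysis: seven taxa
#' with the derived chromosomal arrangement carried by four taxa in two
#' separate clades (Fitch parsimony: two origins), and two introgression
#' pulses between the lineages sharing the derived state with total
#' probability 0.201, mirroring the published input's pulse total.
#'
#' @return A [species_network()] with attributes `derived_taxa` and
#'   `outgroup`.
#' @export
synthetic_heliconius_network <- function() {
  nwk <- paste0(
    "((((inv1:0.50,inv2:0.50):0.10,(anc1:0.55,anc2:0.55):0.05):0.80,",
    "(inv3:0.60,inv4:0.60):0.80):1.75,out:3.15);")
  pulses <- tibble::tibble(
    donor = c("inv1", "inv3"), recipient = c("inv3", "inv2"),
    time = c(0.30, 0.15), probability = c(0.110, 0.091)
  )
  net <- species_network(nwk, pulses = pulses, outgroup = "out")
  attr(net, "derived_taxa") <- c("inv1", "inv2", "inv3", "inv4")
  attr(net, "rate") <- 5e-3
  net
}

#' Read a pipeline input file
#'
#' The plain-text dialect: one `tree` line with a rooted ultrametric Newick
#' string in coalescent units, optional `introgression <donor> <recipient>
#' <time> <probability>` lines, one `derived <taxon> [<taxon> ...]` line,
#' optional `outgroup <taxon>` and `rate <value>` lines.  Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path Path to the input file.
#' @return A list with `network` (a [species_network()]), `derived_taxa`,
#'   `outgroup` and `rate` (or `NULL` where absent).
#' @examples
#' inp <- read_pipeline_input(system.file("extdata",
#'   "heliconius_synthetic.input", package = "hemicoal"))
#' inp$network
#' @export
read_pipeline_input <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^", key, "\\s*=?\\s*"), "", hit[1]))
  }
  tree_txt <- get1("tree")
  if (is.null(tree_txt)) {
    nwk <- grep("^\\(.*;\\s*$", lines, value = TRUE)
    if (length(nwk) == 0) stop("no tree found in ", path)
    tree_txt <- nwk[1]
  }
  intro <- grep("^introgression\\b", lines, value = TRUE)
  pulses <- NULL
  if (length(intro) > 0) {
    parts <- strsplit(sub("^introgression\\s+", "", intro), "\\s+")
    pulses <- tibble::tibble(
      donor = vapply(parts, `[`, "", 1),
      recipient = vapply(parts, `[`, "", 2),
      time = as.numeric(vapply(parts, `[`, "", 3)),
      probability = as.numeric(vapply(parts, `[`, "", 4))
    )
  }
  derived <- get1("derived")
  if (is.null(derived)) stop("no 'derived' line in ", path)
  derived <- strsplit(derived, "[, \t]+")[[1]]
  outgroup <- get1("outgroup")
  rate <- get1("rate")
  net <- species_network(tree_txt, pulses = pulses, outgroup = outgroup)
  list(network = net, derived_taxa = derived, outgroup = outgroup,
       rate = if (is.null(rate)) NULL else as.numeric(rate))
}

#' Write a pipeline input file
#'
#' @param network A [species_network()].
#' @param derived_taxa Derived tip labels.
#' @param path Output path.
#' @param rate Optional mutation rate line.
#' @return `path`, invisibly.
#' @export
write_pipeline_input <- function(network, derived_taxa, path,
                                 rate = NULL) {
  lines <- c(
    paste0("tree ", ape::write.tree(network$tree)),
    if (!is.null(network$pulses))
      sprintf("introgression %s %s %g %g", network$pulses$donor,
              network$pulses$recipient, network$pulses$time,
              network$pulses$probability),
    paste("derived", paste(derived_taxa, collapse = " ")),
    if (!is.null(network$outgroup)) paste("outgroup", network$outgroup),
    if (!is.null(rate)) paste("rate", rate)
  )
  writeLines(lines, path)
  invisible(path)
}
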