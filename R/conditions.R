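# Benchmark conditions: a four-taxon tree (((4,3),2),1) with derived taxa
# t4 and t2, increasing expected hemiplasy across conditions.
#
# Times are stated in N generations in the condition definitions and
# converted once to coalescent units (2N generations) at construction
# (divide by 2).  The root (split of t1) sits at 8N = 4 coalescent units for
# every condition; the age of the 2-vs-(3,4) split is fixed at 1.75
# coalescent units (a design-time calibration that keeps the frequency of
# the hemiplasy-capable {4,2} gene-tree topology as close to constant as
# the CGF parameter sets allow); the (4,3) split age is that value minus
# the condition's internal branch length.

.benchmark_root_cu <- 4.0
.benchmark_a2_cu <- 1.75

.condition_table <- tibble::tibble(
  name = c("ILS1", "ILS2", "ILS3",
           "INT1", "INT2", "INT3", "INT4", "INT5", "INT6",
           "CGF1", "CGF2", "CGF3", "CGF4", "CGF5"),
  internal_n = c(2, 1.5, 1, rep(1, 6), 2, 2.08, 2.32, 2.6, 2.8),
  delta = c(0, 0, 0, 0.01, 0.05, 0.1, 0.1, 0.1, 0.1,
            0, 0.01, 0.025, 0.04, 0.05),
  tm_n = c(NA, NA, NA, 0.6, 0.6, 0.6, 0.4, 0.2, 0.1,
           NA, 0.4, 0.3, 0.2, 0.1)
)

#' Benchmark simulation conditions
#'
#' Returns the fully parameterized benchmark condition: the four-taxon tree
#' `(((t4,t3),t2),t1)` in coalescent units with derived taxa `t4` and `t2`
#' and outgroup `t1`, plus the condition's introgression pulse (from `t2`
#' into `t4`), if any.  `ILS1`-`ILS3` shorten the internal branch
#' subtending `t4` and `t3` (2N, 1.5N, N generations) with no introgression;
#' `INT1`-`INT3` add introgression at 0.6N generations with probability
#' 0.01, 0.05, 0.1; `INT4`-`INT6` hold the probability at 0.1 and make the
#' pulse more recent (0.4N, 0.2N, 0.1N); `CGF1`-`CGF5` increase the pulse
#' probability and recency while lengthening the internal branch so the
#' frequency of the discordant topology grouping the derived taxa stays
#' approximately constant (`CGF1` equals `ILS1`).
#'
#' @param name One of `"ILS1"`-`"ILS3"`, `"INT1"`-`"INT6"`,
#'   `"CGF1"`-`"CGF5"`, or `"TEST8"` (an eight-taxon introgression-free
#'   tree with three incongruent derived taxa, used for the tree-estimation
#'   round-trip checks).
#' @param rate Trait mutation rate per 2N generations.
#' @return A list of class `benchmark_condition` with elements `name`,
#'   `network` (a [species_network()]), `derived_taxa`, `outgroup`, `rate`
#'   and the raw parameters (in both N and 2N generations).
#' @examples
#' make_condition("ILS3")
#' @export
make_condition <- function(name, rate = 0.05) {
  if (name == "TEST8") {
    nwk <- paste0(
      "(((((t1:0.4,t2:0.4):0.4,t3:0.8):0.6,(t4:0.9,t5:0.9):0.5):0.8,",
      "(t6:1.2,t7:1.2):1.0):1.8,t8:4.0);")
    net <- species_network(nwk, outgroup = "t8")
    return(structure(list(name = name, network = net,
                          derived_taxa = c("t2", "t3", "t5"),
                          outgroup = "t8", rate = rate),
                     class = "benchmark_condition"))
  }
  row <- .condition_table[.condition_table$name == name, ]
  if (nrow(row) != 1)
    stop("unknown benchmark condition: ", name)
  internal_cu <- row$internal_n / 2
  a3 <- .benchmark_a2_cu - internal_cu
  stopifnot(a3 > 0)
  nwk <- sprintf("(((t4:%.6f,t3:%.6f):%.6f,t2:%.6f):%.6f,t1:%.6f);",
                 a3, a3, internal_cu, .benchmark_a2_cu,
                 .benchmark_root_cu - .benchmark_a2_cu, .benchmark_root_cu)
  pulses <- NULL
  if (!is.na(row$tm_n) && row$delta > 0) {
    pulses <- tibble::tibble(donor = "t2", recipient = "t4",
                             time = row$tm_n / 2,
                             probability = row$delta)
  }
  net <- species_network(nwk, pulses = pulses, outgroup = "t1")
  structure(
    list(name = name, network = net, derived_taxa = c("t4", "t2"),
         outgroup = "t1", rate = rate,
         internal_n = row$internal_n, internal_cu = internal_cu,
         delta = row$delta, tm_n = row$tm_n, tm_cu = row$tm_n / 2),
    class = "benchmark_condition"
  )
}

#' @export
print.benchmark_condition <- function(x, ...) {
  cat("Benchmark condition", x$name, "\n")
  print(x$network)
  cat("derived:", paste(x$derived_taxa, collapse = ", "),
      "| rate:", x$rate, "per 2N generations\n")
  invisible(x)
}

#' Replicate a benchmark condition
#'
#' Runs the full pipeline `n_replicates` times (seeds spawned from the
#' master seed and recorded in the output) and reports the per-replicate
#' hemiplasy and homoplasy summaries in the standard schema: `hemi_count`
#' (focal trees with a single mutation), `homo_count` (two mutations),
#' the conditional probabilities `cond_hemi`/`cond_homo`, the raw
#' probabilities out of all simulated trees, and their ratio `pepo`.
#'
#' @param condition A [make_condition()] result (or a condition name).
#' @param n_replicates Number of replicate runs.
#' @param n_trees Gene trees per replicate.
#' @param rate Optional override of the condition's mutation rate.
#' @param seed Master seed.
#' @param prune Passed to [run_hemiplasy()]; the four-taxon benchmark trees
#'   are already minimal, so pruning is a no-op there.
#' @return A tibble with one row per replicate.
#' @export
replicate_benchmark <- function(condition, n_replicates = 10,
                                n_trees = 1e5, rate = NULL, seed = 1,
                                prune = FALSE) {
  if (is.character(condition)) condition <- make_condition(condition)
  stopifnot(inherits(condition, "benchmark_condition"))
  if (is.null(rate)) rate <- condition$rate
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  purrr::map_dfr(seq_len(n_replicates), function(i) {
    fit <- run_hemiplasy(condition$network, condition$derived_taxa,
                         rate = rate, n_trees = n_trees, seed = seeds[i],
                         outgroup = condition$outgroup, prune = prune)
    g <- glance(fit)
    tibble::tibble(
      condition = condition$name, replicate = i, seed = seeds[i],
      n_trees = n_trees, rate = rate,
      hemi_count = g$hemi_count, homo_count = g$homo_count,
      cond_hemi = g$cond_hemi, raw_hemi = g$raw_hemi,
      cond_homo = g$cond_homo, raw_homo = g$raw_homo, pepo = g$pepo
    )
  })
}

#' Frequency of the discordant topology grouping the derived taxa
#'
#' Simulates gene trees (without a trait) and returns the fraction in which
#' the derived taxa form a single clade, the quantity the constant-frequency
#' (`CGF`) conditions are designed to hold fixed.
#'
#' @param condition A [make_condition()] result or name.
#' @param n_trees Number of gene trees.
#' @param seed Seed.
#' @return A one-row tibble with `condition`, `n_trees`, `count`,
#'   `frequency`.
#' @export
discordant_topology_frequency <- function(condition, n_trees = 1e5,
                                          seed = 1) {
  if (is.character(condition)) condition <- make_condition(condition)
  set.seed(seed)
  res <- .msnc_call(condition$network, n_trees, mut_rate = 0,
                    want_topologies = TRUE, want_focal = FALSE)
  counts <- res$topology_counts
  tree <- condition$network$tree
  idx <- match(condition$derived_taxa, tree$tip.label)
  # canonical strings use tip positions (t<i>), children sorted
  # lexicographically; a clade of two derived taxa is a cherry
  pat <- paste0("(", paste(sort(paste0("t", idx)), collapse = ","), ")")
  hit <- sum(counts[grepl(pat, names(counts), fixed = TRUE)])
  tibble::tibble(condition = condition$name, n_trees = n_trees,
                 count = hit, frequency = hit / n_trees)
}
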