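test_that("three-taxon topology frequencies match the analytic classes", {
  net3 <- three_taxon_network(1, 3.5, tm = 0.4, delta2 = 0.07,
                              delta3 = 0.03, theta = 0.002)
  snet <- species_network(
    "((A:1,B:1):2.5,C:3.5);",
    pulses = tibble::tibble(donor = c("C", "B"), recipient = c("B", "C"),
                            time = 0.4, probability = c(0.07, 0.03))
  )
  cls <- gene_tree_classes(net3)
  expected <- vapply(c("AB", "AC", "BC"), function(s)
    sum(cls$probability[cls$sister == s]), numeric(1))
  set.seed(42)
  n <- 1e5
  res <- hemicoal:::.msnc_call(snet, n, want_topologies = TRUE,
                               want_focal = FALSE)
  counts <- res$topology_counts
  obs <- c(AB = sum(counts[grepl("(t1,t2)", names(counts), fixed = TRUE)]),
           AC = sum(counts[grepl("(t1,t3)", names(counts), fixed = TRUE)]),
           BC = sum(counts[grepl("(t2,t3)", names(counts), fixed = TRUE)]))
  expect_equal(sum(obs), n)
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("pairwise coalescence time has the right expectation", {
  net <- species_network("(A:2,B:2);")
  sims <- simulate_gene_trees(net, 5000, seed = 7)
  heights <- vapply(as_multiphylo(sims), function(tr)
    max(ape::node.depth.edgelength(tr)), numeric(1))
  # split at t = 2, plus Exp(1) waiting time above it
  expect_lt(abs(mean(heights) - 3), 3 * 1 / sqrt(5000))
})

test_that("pulse probability sets the introgressed-locus fraction", {
  net <- species_network(
    "((A:1,B:1):2.5,C:3.5);",
    pulses = tibble::tibble(donor = "C", recipient = "B", time = 0.5,
                            probability = 0.1)
  )
  sims <- simulate_gene_trees(net, 2e4, seed = 3)
  frac <- mean(sims$origin != "species")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 2e4))
})

test_that("a certain pulse forces the introgressed topology frequency", {
  # delta = 1 just below t1: every locus follows the C->B parent tree, so
  # P(B,C sister) = 1 - (2/3) exp(-(t2 - tm))
  snet <- species_network(
    "((A:1,B:1):2.5,C:3.5);",
    pulses = tibble::tibble(donor = "C", recipient = "B", time = 0.95,
                            probability = 1)
  )
  set.seed(5)
  n <- 4e4
  res <- hemicoal:::.msnc_call(snet, n, want_topologies = TRUE,
                               want_focal = FALSE)
  counts <- res$topology_counts
  bc <- sum(counts[grepl("(t2,t3)", names(counts), fixed = TRUE)]) / n
  p <- 1 - (2 / 3) * exp(-(3.5 - 0.95))
  expect_lt(abs(bc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the gene-tree stream is deterministic given a seed", {
  net <- species_network(
    "((A:1,B:1):2.5,C:3.5);",
    pulses = tibble::tibble(donor = "C", recipient = "B", time = 0.5,
                            probability = 0.2)
  )
  s1 <- simulate_gene_trees(net, 50, seed = 99)
  s2 <- simulate_gene_trees(net, 50, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_gene_trees(net, 50, seed = 100)
  expect_false(identical(s1$newick, s3$newick))
})

test_that("simulated gene trees are ultrametric with the full tip set", {
  net <- species_network(
    "(((t1:0.4,t2:0.4):0.6,t3:1):2,(t4:1.5,t5:1.5):1.5);",
    pulses = tibble::tibble(donor = "t3", recipient = "t1", time = 0.2,
                            probability = 0.3)
  )
  trees <- as_multiphylo(simulate_gene_trees(net, 200, seed = 1))
  expect_true(all(vapply(trees, function(tr) {
    ape::is.ultrametric(tr, tol = 1e-7) &&
      setequal(tr$tip.label, net$tree$tip.label)
  }, logical(1))))
})

test_that("species networks validate their inputs", {
  expect_error(species_network("((A:1,B:2):1,C:3);"), "ultrametric")
  expect_error(
    species_network("((A:1,B:1):2.5,C:3.5);",
                    pulses = tibble::tibble(donor = "A", recipient = "B",
                                            time = 2, probability = 0.1)),
    "already merged")
  expect_error(
    species_network("((A:1,B:1):2.5,C:3.5);",
                    pulses = tibble::tibble(donor = "C", recipient = "B",
                                            time = 0.5, probability = 1.5)),
    "probabilities")
})

test_that("pruning keeps the minimal derived clade plus the outgroup", {
  nwk <- paste0("((((t1:0.5,t2:0.5):0.5,(t3:0.7,t4:0.7):0.3):1,",
                "(t5:1.2,t6:1.2):0.8):1,(t7:2.2,t8:2.2):0.8);")
  net <- species_network(nwk)
  pr <- prune_to_focal_clade(net, c("t2", "t4"), "t7")
  expect_setequal(pr$tree$tip.label, c("t1", "t2", "t3", "t4", "t7"))
  # outgroup still attaches at its original divergence time (the root)
  expect_equal(max(pr$ages), 3, tolerance = 1e-9)
  expect_error(prune_to_focal_clade(net, c("t2", "t4"), "t1"),
               "inside the minimal clade")
  # derived = everything but the outgroup: tree unchanged
  all_d <- paste0("t", 1:6)
  pr2 <- prune_to_focal_clade(net, all_d, "t8")
  expect_setequal(pr2$tree$tip.label, c(all_d, "t8"))
  # pulses outside the retained taxa are dropped with a warning
  net2 <- species_network(
    nwk, pulses = tibble::tibble(donor = "t5", recipient = "t1",
                                 time = 0.4, probability = 0.1))
  expect_warning(prune_to_focal_clade(net2, c("t2", "t4"), "t7"),
                 "dropped")
})
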