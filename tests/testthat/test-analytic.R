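test_that("network constructor enforces the model invariants", {
  expect_error(three_taxon_network(1, 0.5, theta = 0.002), "t1 < t2")
  expect_error(three_taxon_network(1, 3.5, tm = 1.2, theta = 0.002),
               "tm < t1")
  expect_error(three_taxon_network(1, 3.5, tm = 0.5, delta2 = 0.6,
                                   delta3 = 0.6, theta = 0.002),
               "delta2")
  expect_error(three_taxon_network(1, 3.5, theta = -1), "theta")
  expect_error(three_taxon_network(1, 3.5, delta2 = 0.1, theta = 0.002),
               "tm required")
})

test_that("parent-tree probabilities are the admixture complements", {
  p <- function(...) parent_tree_probabilities(
    three_taxon_network(1, 3.5, tm = 0.5, theta = 0.002, ...))$probability
  expect_equal(p(), c(1, 0, 0))
  expect_equal(p(delta2 = 0.05), c(0.95, 0.05, 0))
  expect_equal(p(delta2 = 0.03, delta3 = 0.02), c(0.95, 0.03, 0.02))
})

test_that("gene-tree class probabilities follow the coalescent", {
  net <- three_taxon_network(1, 3.5, theta = 0.002)
  cls <- gene_tree_classes(net)
  expect_equal(nrow(cls), 12)
  # ILS class of parent tree 1 with B,C sister
  expect_equal(cls$probability[cls$class == "BC_1"], exp(-2.5) / 3)
  # lineage sorting in parent tree 1
  expect_equal(cls$probability[cls$class == "AB1_1"], 1 - exp(-2.5))
  # long internal branch: concordance -> 1
  wide <- gene_tree_classes(three_taxon_network(1, 12, theta = 0.002))
  expect_lt(wide$probability[wide$class == "BC_1"], 1e-4)
  expect_gt(wide$probability[wide$class == "AB1_1"], 1 - 1e-4)
})

test_that("class probabilities normalize within and across parent trees", {
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- runif(1, 0.5, 2)
    net <- three_taxon_network(
      t1 = t1, t2 = t1 + runif(1, 0.5, 3), tm = runif(1, 0.05, t1 * 0.9),
      delta2 = runif(1, 0, 0.3), delta3 = runif(1, 0, 0.3),
      theta = runif(1, 1e-4, 0.01)
    )
    cls <- gene_tree_classes(net)
    expect_true(all(cls$probability >= 0 & cls$probability <= 1))
    expect_equal(sum(cls$probability), 1, tolerance = 1e-12)
    w <- parent_tree_probabilities(net)$probability
    for (pt in 1:3) {
      if (w[pt] == 0) next
      expect_equal(sum(cls$probability[cls$parent_tree == pt]) / w[pt], 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("branch mutation probabilities behave like Poisson hit rates", {
  net <- function(theta) three_taxon_network(1, 3.5, tm = 0.5,
                                             delta2 = 0.05, theta = theta)
  lo <- gene_tree_classes(net(1e-8))
  nu_cols <- paste0("nu_lambda", 1:5)
  expect_true(all(as.matrix(lo[, nu_cols]) < 1e-7))
  mid <- gene_tree_classes(net(0.002))
  hi <- gene_tree_classes(net(0.02))
  expect_true(all(as.matrix(hi[, nu_cols]) > as.matrix(mid[, nu_cols])))
  expect_true(all(as.matrix(hi[, nu_cols]) >= 0 &
                    as.matrix(hi[, nu_cols]) < 1))
  # same coalescence bounds, same internal-branch mutation probability
  m <- net(0.002)
  expect_equal(branch_mutation_profile(m, "BC2_2")[["lambda4"]],
               branch_mutation_profile(m, "BC_1")[["lambda4"]])
  # lineage sorting in parent tree 2 gives the longer internal branch
  expect_gt(branch_mutation_profile(m, "BC1_2")[["lambda4"]],
            branch_mutation_profile(m, "BC2_2")[["lambda4"]])
  expect_error(branch_mutation_profile(m, "XY_9"), "unknown")
})

test_that("internal-branch mutation probability matches a Monte-Carlo
           draw of the coalescent branch length", {
  # ILS internal branch is the second coalescent interval: Exp(1)
  net <- three_taxon_network(1, 3.5, theta = 0.02)
  set.seed(11)
  len <- rexp(2e5)
  mc <- mean(rpois(2e5, (net$theta / 2) * len) > 0)
  ana <- branch_mutation_profile(net, "BC_1")[["lambda4"]]
  expect_lt(abs(mc - ana), 3 * sqrt(mc * (1 - mc) / 2e5))
})

test_that("hemiplasy probability reduces to the ILS-only expression", {
  net <- three_taxon_network(1, 3.5, theta = 0.002)
  cls <- gene_tree_classes(net)
  bc <- cls[cls$class == "BC_1", ]
  eq1 <- bc$probability * bc$nu_lambda4 * (1 - bc$nu_lambda1) *
    (1 - bc$nu_lambda2) * (1 - bc$nu_lambda3) * (1 - bc$nu_lambda5)
  expect_equal(prob_hemiplasy(net), eq1, tolerance = 1e-14)
  # theta -> 0 kills both probabilities
  tiny <- three_taxon_network(1, 3.5, theta = 1e-12)
  expect_lt(prob_hemiplasy(tiny), 1e-12)
  expect_lt(prob_homoplasy(tiny), 1e-18)
})

test_that("analytic values are stable (frozen regression values)", {
  # frozen from the closed forms at first implementation; guards refactors
  net <- three_taxon_network(1, 3.5, tm = 0.5, delta2 = 0.05,
                             theta = 0.002)
  expect_equal(prob_hemiplasy(net), 1.72963413e-04, tolerance = 1e-6)
  expect_equal(prob_homoplasy(net), 3.38444910e-05, tolerance = 1e-6)
})

test_that("introgression increases hemiplasy risk monotonically", {
  ratio <- function(d2, d3 = 0, tm = 0.5)
    pepo_ratio(three_taxon_network(1, 3.5, tm = tm, delta2 = d2,
                                   delta3 = d3, theta = 0.002))
  r <- vapply(seq(0, 0.1, by = 0.02), ratio, numeric(1))
  expect_true(all(diff(r) > 0))
  # more recent pulse (smaller tm) -> higher ratio, either direction
  r_tm <- vapply(seq(0.9, 0.1, by = -0.2), function(tm)
    ratio(0.05, tm = tm), numeric(1))
  expect_true(all(diff(r_tm) > 0))
  r_tm3 <- vapply(seq(0.9, 0.1, by = -0.2), function(tm)
    ratio(0, d3 = 0.05, tm = tm), numeric(1))
  expect_true(all(diff(r_tm3) > 0))
  # C->B introgression dominates B->C everywhere on the grid
  g <- pepo_grid(delta = c(0.02, 0.05, 0.1), tm = c(0.2, 0.5, 0.8),
                 direction = c("CtoB", "BtoC"))
  cb <- g[g$direction == "CtoB", ]
  bc <- g[g$direction == "BtoC", ]
  expect_true(all(cb$ratio >= bc$ratio))
})

test_that("parent tree 2 always raises the hemiplasy probability", {
  # Pe[BC1_2] + Pe[BC2_2] > Pe[BC_1] whenever t2 > tm
  for (seed in 1:10) {
    set.seed(seed)
    t1 <- runif(1, 0.5, 2)
    net <- three_taxon_network(
      t1 = t1, t2 = t1 + runif(1, 0.2, 3), tm = runif(1, 0.02, t1 * 0.95),
      delta2 = 1e-9, theta = runif(1, 1e-4, 0.05)
    )
    cls <- gene_tree_classes(net)
    term <- function(row) row$probability * row$nu_lambda4 *
      (1 - row$nu_lambda1) * (1 - row$nu_lambda2) *
      (1 - row$nu_lambda3) * (1 - row$nu_lambda5)
    pe_pt2 <- (term(cls[cls$class == "BC1_2", ]) +
                 term(cls[cls$class == "BC2_2", ])) / net$delta2
    pe_bc1 <- term(cls[cls$class == "BC_1", ]) /
      (1 - net$delta2)
    expect_gt(pe_pt2, pe_bc1)
  }
})

test_that("the ratio grid is flat in tm at zero admixture", {
  g <- pepo_grid(delta = 0, tm = seq(0.1, 0.9, by = 0.2),
                 direction = "CtoB")
  expect_equal(max(g$ratio) - min(g$ratio), 0, tolerance = 1e-12)
})
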