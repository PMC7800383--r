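test_that("concordance-factor inversion round-trips exactly", {
  # CF values near 1 carry limited precision in double arithmetic: an
  # interval of 1e-12 around T is resolvable in the stored CF only up to
  # T ~ 8 (beyond that, 1 - cf itself underflows the tolerance)
  T <- seq(0.01, 8, length.out = 101)
  cf <- 1 - (2 / 3) * exp(-T)
  expect_equal(cf_to_coalescent_length(cf), T, tolerance = 1e-12)
  T2 <- seq(8, 20, length.out = 25)
  expect_equal(cf_to_coalescent_length(1 - (2 / 3) * exp(-T2)), T2,
               tolerance = 1e-6)
  expect_equal(cf_to_coalescent_length(1 - 2 / (3 * exp(1))), 1,
               tolerance = 1e-12)
  expect_equal(cf_to_coalescent_length(0.90), -log(0.15),
               tolerance = 1e-12)
  # the star-tree limit: cf -> 1/3 gives T -> 0
  expect_equal(cf_to_coalescent_length(1 / 3 + 1e-12), 0,
               tolerance = 1e-9)
})

test_that("degenerate concordance factors are excluded or clamped", {
  expect_warning(out <- cf_to_coalescent_length(c(0.2, 0.9)),
                 "excluded")
  expect_true(is.na(out[1]))
  expect_warning(cf_to_coalescent_length(c(0.5, 1)), "clamped")
  expect_warning(out2 <- cf_to_coalescent_length(c(90, 50)),
                 "percentages")
  expect_equal(out2[2], cf_to_coalescent_length(0.5))
})

test_that("an exact linear fixture is recovered to machine precision", {
  true <- deep_ultrametric()
  fx <- make_cf_fixture(true, slope = 150, intercept = 0.3, noise_sd = 0)
  fit <- fit_conversion(fx)
  expect_equal(fit$slope, 150, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  g <- glance(fit)
  expect_gte(g$n_points, 3)
  td <- tidy(fit)
  expect_equal(td$estimate, c(0.3, 150), tolerance = 1e-8)
})

test_that("tip predictions fall inside the prediction interval as often
           as advertised", {
  set.seed(9)
  cover <- replicate(120, {
    true <- random_ultrametric(10)
    fx <- make_cf_fixture(true, slope = 120, intercept = 0.002,
                          noise_sd = 2e-4)
    fit <- fit_conversion(fx)
    tips <- suppressWarnings(predict_tips(fx, fit))
    n_tip <- length(true$tip.label)
    truth <- true$edge.length[match(seq_len(n_tip), true$edge[, 2])]
    mean(truth >= tips$lower95 & truth <= tips$upper95)
  })
  expect_gt(mean(cover), 0.90)
})

test_that("regression requirements are enforced", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)0.9:0.1,C:0.2);")
  expect_error(fit_conversion(tr), "at least 3")
  tr2 <- random_ultrametric(6, 1)
  fx <- make_cf_fixture(tr2, slope = 100, intercept = 0)
  fx$edge.length[fx$edge[, 2] > length(fx$tip.label)] <- 0.01
  expect_error(fit_conversion(fx), "zero variance")
})

test_that("extrapolated tip branches are flagged", {
  true <- random_ultrametric(8, seed = 12)
  n_tip <- length(true$tip.label)
  long <- true
  tip_edges <- match(seq_len(n_tip), true$edge[, 2])
  long$edge.length[tip_edges[1]] <- 50 # way beyond the internal range
  fx <- make_cf_fixture(long, slope = 150, intercept = 0.001)
  fit <- fit_conversion(fx)
  expect_warning(tips <- predict_tips(fx, fit), "extrapolation")
  expect_true(tips$extrapolated[1])
})

test_that("both smoothing methods return ultrametric trees", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::rtree(7) # non-ultrametric
    for (m in c("redistribute", "extend")) {
      sm <- smooth_ultrametric(tr, m)
      expect_true(ape::is.ultrametric(sm, tol = 1e-9))
    }
  }
})

test_that("'extend' preserves internal branch lengths exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
  sm <- smooth_ultrametric(tr, "extend")
  n_tip <- 3
  internal <- which(sm$edge[, 2] > n_tip)
  expect_equal(sm$edge.length[internal], tr$edge.length[internal])
  lenA <- sm$edge.length[match(match("A", sm$tip.label), sm$edge[, 2])]
  expect_equal(lenA, 3)
  for (seed in 1:10) {
    set.seed(seed)
    rt <- ape::rtree(9)
    sm2 <- smooth_ultrametric(rt, "extend")
    int2 <- which(rt$edge[, 2] > 9)
    expect_equal(sm2$edge.length[int2], rt$edge.length[int2])
  }
})

test_that("an evenly spaced ultrametric tree is a fixed point of both
           smoothing methods", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  for (m in c("redistribute", "extend"))
    expect_equal(smooth_ultrametric(tr, m)$edge.length, tr$edge.length,
                 tolerance = 1e-12)
})

test_that("subs2coal produces an ultrametric coalescent-unit tree", {
  true <- random_ultrametric(8, seed = 6)
  fx <- make_cf_fixture(true, slope = 150, intercept = 0.001,
                        noise_sd = 2e-4, seed = 7)
  out <- suppressWarnings(subs2coal(fx, smoothing = "extend"))
  expect_true(ape::is.ultrametric(out$tree, tol = 1e-8))
  expect_s3_class(out$fit, "cf_conversion_fit")
  # outgroup exclusion path
  out2 <- suppressWarnings(subs2coal(fx, smoothing = "extend",
                    exclude_outgroup = true$tip.label[1]))
  expect_true(ape::is.ultrametric(out2$tree, tol = 1e-8))
  expect_true(true$tip.label[1] %in% out2$tree$tip.label)
})

test_that("estimating the tree from noisy lengths is conservative for
           hemiplasy", {
  # both arms of the round trip: the true coalescent tree vs the tree
  # re-estimated from the concordance-factor fixture and smoothed
  cond <- make_condition("TEST8")
  true_net <- cond$network
  fx <- make_cf_fixture(true_net$tree, slope = 150, intercept = 0.05,
                        noise_sd = 2e-3, seed = 3)
  for (m in c("extend", "redistribute")) {
    est <- suppressWarnings(subs2coal(fx, smoothing = m))
    est_net <- species_network(est$tree, outgroup = "t8")
    fit_true <- run_hemiplasy(true_net, cond$derived_taxa, rate = 0.05,
                              n_trees = 1.5e5, seed = 10,
                              outgroup = "t8", prune = FALSE)
    fit_est <- run_hemiplasy(est_net, cond$derived_taxa, rate = 0.05,
                             n_trees = 1.5e5, seed = 10,
                             outgroup = "t8", prune = FALSE)
    expect_lte(glance(fit_est)$cond_hemi,
               glance(fit_true)$cond_hemi + 0.02)
  }
})
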