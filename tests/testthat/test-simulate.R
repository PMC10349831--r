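test_that("Yule simulation is deterministic, ultrametric, and well formed", {
  t1 <- simulate_yule_tree(25, 1, seed = 5)
  t2 <- simulate_yule_tree(25, 1, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1),
                         write_newick(simulate_yule_tree(25, 1, seed = 6))))
  depths <- diag(vcv_matrix(t1))
  expect_lt(diff(range(depths)), 1e-9)      # ultrametric
  expect_true(all(t1$edge.length > 0))
  expect_equal(length(t1$tip.label), 25L)
  expect_equal(t1$Nnode, 24L)

  cherry <- simulate_yule_tree(2, 2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(unname(diff(diag(vcv_matrix(cherry)))), 0)
})

test_that("Yule waiting times match the closed-form expected depth", {
  # depth = sum of Exp(b*k) waits for k = 2..n-1 plus the final Exp(b*n),
  # so E[depth] = (1/b) * (sum_{k=2}^{n-1} 1/k + 1/n)
  n <- 10; b <- 2
  depths <- vapply(1:400, function(s)
    max(diag(vcv_matrix(simulate_yule_tree(n, b, seed = s)))), numeric(1))
  expected <- (sum(1 / (2:(n - 1))) + 1 / n) / b
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("Brownian simulation reproduces the tree covariance", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  sig2 <- 0.5
  sims <- vapply(1:2000, function(s)
    simulate_bm_traits(tr, root_state = 2, sigma2 = sig2, seed = s)$tip_states,
    numeric(4))
  emp <- cov(t(sims))
  expect_equal(unname(emp), unname(sig2 * vcv_matrix(tr)[rownames(emp), colnames(emp)]),
               tolerance = 0.12)
  # Var(tip - root) = sigma2 * depth, and states degenerate as sigma2 -> 0
  expect_equal(unname(apply(sims - 2, 1, var)), rep(sig2 * 2, 4), tolerance = 0.12)
  tiny <- simulate_bm_traits(tr, root_state = 3, sigma2 = 1e-12, seed = 1)
  expect_equal(unname(tiny$tip_states), rep(3, 4), tolerance = 1e-4)
  expect_equal(length(tiny$node_states), tr$Nnode)
})

test_that("scenario generation is reproducible and hits the overlap target", {
  cfg <- scenario_config(master_n_tips = 260, n_communities = 3,
                         tips_per_community = 80, pairwise_overlap = 0.1,
                         n_conditions = 2, heritable_fraction = 0.7, seed = 21)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))

  sizes <- lengths(s1$community_tips)
  expect_true(all(sizes == 80))
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- length(intersect(s1$community_tips[[i]], s1$community_tips[[j]])) / 80
    expect_lt(abs(ov - 0.1), 0.05)
  }
  expect_equal(nrow(s1$table), 3 * 2 * 80)
  # per-cell means and sds follow the configuration
  cell <- trait_vector(s1$table, "comm1", "cond1")
  expect_equal(mean(cell), cfg$condition_means[1], tolerance = 0.05)
})

test_that("full heritability with identical subsets gives identical communities", {
  cfg <- scenario_config(master_n_tips = 60, n_communities = 2,
                         tips_per_community = 60, pairwise_overlap = 1,
                         n_conditions = 1, heritable_fraction = 1, seed = 31)
  s <- simulate_scenario(cfg)
  xa <- trait_vector(s$table, "comm1", "cond1")
  xb <- trait_vector(s$table, "comm2", "cond1")
  expect_identical(xa, xb[names(xa)])
  cp <- cross_pair(s$tree, xa, xb)
  expect_equal(cp$r, 1)
  expect_equal(cp$r_squared, 1)
})

test_that("no heritability leaves no exploitable signal", {
  cfg <- scenario_config(master_n_tips = 120, n_communities = 1,
                         tips_per_community = 60, pairwise_overlap = 0,
                         n_conditions = 1, heritable_fraction = 0, seed = 41)
  s <- simulate_scenario(cfg)
  x <- trait_vector(s$table, "comm1", "cond1")
  tr <- prune_to_tips(s$tree, names(x))
  # predictions are strongly shrunken toward the mean, so the null R^2 has
  # few effective degrees of freedom; the bound is correspondingly loose
  val <- exclusion_validation(tr, x, fraction = 0.2, reps = 60, seed = 42)
  expect_lt(val$r_squared, 0.3)
  k <- blomberg_k(tr, x, nperm = 199, seed = 43)
  expect_gt(k$p_value, 0.01)
})

test_that("scenario configuration validates feasibility", {
  expect_error(scenario_config(master_n_tips = 100, n_communities = 4,
                               tips_per_community = 80, pairwise_overlap = 0.1),
               "infeasible")
  expect_error(scenario_config(heritable_fraction = 1.5), "heritable_fraction")
  expect_error(simulate_scenario(scenario_config(master_n_tips = 50,
                                                 n_communities = 1,
                                                 tips_per_community = 20)),
               "seed")
})
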