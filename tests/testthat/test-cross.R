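test_that("shared nodes: identity, disjoint cherries, and brute-force oracle", {
  tr8 <- read_newick(paste0("(((A:1,B:1)n1:1,(C:1,D:1)n2:1)n5:1,",
                            "((E:1,F:1)n3:1,(G:1,H:1)n4:1)n6:1)r;"))
  tipsA <- c("A", "B", "C", "D")
  # identical communities share every internal node of the pruned tree
  pruned <- prune_to_tips(tr8, tipsA)
  expect_setequal(shared_nodes(tr8, tipsA, tipsA), pruned$node.label)

  # pruning roots each community tree at the MRCA of its tips, so disjoint
  # cherries from opposite sides of the root share no ancestral node at all,
  # while groups spanning the root share exactly the root
  expect_length(shared_nodes(tr8, c("A", "B"), c("E", "F")), 0L)
  expect_identical(shared_nodes(tr8, c("A", "B", "E", "F"),
                                c("C", "D", "G", "H")), "r")

  # symmetry and brute-force retention oracle on random subsets
  master <- simulate_yule_tree(120, 1, seed = 31)
  for (seed in 1:5) {
    set.seed(seed)
    ta <- sample(master$tip.label, 45)
    tb <- sample(master$tip.label, 45)
    got <- shared_nodes(master, ta, tb)
    expect_setequal(got, shared_nodes(master, tb, ta))
    expect_setequal(got, intersect(brute_retained_nodes(master, ta),
                                   brute_retained_nodes(master, tb)))
  }
})

test_that("ancestral correlation handles exact and degenerate cases", {
  est <- data.frame(node_id = letters[1:6], estimate = c(1, 3, 2, 5, 4, 6))
  same <- ancestral_correlation(est, est)
  expect_equal(same$r, 1)
  flipped <- est; flipped$estimate <- -est$estimate
  expect_equal(ancestral_correlation(est, flipped)$r, -1)
  const <- est; const$estimate <- rep(1, 6)
  expect_error(ancestral_correlation(est, const), "zero variance")
  expect_error(ancestral_correlation(est[1:2, ], est[1:2, ]), "at least 3")
})

test_that("ancestral correlation weakens as independent noise grows", {
  master <- simulate_yule_tree(80, 1, seed = 41)
  bm <- simulate_bm_traits(master, 0, 1, seed = 42)
  tips <- master$tip.label
  rs <- vapply(c(0.1, 1, 5), function(noise_sd) {
    set.seed(43)
    xa <- bm$tip_states + rnorm(80, 0, noise_sd)
    xb <- bm$tip_states + rnorm(80, 0, noise_sd)
    ea <- ancestral_estimates(master, setNames(xa, tips))
    eb <- ancestral_estimates(master, setNames(xb, tips))
    ancestral_correlation(ea, eb)$r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_gt(rs[1], 0.9)
})

test_that("cross-prediction substitutes observed values for shared tips", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  xa <- c(A = 1, B = 2, C = 3, D = 4)
  # target community a subset of the predictor: pure substitution
  got <- cross_predict(tr, xa, c("B", "C"))
  expect_equal(got$predicted, c(2, 3))
  expect_true(all(got$method == "observed-substitution"))
  expect_true(all(got$se == 0))

  # disjoint target with constant predictor traits: the constant
  got2 <- cross_predict(tr, c(A = 7, B = 7), c("C", "D"))
  expect_equal(got2$predicted, c(7, 7))
  expect_true(all(got2$method == "phylogeny"))
})

test_that("phylogenetic cross-predictions equal the conditional-Gaussian oracle", {
  case <- random_case(30, 901)
  tips <- case$tree$tip.label
  tips_a <- tips[1:18]
  tips_b <- tips[19:30]
  got <- cross_predict(case$tree, case$x[tips_a], tips_b)
  for (i in seq_along(tips_b)) {
    expect_equal(got$predicted[i],
                 dense_blup(prune_to_tips(case$tree, c(tips_a, tips_b[i])),
                            case$x[tips_a], tips_b[i]),
                 tolerance = 1e-8)
  }
})

test_that("cross accuracy scores and degenerates correctly", {
  obs <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_equal(cross_accuracy(obs, obs), 1)
  preds <- data.frame(tip = letters[1:5], predicted = c(1.1, 2.2, 2.9, 4.3, 4.8))
  expect_gt(cross_accuracy(preds, obs), 0.95)
  expect_error(cross_accuracy(setNames(rep(1, 5), letters[1:5]), obs), "zero variance")

  # permuted predictions carry no information: R^2 near its null scale
  set.seed(8)
  r2s <- replicate(200, {
    y <- rnorm(40)
    cross_accuracy(sample(y), setNames(y, paste0("t", 1:40)))
  })
  expect_lt(mean(r2s), 0.06)  # E[R^2] = 1/(n-1) under independence
})

test_that("identical communities give r = 1 and cross R^2 = 1", {
  case <- random_case(40, 905)
  x <- case$x
  cp <- cross_pair(case$tree, x, x)
  expect_equal(cp$r, 1)
  expect_equal(cp$r_squared, 1)
  expect_equal(cp$n_substituted, 40L)
  expect_equal(cp$n_phylogeny, 0L)
  expect_setequal(cp$shared_node_ids, case$tree$node.label)
})
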