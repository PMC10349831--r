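test_that("hidden-tip prediction closed forms hold", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # constant observed traits predict the constant, whatever the target
  p <- predict_tip(tr, c(A = 0.4, B = 0.4, C = 0.4), "D")
  expect_equal(p$predicted, 0.4)
  expect_equal(p$n_observed_used, 3L)

  # target glued to an observed sibling (both branches ~0) inherits its value
  tr2 <- read_newick("((S:0.000001,T:0.000001):1,(C:1,D:1):1);")
  p2 <- predict_tip(tr2, c(S = 2, C = 9, D = 7), "T")
  expect_equal(p2$predicted, 2, tolerance = 1e-4)
})

test_that("prediction equals the dense conditional-Gaussian oracle", {
  for (seed in 1:12) {
    case <- random_case(25, seed + 500)
    target <- sample(case$tree$tip.label, 1)
    obs <- case$x[setdiff(case$tree$tip.label, target)]
    p <- predict_tip(case$tree, obs, target)
    expect_equal(p$predicted, dense_blup(case$tree, obs, target),
                 tolerance = 1e-8)
    expect_gt(p$se, 0)
    expect_gte(p$predicted, min(obs) - 1e-10)
    expect_lte(p$predicted, max(obs) + 1e-10)
  }
})

test_that("prediction agrees with the independent phyEstimate reference", {
  skip_if_not_installed("picante")
  case <- random_case(20, 601)
  target <- case$tree$tip.label[7]
  obs <- case$x[setdiff(case$tree$tip.label, target)]
  mine <- predict_tip(case$tree, obs, target)
  ref <- picante::phyEstimate(case$tree, data.frame(trait = obs))
  expect_equal(mine$predicted, ref[target, "estimate"], tolerance = 1e-6)
})

test_that("predict_tip validates its inputs", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(predict_tip(tr, c(A = 1, B = 2, C = 3), "Z"), "not in tree")
  expect_error(predict_tip(tr, c(A = 1, B = 2, C = 3), "A"), "observed")
  expect_error(predict_tip(tr, c(A = 1), "D"), "at least 2")
})

test_that("single-tip exclusion reproduces direct predictions (leave-one-out)", {
  case <- random_case(10, 700)
  # fraction small enough that exactly one tip is excluded per replicate
  val <- exclusion_validation(case$tree, case$x, fraction = 0.05, reps = 300,
                              seed = 11, keep_replicates = TRUE,
                              method = "reroot")
  expect_equal(val$n_excluded_per_rep, 1L)
  for (t in val$per_taxon$tip) {
    direct <- predict_tip(case$tree, case$x[setdiff(names(case$x), t)], t)
    got <- val$replicates$predicted[val$replicates$tip == t][1]
    expect_equal(got, direct$predicted, tolerance = 1e-12)
  }
})

test_that("dense BLUP and prune/reroot validation routes are identical", {
  case <- random_case(24, 750)
  v1 <- exclusion_validation(case$tree, case$x, fraction = 0.2, reps = 15,
                             seed = 6, method = "blup", keep_replicates = TRUE)
  v2 <- exclusion_validation(case$tree, case$x, fraction = 0.2, reps = 15,
                             seed = 6, method = "reroot", keep_replicates = TRUE)
  expect_equal(v1$replicates$predicted, v2$replicates$predicted,
               tolerance = 1e-8)
  expect_equal(v1$r_squared, v2$r_squared, tolerance = 1e-8)

  tips_b <- case$tree$tip.label[1:8]
  xa <- case$x[setdiff(names(case$x), tips_b)]
  c1 <- cross_predict(case$tree, xa, tips_b, method = "blup")
  c2 <- cross_predict(case$tree, xa, tips_b, method = "reroot")
  expect_equal(c1$predicted, c2$predicted, tolerance = 1e-8)
  expect_equal(c1$se, c2$se, tolerance = 1e-8)
})

test_that("exclusion validation separates strong from absent signal", {
  # tight two-clade structure: excluded tips have same-valued neighbors
  tr <- read_newick(paste0("(((a1:1,a2:1):1,(a3:1,a4:1):1):10,",
                           "((b1:1,b2:1):1,(b3:1,b4:1):1):10);"))
  set.seed(2)
  x <- setNames(c(rnorm(4, 0, 0.01), rnorm(4, 5, 0.01)), tr$tip.label)
  v_strong <- exclusion_validation(tr, x, fraction = 0.2, reps = 100, seed = 4)
  expect_gt(v_strong$r_squared, 0.95)

  # unequal-branch star tree: the phylogeny carries no information, so the
  # predictions shrink to the community mean. Excluding a high-valued tip
  # lowers that mean, so the only association left is a weak NEGATIVE one
  # (an inherent property of exclusion validation under the null); the
  # strong-signal case must show the opposite, near-perfect positive slope
  set.seed(3)
  star <- read_newick(paste0("(", paste(sprintf("s%d:%0.3f", 1:30, runif(30, 0.5, 1.5)),
                                        collapse = ","), ");"))
  xs <- setNames(rnorm(30), star$tip.label)
  v_null <- exclusion_validation(star, xs, fraction = 0.2, reps = 100, seed = 5)
  expect_lt(cor(v_null$per_taxon$mean_predicted, v_null$per_taxon$observed), 0)
  expect_gt(cor(v_strong$per_taxon$mean_predicted, v_strong$per_taxon$observed),
            0.95)
  # and the null predictions are an order of magnitude flatter than observed
  expect_lt(sd(v_null$per_taxon$mean_predicted), 0.2 * sd(xs))
})

test_that("every tip is excluded at least once at the study replicate counts", {
  case <- random_case(20, 800)
  val <- exclusion_validation(case$tree, case$x, fraction = 0.2, reps = 200,
                              seed = 9)
  expect_equal(nrow(val$per_taxon), 20L)
  expect_true(all(val$per_taxon$n_excluded >= 1L))
  expect_gte(val$r_squared, 0)
  expect_lte(val$r_squared, 1)
})

test_that("trend regression recovers exact and simulated relationships", {
  fit <- suppressWarnings(trend_regression(c(0, 0.5, 1), c(0, 0.25, 0.5)))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(trend_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(trend_regression(c(1, 2), c(1, 2)), "at least 3")
})
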