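#' Simulate a pure-birth (Yule) phylogeny
#'
#' Grows a tree from a root split under a constant per-lineage birth rate:
#' with k extant lineages the waiting time to the next split is exponential
#' with rate `birth_rate * k`, and the splitting lineage is chosen uniformly.
#' After the tree reaches `n_tips` lineages one further exponential waiting
#' time (rate `birth_rate * n_tips`) is appended so terminal branches are
#' never zero. The result is ultrametric and binary, with tip labels
#' `otu0001 ...` and deterministic internal node ids.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time (> 0).
#' @param seed optional RNG seed; identical seeds give identical trees.
#' @return a `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("'n_tips' must be >= 2")
  if (birth_rate <= 0) stop("'birth_rate' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  # internal node k has parent int_parent[k] (0 for root) and split time
  int_parent <- integer(n_tips - 1L); int_time <- numeric(n_tips - 1L)
  n_int <- 1L
  act_parent <- c(1L, 1L)   # parent internal node of each active lineage
  act_start <- c(0, 0)
  t <- 0
  while (length(act_start) < n_tips) {
    k <- length(act_start)
    t <- t + stats::rexp(1L, rate = birth_rate * k)
    i <- sample.int(k, 1L)
    n_int <- n_int + 1L
    int_parent[n_int] <- act_parent[i]
    int_time[n_int] <- t
    act_parent <- c(act_parent[-i], n_int, n_int)
    act_start <- c(act_start[-i], t, t)
  }
  t_end <- t + stats::rexp(1L, rate = birth_rate * n_tips)
  # assemble the phylo object: tips 1..n, internals n+1..2n-1 (root = n+1)
  n <- n_tips
  tip_edges <- cbind(n + act_parent, seq_len(n))
  tip_len <- t_end - act_start
  int_idx <- seq_len(n_int)[-1L]
  int_edges <- cbind(n + int_parent[int_idx], n + int_idx)
  int_len <- int_time[int_idx] - int_time[int_parent[int_idx]]
  tr <- structure(list(
    edge = rbind(int_edges, tip_edges),
    edge.length = c(int_len, tip_len),
    tip.label = sprintf("otu%04d", seq_len(n)),
    Nnode = n_int
  ), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  as_phylopred_tree(tr)
}

#' Simulate Brownian trait evolution on a tree
#'
#' Evolves a continuous trait from the root along every branch with
#' independent Gaussian increments of variance `sigma2 * branch_length`,
#' recording the true state at every node — so ancestral-state and root
#' estimators can be checked against the generating truth.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param root_state trait value at the root.
#' @param sigma2 Brownian rate (trait variance per unit branch length, > 0).
#' @param seed optional RNG seed.
#' @return list with `tip_states` (named by tip label), `node_states` (named
#'   by node id, root included), `root_state`, `sigma2`, `tree`.
#' @export
simulate_bm_traits <- function(tree, root_state = 0, sigma2 = 1, seed = NULL) {
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- as_phylopred_tree(tree)
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  state <- numeric(n_tip + tree$Nnode)
  state[.root_node(tree)] <- root_state
  inc <- stats::rnorm(nrow(post$edge), 0, sqrt(sigma2 * post$edge.length))
  for (e in rev(seq_len(nrow(post$edge)))) {
    state[post$edge[e, 2L]] <- state[post$edge[e, 1L]] + inc[e]
  }
  list(tip_states = stats::setNames(state[seq_len(n_tip)], tree$tip.label),
       node_states = stats::setNames(state[(n_tip + 1L):(n_tip + tree$Nnode)],
                                     tree$node.label),
       root_state = root_state, sigma2 = sigma2, tree = tree)
}

#' Scenario configuration for the synthetic community generator
#'
#' Bundles and validates the knobs of [simulate_scenario()]. The defaults
#' describe the study design the generator emulates: four soil communities
#' (sizes spanning roughly 165-381 tips) incubated at four conditions, drawn
#' as overlapping subsets of one master phylogeny with about 10% pairwise
#' tip overlap, with trait means rising across conditions the way growth
#' rates rise with incubation temperature.
#'
#' The trait of community i at condition j for tip t is
#' `mean[j] + sd * (sqrt(h) * z_BM(t) + sqrt(1-h) * eps)`, where `z_BM` is the
#' community-standardized Brownian tip state inherited from the master tree
#' and `eps` is independent standard-normal noise drawn per community and
#' condition. `h` (the heritable fraction) is therefore the share of trait
#' variance attributable to shared evolutionary history; it is the single
#' dial that moves Blomberg's K, within-community prediction accuracy and
#' cross-community transfer together.
#'
#' @param master_n_tips tips in the master phylogeny.
#' @param birth_rate Yule birth rate for the master tree.
#' @param n_communities number of communities.
#' @param tips_per_community integer vector (recycled) of community sizes.
#' @param pairwise_overlap target fraction of a community's tips shared with
#'   another community (achieved by a common core of master tips).
#' @param bm_sigma2,root_state Brownian rate and root state on the master tree.
#' @param heritable_fraction h in `[0, 1]`; scalar, or vector/matrix recycled
#'   to `n_communities * n_conditions` (rows = communities).
#' @param n_conditions number of conditions.
#' @param condition_means trait mean per condition (recycled), trait units
#'   (e.g. proportion per day).
#' @param trait_sd trait standard deviation within a community-condition cell.
#' @param community_labels,condition_labels optional label vectors.
#' @param seed RNG seed for the whole scenario.
#' @return a validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(master_n_tips = 1000, birth_rate = 1,
                            n_communities = 4,
                            tips_per_community = c(207, 182, 378, 260),
                            pairwise_overlap = 0.10,
                            bm_sigma2 = 1, root_state = 0,
                            heritable_fraction = 0.6,
                            n_conditions = 4,
                            condition_means = c(0.03, 0.12, 0.18, 0.22),
                            trait_sd = 0.05,
                            community_labels = NULL, condition_labels = NULL,
                            seed = NULL) {
  cfg <- list(master_n_tips = as.integer(master_n_tips),
              birth_rate = birth_rate,
              n_communities = as.integer(n_communities),
              tips_per_community = rep_len(as.integer(tips_per_community), n_communities),
              pairwise_overlap = pairwise_overlap,
              bm_sigma2 = bm_sigma2, root_state = root_state,
              heritable_fraction = heritable_fraction,
              n_conditions = as.integer(n_conditions),
              condition_means = rep_len(condition_means, n_conditions),
              trait_sd = trait_sd,
              community_labels = community_labels %||% sprintf("comm%d", seq_len(n_communities)),
              condition_labels = condition_labels %||% sprintf("cond%d", seq_len(n_conditions)),
              seed = seed)
  stopifnot(cfg$master_n_tips >= 2L, cfg$birth_rate > 0,
            cfg$n_communities >= 1L, all(cfg$tips_per_community >= 5L),
            all(cfg$tips_per_community <= cfg$master_n_tips),
            cfg$pairwise_overlap >= 0, cfg$pairwise_overlap <= 1,
            cfg$bm_sigma2 > 0, cfg$trait_sd > 0,
            all(cfg$heritable_fraction >= 0), all(cfg$heritable_fraction <= 1))
  h <- matrix(rep_len(as.numeric(cfg$heritable_fraction),
                      cfg$n_communities * cfg$n_conditions),
              nrow = cfg$n_communities)
  dimnames(h) <- list(cfg$community_labels, cfg$condition_labels)
  cfg$h_matrix <- h
  n_core <- round(cfg$pairwise_overlap * mean(cfg$tips_per_community))
  n_core <- min(n_core, min(cfg$tips_per_community))
  if (n_core + sum(cfg$tips_per_community - n_core) > cfg$master_n_tips)
    stop("infeasible overlap/size combination: master tree too small for ",
         "the requested community sizes and overlap")
  cfg$n_core <- as.integer(n_core)
  class(cfg) <- "scenario_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw community trait tables from a Brownian truth
#'
#' Samples the community tip subsets (a shared core of `n_core` master tips
#' plus disjoint community-exclusive sets, so the pairwise shared-tip count
#' is exactly the core size) and generates the per-community, per-condition
#' trait tables as the heritable-fraction mixture described in
#' [scenario_config()].
#'
#' @param truth result of [simulate_bm_traits()] on the master tree.
#' @param config a [scenario_config()].
#' @param seed optional RNG seed (defaults to a sub-seed of `config$seed`).
#' @return list with `table` (long data frame: `otu_id`, `community`,
#'   `condition`, `trait`), `community_tips` (named list), `config`.
#' @export
make_community_tables <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  tips <- names(truth$tip_states)
  if (length(tips) < config$master_n_tips)
    stop("truth has fewer tips than the configuration expects")
  core <- sample(tips, config$n_core)
  pool <- setdiff(tips, core)
  community_tips <- vector("list", config$n_communities)
  names(community_tips) <- config$community_labels
  for (i in seq_len(config$n_communities)) {
    n_excl <- config$tips_per_community[i] - config$n_core
    excl <- sample(pool, n_excl)
    pool <- setdiff(pool, excl)
    community_tips[[i]] <- sort(c(core, excl))
  }
  rows <- list()
  for (i in seq_len(config$n_communities)) {
    ct <- community_tips[[i]]
    z <- standardize_z(truth$tip_states[ct])
    for (j in seq_len(config$n_conditions)) {
      h <- config$h_matrix[i, j]
      eps <- stats::rnorm(length(ct))
      raw <- sqrt(h) * z + sqrt(1 - h) * eps
      rows[[length(rows) + 1L]] <- data.frame(
        otu_id = ct,
        community = config$community_labels[i],
        condition = config$condition_labels[j],
        trait = config$condition_means[j] + config$trait_sd * raw,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), community_tips = community_tips,
       config = config)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: master Yule tree, Brownian trait evolution with
#' recorded true node states, and overlapping community trait tables. All
#' randomness derives from `config$seed` (or `seed`), so identical
#' configurations reproduce byte-identical output.
#'
#' @param config a [scenario_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `"synthetic_scenario"`: `tree` (master phylogeny),
#'   `truth` (from [simulate_bm_traits()]), `table`, `community_tips`,
#'   `config`.
#' @export
simulate_scenario <- function(config = scenario_config(), seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required for a reproducible scenario")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 3L)
  tree <- simulate_yule_tree(config$master_n_tips, config$birth_rate,
                             seed = subseeds[1L])
  truth <- simulate_bm_traits(tree, root_state = config$root_state,
                              sigma2 = config$bm_sigma2, seed = subseeds[2L])
  tab <- make_community_tables(truth, config, seed = subseeds[3L])
  structure(list(tree = tree, truth = truth, table = tab$table,
                 community_tips = tab$community_tips, config = config,
                 seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d-tip master tree, %d communities x %d conditions\n",
              length(x$tree$tip.label), x$config$n_communities, x$config$n_conditions))
  cat(sprintf("  community sizes: %s (shared core %d tips)\n",
              paste(x$config$tips_per_community, collapse = ", "), x$config$n_core))
  cat(sprintf("  heritable fraction: %s\n",
              paste(unique(as.vector(x$config$h_matrix)), collapse = ", ")))
  invisible(x)
}
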