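# Independent brute-force oracles. These deliberately avoid the package's
# pruning engine: everything here is dense linear algebra or explicit
# enumeration, so agreement with the fast paths is a genuine cross-check.

# dense GLS mean and sum of squares from the covariance matrix
dense_gls <- function(tree, x) {
  V <- vcv_matrix(tree)[tree$tip.label, tree$tip.label]
  x <- x[tree$tip.label]
  Vi <- solve(V)
  n <- length(x)
  a <- sum(Vi %*% x) / sum(Vi)
  ss <- drop(t(x - a) %*% Vi %*% (x - a))
  list(mean = a, root_v = 1 / sum(Vi), ss = ss, sigma2 = ss / (n - 1))
}

# dense Blomberg's K straight from the defining formula
dense_k <- function(tree, x) {
  g <- dense_gls(tree, x)
  x <- x[tree$tip.label]
  n <- length(x)
  V <- vcv_matrix(tree)[tree$tip.label, tree$tip.label]
  mse0 <- sum((x - g$mean)^2) / (n - 1)
  mse <- g$ss / (n - 1)
  (mse0 / mse) / ((sum(diag(V)) - n * g$root_v) / (n - 1))
}

# conditional-Gaussian best linear unbiased prediction of one tip given the
# others, with the GLS plug-in mean (all from the dense covariance matrix)
dense_blup <- function(tree, obs, target) {
  V <- vcv_matrix(tree)
  oo <- names(obs)
  Vi <- solve(V[oo, oo])
  a <- sum(Vi %*% obs[oo]) / sum(Vi)
  drop(a + V[target, oo] %*% Vi %*% (obs[oo] - a))
}

# covariance matrix by explicit per-pair shared-path scan: intersect the two
# root-to-tip edge paths and sum the branch lengths of common edges
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path <- function(i) {  # nodes on the path root -> i (excluding root)
    out <- integer(0)
    while (parent[i] != 0) { out <- c(out, i); i <- parent[i] }
    out
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- V[j, i] <- sum(plen[shared])
  }
  V
}

# node ids of the master tree retained as branching nodes after pruning to
# `keep`: a node survives iff at least two of its child subtrees contain a
# kept tip (counted by brute-force subtree membership)
brute_retained_nodes <- function(master, keep) {
  n <- length(master$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(master$tip.label[node])
    kids <- master$edge[master$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- character(0)
  for (k in seq_len(master$Nnode)) {
    node <- n + k
    kids <- master$edge[master$edge[, 1] == node, 2]
    hits <- sum(vapply(kids, function(c) any(tips_below(c) %in% keep), logical(1)))
    if (hits >= 2) out <- c(out, master$node.label[k])
  }
  out
}

# exhaustive enumeration for the GLS-mse signal statistic: returns the
# fraction of ALL n! tip relabelings whose mse is <= the observed mse (the
# package's random-permutation p converges to (1 + nperm*f)/(nperm + 1))
exhaustive_perm_fraction <- function(tree, x) {
  x <- x[tree$tip.label]
  n <- length(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  V <- vcv_matrix(tree)[tree$tip.label, tree$tip.label]
  Vi <- solve(V)
  msef <- function(z) {
    a <- sum(Vi %*% z) / sum(Vi)
    drop(t(z - a) %*% Vi %*% (z - a)) / (n - 1)
  }
  obs <- msef(x)
  ps <- apply(perms, 1, function(p) msef(x[p]))
  mean(ps <= obs + 1e-12 * abs(obs))
}

# a random Yule tree with BM traits, for property loops
random_case <- function(n, seed, sigma2 = 1) {
  tr <- simulate_yule_tree(n, 1, seed = seed)
  x <- simulate_bm_traits(tr, 0, sigma2, seed = seed + 1000L)$tip_states
  list(tree = tr, x = x)
}
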