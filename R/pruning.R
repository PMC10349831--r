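# Felsenstein-style pruning (belief propagation) for Brownian motion on a
# rooted tree. These two passes are the computational core: every
# generalized-least-squares quantity used elsewhere (phylogenetic mean, GLS
# sum of squares, ancestral states, hidden-tip predictions) reduces to them.
#
# Up pass. Conditioning on the tips below node u, the trait at u is Gaussian
# with mean mu_up[u] and variance sigma2 * v_up[u]. For a tip, (x_tip, 0).
# For an internal node with children c_i reached over branches t_i, writing
# v'_i = v_up[c_i] + t_i:
#     1 / v_up[u]  = sum_i 1 / v'_i
#     mu_up[u]     = v_up[u] * sum_i mu_up[c_i] / v'_i
# Polytomies and unifurcations need no special casing. At the root,
# mu_up = (1' V^-1 x) / (1' V^-1 1) (the GLS/phylogenetic mean) and
# v_up = 1 / (1' V^-1 1). The GLS sum of squares decomposes edge-wise:
#     (x - a 1)' V^-1 (x - a 1) = sum_edges (mu_up[c] - mu_up[p])^2 / v'_c
# which is what .bm_uppass accumulates in `ss`.
#
# Down pass. For non-root u with parent p, the message from the rest of the
# tree (everything not below u) has precision P_rest = the sum of 1/v' over
# p's other children plus p's own down-message precision, carried across u's
# branch. Combining up and down messages at u gives the conditional mean and
# variance of the trait at u given ALL tips — identical to rerooting the tree
# at u and reading off the root GLS mean, but in O(n) for all nodes at once.

# tree: phylo (validated); x: numeric named by tip label, complete.
# Returns root mean/variance coefficient, GLS ss, and per-node up messages.
.bm_uppass <- function(tree, x) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  elen <- post$edge.length
  mu <- numeric(n_node)
  v <- numeric(n_node)
  prec <- numeric(n_node)   # accumulated child precision at internals
  pm <- numeric(n_node)     # accumulated precision-weighted child means
  mu[seq_len(n_tip)] <- x[tree$tip.label]
  # children appear before parents in postorder, and all edges into a parent
  # are contiguous; a simple edge loop accumulates correctly
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    if (ch > n_tip) {          # finalize internal child before using it
      v[ch] <- 1 / prec[ch]
      mu[ch] <- pm[ch] * v[ch]
    }
    vp <- v[ch] + elen[e]
    if (vp <= 0) stop("nonpositive branch variance during pruning (zero-length terminal branch?)")
    prec[p] <- prec[p] + 1 / vp
    pm[p] <- pm[p] + mu[ch] / vp
  }
  root <- edge[nrow(edge), 1L]
  v[root] <- 1 / prec[root]
  mu[root] <- pm[root] * v[root]
  # GLS sum of squares, edge-wise decomposition
  vprime <- v[edge[, 2L]] + elen
  ss <- sum((mu[edge[, 2L]] - mu[edge[, 1L]])^2 / vprime)
  list(root = root, root_mean = mu[root], root_v = v[root], ss = ss,
       mu_up = mu, v_up = v, edge = edge, elen = elen)
}

# Down pass; requires the result of .bm_uppass. Returns, for every node, the
# conditional (given all tips) mean and the variance coefficient (multiply by
# sigma2 for the variance). Root values equal the up-pass root values.
.bm_downpass <- function(tree, up) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- up$edge; elen <- up$elen
  vprime <- up$v_up[edge[, 2L]] + elen
  # per-parent totals of child messages
  tot_prec <- numeric(n_node); tot_pm <- numeric(n_node)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    tot_prec[p] <- tot_prec[p] + 1 / vprime[e]
    tot_pm[p] <- tot_pm[p] + up$mu_up[edge[e, 2L]] / vprime[e]
  }
  mu_dn <- numeric(n_node); v_dn <- rep(Inf, n_node)
  root <- up$root
  # preorder = reverse postorder edge sweep
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    prec_rest <- tot_prec[p] - 1 / vprime[e]
    pm_rest <- tot_pm[p] - up$mu_up[ch] / vprime[e]
    if (p != root && is.finite(v_dn[p])) {
      prec_rest <- prec_rest + 1 / v_dn[p]
      pm_rest <- pm_rest + mu_dn[p] / v_dn[p]
    }
    if (prec_rest > 0) {
      v_dn[ch] <- 1 / prec_rest + elen[e]
      mu_dn[ch] <- (pm_rest / prec_rest)
    } # else: no information from the rest of the tree (v_dn stays Inf)
  }
  est <- numeric(n_node); vcoef <- numeric(n_node)
  for (u in seq_len(n_node)) {
    pu <- if (u > n_tip) 1 / up$v_up[u] else Inf  # tips are observed exactly
    pd <- if (is.finite(v_dn[u])) 1 / v_dn[u] else 0
    if (is.finite(pu)) {
      vcoef[u] <- 1 / (pu + pd)
      est[u] <- (up$mu_up[u] * pu + mu_dn[u] * pd) * vcoef[u]
    } else {
      vcoef[u] <- 0
      est[u] <- up$mu_up[u]
    }
  }
  est[root] <- up$root_mean
  vcoef[root] <- up$root_v
  list(estimate = est, vcoef = vcoef)
}

# Shared argument checking for GLS operations: complete named trait vector.
.check_traits <- function(tree, x, require_variance = TRUE) {
  if (is.null(names(x))) stop("'traits' must be a named numeric vector (names = tip labels)")
  x <- x[!is.na(x)]
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing))
    stop("missing trait value(s) for tip(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- x[tree$tip.label]
  if (require_variance && stats::var(x) == 0)
    stop("trait values are constant; statistic undefined")
  x
}
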