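#' Brownian-motion ancestral state estimates at every internal node
#'
#' Estimates the trait value at each internal node as the
#' generalized-least-squares (phylogenetic) mean of the tree rerooted at that
#' node — the maximum-likelihood ancestral state under Brownian motion, with a
#' REML-based variance. The default implementation is a two-pass
#' message-passing sweep that computes all nodes in linear time;
#' `method = "reroot"` performs the literal reroot-and-estimate construction
#' node by node and is retained as the reference the fast path must reproduce.
#'
#' Every estimate is a convex combination of tip values, so it lies within
#' the observed trait range.
#'
#' @inheritParams fit_bm
#' @param method `"twopass"` (default) or `"reroot"`.
#' @return a data frame with one row per internal node: `node_id`,
#'   `estimate`, `variance`. The root row is included; its values equal the
#'   phylogenetic mean and its variance.
#' @examples
#' tr <- read_newick("((A:1,B:1)mrcaAB:1,(C:1,D:1)mrcaCD:1)root;")
#' ancestral_estimates(tr, c(A = 0, B = 0, C = 1, D = 1))
#' @export
ancestral_estimates <- function(tree, traits, method = c("twopass", "reroot"),
                                jitter = FALSE) {
  method <- match.arg(method)
  tree <- as_phylopred_tree(tree)
  tree <- .check_terminal_branches(tree, jitter = jitter)
  x <- .check_traits(tree, traits, require_variance = FALSE)
  n_tip <- length(tree$tip.label)
  up <- .bm_uppass(tree, x)
  sigma2 <- up$ss / (n_tip - 1)
  if (method == "twopass") {
    dn <- .bm_downpass(tree, up)
    internal <- (n_tip + 1L):(n_tip + tree$Nnode)
    est <- dn$estimate[internal]
    vr <- sigma2 * dn$vcoef[internal]
    ids <- tree$node.label
  } else {
    ids <- tree$node.label
    est <- numeric(tree$Nnode)
    vr <- numeric(tree$Nnode)
    for (k in seq_len(tree$Nnode)) {
      rt <- reroot_at_node(tree, ids[k])
      upk <- .bm_uppass(rt, x)
      est[k] <- upk$root_mean
      vr[k] <- sigma2 * upk$root_v
    }
  }
  data.frame(node_id = ids, estimate = est, variance = vr,
             stringsAsFactors = FALSE)
}

#' Standardize values to Z-scores within a community
#'
#' Centers and scales by the community mean and (n-1) standard deviation, so
#' values below zero are below the community average. Used to compare clade
#' trait levels across communities on a common scale.
#'
#' @param x numeric vector (observed tip traits or ancestral estimates of one
#'   community at one condition).
#' @return numeric vector of Z-scores with mean 0 and standard deviation 1.
#' @export
standardize_z <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: Z-scores undefined")
  (x - mean(x)) / s
}
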