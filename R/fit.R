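#' Fit a Brownian-motion trait model to a phylogeny
#'
#' Fits the single-rate Brownian-motion (BM) model to a continuous trait
#' observed at the tips of a rooted phylogeny. The fit estimates the root
#' (phylogenetic) mean by generalized least squares,
#' \eqn{\hat a = (1' V^{-1} x) / (1' V^{-1} 1)}, and the evolutionary rate
#' \eqn{\hat\sigma^2 = (x - \hat a 1)' V^{-1} (x - \hat a 1) / (n - 1)}
#' (the residual-maximum-likelihood rate), where \eqn{V} is the
#' phylogenetic covariance matrix of [vcv_matrix()]. Computation uses a
#' linear-time pruning pass, not dense matrix algebra.
#'
#' The tree may contain tips with no trait value: the model is fitted on the
#' pruned tree of observed tips, and the remaining tips form the prediction
#' set of [predict.phybm()].
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param traits named numeric vector of trait values; names are tip labels.
#'   Tips of `tree` absent from `traits` (or `NA`) are treated as unobserved.
#' @param jitter if `TRUE`, zero-length terminal branches are perturbed by
#'   `1e-8` times the tree depth instead of raising an error.
#' @return an object of class `"phybm"`: a list with elements `tree`
#'   (observed-tip tree), `master` (the tree as given), `traits` (observed
#'   values in tip order), `root` (estimate and variance of the root state),
#'   `sigma2` (REML rate), `ss` (GLS sum of squares), and `n`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fit <- fit_bm(tr, c(A = 0.1, B = 0.12, C = 0.3, D = 0.28))
#' coef(fit)
#' @seealso [ancestral_estimates()], [blomberg_k()], [predict.phybm()]
#' @export
fit_bm <- function(tree, traits, jitter = FALSE) {
  master <- as_phylopred_tree(tree)
  if (is.null(names(traits))) stop("'traits' must be named by tip label")
  traits <- traits[!is.na(traits)]
  obs <- intersect(master$tip.label, names(traits))
  if (length(obs) < 2L) stop("need at least 2 observed tips")
  extra <- setdiff(names(traits), master$tip.label)
  if (length(extra))
    warning("dropping ", length(extra), " trait value(s) for tips absent from the tree")
  tr <- prune_to_tips(master, obs)
  tr <- .check_terminal_branches(tr, jitter = jitter)
  x <- .check_traits(tr, traits[obs], require_variance = FALSE)
  up <- .bm_uppass(tr, x)
  n <- length(x)
  sigma2 <- up$ss / (n - 1)
  structure(list(
    tree = tr, master = master, traits = x,
    root = c(estimate = up$root_mean, variance = sigma2 * up$root_v),
    sigma2 = sigma2, ss = up$ss, root_v = up$root_v, n = n,
    jitter = jitter
  ), class = "phybm")
}

#' Phylogenetic (generalized-least-squares) mean of a trait
#'
#' The Brownian-motion estimate of the trait at the root of the tree, with its
#' REML variance. Equivalent to `fit_bm(tree, traits)$root` but returned as a
#' plain list.
#'
#' @inheritParams fit_bm
#' @return list with `estimate`, `variance`, and `sigma2`.
#' @export
phylogenetic_mean <- function(tree, traits, jitter = FALSE) {
  fit <- fit_bm(tree, traits, jitter = jitter)
  list(estimate = unname(fit$root["estimate"]),
       variance = unname(fit$root["variance"]),
       sigma2 = fit$sigma2)
}

#' @export
print.phybm <- function(x, ...) {
  cat("Brownian-motion trait model (GLS, REML rate)\n")
  cat(sprintf("  tips observed: %d of %d\n", x$n, length(x$master$tip.label)))
  cat(sprintf("  root state: %.6g (se %.3g)\n",
              x$root["estimate"], sqrt(x$root["variance"])))
  cat(sprintf("  rate sigma^2: %.6g per unit branch length\n", x$sigma2))
  invisible(x)
}

#' @export
coef.phybm <- function(object, ...) {
  c(root = unname(object$root["estimate"]), sigma2 = object$sigma2)
}

#' Summarize a fitted Brownian-motion trait model
#'
#' Adds Blomberg's K (and, when `nperm > 0`, its permutation p-value) to the
#' fitted quantities.
#'
#' @param object a `"phybm"` fit.
#' @param nperm number of trait permutations for the signal test (0 = skip).
#' @param seed optional RNG seed for the permutation test.
#' @param ... unused.
#' @return an object of class `"summary.phybm"`.
#' @export
summary.phybm <- function(object, nperm = 0, seed = NULL, ...) {
  k <- if (stats::var(object$traits) > 0) {
    blomberg_k(object$tree, object$traits, nperm = nperm, seed = seed,
               jitter = object$jitter)
  } else NULL
  structure(list(fit = object, signal = k), class = "summary.phybm")
}

#' @export
print.summary.phybm <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$signal)) {
    cat(sprintf("  Blomberg's K: %.4g", x$signal$K))
    if (!is.null(x$signal$p_value))
      cat(sprintf("  (permutation p = %.4g, %d permutations)",
                  x$signal$p_value, x$signal$n_permutations))
    cat("\n")
  }
  invisible(x)
}

#' Residuals of a Brownian-motion trait fit
#'
#' `type = "response"` gives deviations of the tip values from the fitted
#' root state. `type = "normalized"` whitens them by the Cholesky factor of
#' the phylogenetic covariance, giving approximately i.i.d. standard-normal
#' values when the BM model holds.
#'
#' @param object a `"phybm"` fit.
#' @param type `"response"` or `"normalized"`.
#' @param ... unused.
#' @return named numeric vector in tip order.
#' @export
residuals.phybm <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$traits - object$root["estimate"]
  if (type == "response") return(r)
  V <- vcv_matrix(object$tree)[names(r), names(r)]
  L <- chol(object$sigma2 * V)
  stats::setNames(drop(backsolve(L, r, transpose = TRUE)), names(r))
}

#' Simulate tip traits from a fitted Brownian-motion model
#'
#' Draws new trait values on the observed-tip tree under the fitted root state
#' and rate, by simulating Gaussian increments along every branch.
#'
#' @param object a `"phybm"` fit.
#' @param nsim number of simulated trait vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a data frame with one row per tip and one column per simulation.
#' @export
simulate.phybm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_bm_traits(object$tree,
                                            root_state = object$root[["estimate"]],
                                            sigma2 = object$sigma2)$tip_states)
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$tree$tip.label
  out
}

#' Predict traits of unobserved tips from a fitted model
#'
#' Applies the prune-and-reroot hidden-tip procedure (see [predict_tip()]) to
#' tips of the master tree without observed trait values.
#'
#' @param object a `"phybm"` fit whose master tree contains unobserved tips.
#' @param tips tips to predict; default: all unobserved tips of the master tree.
#' @param ... unused.
#' @return a data frame with columns `tip`, `predicted`, `se`,
#'   `n_observed_used`.
#' @export
predict.phybm <- function(object, tips = NULL, ...) {
  unobs <- setdiff(object$master$tip.label, names(object$traits))
  if (is.null(tips)) tips <- unobs
  bad <- setdiff(tips, object$master$tip.label)
  if (length(bad)) stop("tip(s) not in the tree: ", paste(utils::head(bad, 5L), collapse = ", "))
  already <- intersect(tips, names(object$traits))
  if (length(already)) stop("tip(s) already observed: ", paste(utils::head(already, 5L), collapse = ", "))
  if (!length(tips)) return(data.frame(tip = character(), predicted = numeric(),
                                       se = numeric(), n_observed_used = integer()))
  do.call(rbind, lapply(tips, function(t)
    predict_tip(object$master, object$traits, t, jitter = object$jitter)))
}

#' Plot a phylogeny painted with observed and inferred trait values
#'
#' Draws the observed-tip tree with branch colors interpolating the trait:
#' tips take their observed values, internal nodes their Brownian-motion
#' ancestral estimates.
#'
#' @param x a `"phybm"` fit.
#' @param palette color ramp endpoints passed to [grDevices::colorRampPalette()].
#' @param n_colors resolution of the color ramp.
#' @param ... passed to [ape::plot.phylo()].
#' @return invisibly, the per-node values used for coloring.
#' @export
plot.phybm <- function(x, palette = c("navy", "grey85", "firebrick"),
                       n_colors = 64L, ...) {
  anc <- ancestral_estimates(x$tree, x$traits, jitter = x$jitter)
  vals <- c(x$traits[x$tree$tip.label],
            anc$estimate[match(x$tree$node.label, anc$node_id)])
  ramp <- grDevices::colorRampPalette(palette)(n_colors)
  idx <- findInterval(vals, seq(min(vals), max(vals), length.out = n_colors + 1L),
                      all.inside = TRUE)
  edge_col <- ramp[idx[x$tree$edge[, 2L]]]
  ape::plot.phylo(x$tree, edge.color = edge_col, ...)
  invisible(stats::setNames(vals, c(x$tree$tip.label, x$tree$node.label)))
}
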