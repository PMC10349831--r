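#' Ancestral nodes shared by two communities' pruned phylogenies
#'
#' A master-tree internal node is "shared" by two communities when it survives
#' as a branching node in both community trees, i.e. in the master tree pruned
#' to each community's tips (unifurcating nodes are suppressed during
#' pruning). Shared nodes anchor the cross-community comparison of ancestral
#' trait estimates: identity is established through the stable node ids
#' carried by [prune_to_tips()].
#'
#' @param master the master `"phylo"` tree with node labels.
#' @param tips_a,tips_b character vectors of the two communities' tip labels
#'   (each at least 2, subsets of the master tips).
#' @return character vector of shared node ids (order as in community A's
#'   pruned tree).
#' @export
shared_nodes <- function(master, tips_a, tips_b) {
  ta <- prune_to_tips(master, tips_a)
  tb <- prune_to_tips(master, tips_b)
  intersect(ta$node.label, tb$node.label)
}

#' Correlation of ancestral estimates at shared nodes
#'
#' Pearson correlation, across shared ancestral nodes, of the two
#' communities' Brownian-motion ancestral trait estimates, with the usual
#' t-distributed significance test (n - 2 degrees of freedom). A strong
#' correlation indicates that the two communities agree about the trait
#' levels of their common ancestors, the condition under which one
#' community's data can predict the other's tips.
#'
#' @param est_a,est_b data frames from [ancestral_estimates()] for the two
#'   communities (computed on their own pruned trees).
#' @param shared character vector of shared node ids; default: all node ids
#'   present in both estimate tables.
#' @return list with `r`, `p_value`, `n` (number of shared nodes used).
#' @export
ancestral_correlation <- function(est_a, est_b, shared = NULL) {
  if (is.null(shared)) shared <- intersect(est_a$node_id, est_b$node_id)
  shared <- as.character(shared)
  miss_a <- setdiff(shared, est_a$node_id)
  miss_b <- setdiff(shared, est_b$node_id)
  if (length(miss_a) || length(miss_b))
    stop("estimates missing for shared node(s): ",
         paste(utils::head(c(miss_a, miss_b), 5L), collapse = ", "))
  n <- length(shared)
  if (n < 3L) stop("need at least 3 shared nodes")
  a <- est_a$estimate[match(shared, est_a$node_id)]
  b <- est_b$estimate[match(shared, est_b$node_id)]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance in ancestral estimates; correlation undefined")
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Predict one community's tip traits from another community's observations
#'
#' For every target tip: if the predictor community observed that same tip,
#' its observed value is used directly (an "observed-substitution" with zero
#' standard error); otherwise the tip is predicted phylogenetically with
#' [predict_tip()] from the predictor community's data on the master tree.
#'
#' @param master the master `"phylo"` tree containing both communities' tips.
#' @param traits_a named numeric vector: predictor community's observed traits.
#' @param tips_b character vector: target community's tips.
#' @param method `"blup"` (default) computes all phylogenetic predictions from
#'   one dense covariance matrix via the conditional-Gaussian identity;
#'   `"reroot"` runs the prune-and-reroot procedure tip by tip. The two are
#'   algebraically identical.
#' @inheritParams fit_bm
#' @return data frame with columns `tip`, `predicted`, `se`,
#'   `n_observed_used`, `method` (`"observed-substitution"` or `"phylogeny"`).
#' @export
cross_predict <- function(master, traits_a, tips_b, jitter = FALSE,
                          method = c("blup", "reroot")) {
  method <- match.arg(method)
  master <- as_phylopred_tree(master)
  traits_a <- traits_a[!is.na(traits_a)]
  if (!length(traits_a)) stop("predictor community has no observed traits")
  bad <- setdiff(tips_b, master$tip.label)
  if (length(bad)) stop("target tip(s) not in master tree: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  obs <- intersect(names(traits_a), master$tip.label)
  new <- setdiff(tips_b, obs)
  phylo_preds <- if (length(new)) {
    pool <- prune_to_tips(master, union(obs, new))
    if (method == "blup") {
      pool <- .check_terminal_branches(pool, jitter = jitter)
      .blup_predict_core(vcv_matrix(pool), traits_a[obs], new)
    } else {
      do.call(rbind, lapply(new, function(b)
        predict_tip(pool, traits_a[obs], b, jitter = jitter)))
    }
  } else NULL
  out <- lapply(tips_b, function(b) {
    if (b %in% obs) {
      data.frame(tip = b, predicted = unname(traits_a[b]), se = 0,
                 n_observed_used = 1L, method = "observed-substitution",
                 stringsAsFactors = FALSE)
    } else {
      p <- phylo_preds[phylo_preds$tip == b, ]
      p$method <- "phylogeny"
      p
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-community prediction accuracy
#'
#' Squared Pearson correlation between predicted and observed trait values
#' over the target community's tips.
#'
#' @param predicted numeric vector of predictions (or the data frame returned
#'   by [cross_predict()], whose `predicted` column is used, matched by tip).
#' @param observed named numeric vector of the target community's observed
#'   values.
#' @return R-squared (numeric scalar).
#' @export
cross_accuracy <- function(predicted, observed) {
  if (is.data.frame(predicted)) {
    common <- intersect(predicted$tip, names(observed))
    pred <- predicted$predicted[match(common, predicted$tip)]
    obs <- observed[common]
  } else {
    if (length(predicted) != length(observed))
      stop("'predicted' and 'observed' lengths differ")
    pred <- predicted; obs <- observed
  }
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(pred) < 3L) stop("need at least 3 tips with prediction and observation")
  if (stats::var(pred) == 0 || stats::var(obs) == 0)
    stop("zero variance; R-squared undefined")
  stats::cor(pred, obs)^2
}

#' Full cross-community comparison for one ordered pair
#'
#' Convenience wrapper running the shared-node, ancestral-correlation and
#' cross-prediction steps for one ordered (predictor, target) community pair:
#' ancestral states are estimated on each community's own pruned tree,
#' correlated at shared nodes, and the predictor's observations are used to
#' predict every target tip.
#'
#' @param master master `"phylo"` tree.
#' @param traits_a predictor community's observed traits (named vector).
#' @param traits_b target community's observed traits (named vector).
#' @inheritParams fit_bm
#' @return list with `shared_node_ids`, `r`, `r_p_value`, `n_shared_nodes`,
#'   `predictions` (data frame), `r_squared`, `n_substituted`,
#'   `n_phylogeny`.
#' @export
cross_pair <- function(master, traits_a, traits_b, jitter = FALSE) {
  master <- as_phylopred_tree(master)
  tips_a <- intersect(names(traits_a), master$tip.label)
  tips_b <- intersect(names(traits_b), master$tip.label)
  shared <- shared_nodes(master, tips_a, tips_b)
  est_a <- ancestral_estimates(prune_to_tips(master, tips_a), traits_a, jitter = jitter)
  est_b <- ancestral_estimates(prune_to_tips(master, tips_b), traits_b, jitter = jitter)
  corr <- if (length(shared) >= 3L)
    ancestral_correlation(est_a, est_b, shared) else list(r = NA_real_, p_value = NA_real_, n = length(shared))
  preds <- cross_predict(master, traits_a, tips_b, jitter = jitter)
  list(shared_node_ids = shared,
       r = corr$r, r_p_value = corr$p_value, n_shared_nodes = corr$n,
       predictions = preds,
       r_squared = cross_accuracy(preds, traits_b),
       n_substituted = sum(preds$method == "observed-substitution"),
       n_phylogeny = sum(preds$method == "phylogeny"))
}
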