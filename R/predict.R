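#' Predict the trait of one unobserved tip by pruning and rerooting
#'
#' Implements the hidden-tip procedure for continuous traits: the tree is
#' pruned to the observed tips plus the single target tip, rerooted at the
#' target's parent node, and the generalized-least-squares (REML) estimate of
#' the trait at the root of this rearranged tree — computed from the observed
#' tips only — is the prediction. This equals the best linear unbiased
#' predictor \eqn{\hat a + V_{to} V_{oo}^{-1} (x - \hat a 1)} under Brownian
#' motion with the GLS plug-in mean. The squared standard error is the
#' prediction variance at the rearranged root plus \eqn{\hat\sigma^2} times
#' the target's terminal branch length.
#'
#' @param tree a rooted `"phylo"` object containing the target tip and all
#'   observed tips (extra tips are pruned away).
#' @param traits named numeric vector of observed trait values; must not
#'   include the target.
#' @param target tip label to predict.
#' @inheritParams fit_bm
#' @return a one-row data frame: `tip`, `predicted`, `se`, `n_observed_used`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' predict_tip(tr, c(A = 0.1, B = 0.12, C = 0.3), "D")
#' @export
predict_tip <- function(tree, traits, target, jitter = FALSE) {
  tree <- as_phylopred_tree(tree)
  stopifnot(length(target) == 1L)
  if (!target %in% tree$tip.label) stop("target tip not in tree: ", target)
  traits <- traits[!is.na(traits)]
  obs <- intersect(names(traits), tree$tip.label)
  if (target %in% obs) stop("target tip already has an observed value: ", target)
  if (length(obs) < 2L) stop("need at least 2 observed tips")
  pruned <- prune_to_tips(tree, c(obs, target))
  .predict_on_tree(pruned, traits[obs], target, jitter = jitter)
}

# Dense conditional-Gaussian route: predictions for several targets given the
# same observed set, from one covariance matrix. Algebraically identical to
# the prune/reroot construction of predict_tip (the BLUP identity); used as a
# fast path where many predictions share the observed set. V must cover
# observed + targets; x named by the observed tips.
.blup_predict_core <- function(V, x, targets) {
  obs <- names(x)
  Vi <- chol2inv(chol(V[obs, obs, drop = FALSE]))
  w <- colSums(Vi)
  denom <- sum(w)
  a <- sum(w * x) / denom
  n <- length(x)
  sigma2 <- drop(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  B <- V[targets, obs, drop = FALSE] %*% Vi
  pred <- a + drop(B %*% (x - a))
  condvar <- diag(V)[targets] - rowSums(B * V[targets, obs, drop = FALSE])
  meanterm <- (1 - rowSums(B))^2 / denom
  data.frame(tip = targets, predicted = unname(pred),
             se = sqrt(pmax(sigma2 * (condvar + meanterm), 0)),
             n_observed_used = n, stringsAsFactors = FALSE)
}

# prediction on a tree already pruned to observed + target
.predict_on_tree <- function(pruned, x, target, jitter = FALSE) {
  pruned <- .check_terminal_branches(pruned, jitter = jitter)
  parent <- .parent_of_tip(pruned, target)
  parent_id <- pruned$node.label[parent - length(pruned$tip.label)]
  rt <- if (parent == .root_node(pruned)) pruned else
    reroot_at_node(pruned, parent_id)
  t_target <- rt$edge.length[rt$edge[, 2L] == match(target, rt$tip.label)]
  # remove the target but keep the root where it is (the target's parent):
  # the unifurcation left behind is handled natively by the pruning pass
  obs_tree <- ape::drop.tip(rt, target, collapse.singles = FALSE)
  up <- .bm_uppass(obs_tree, x)
  n <- length(x)
  sigma2 <- up$ss / (n - 1)
  data.frame(tip = target,
             predicted = up$root_mean,
             se = sqrt(sigma2 * (up$root_v + t_target)),
             n_observed_used = n,
             stringsAsFactors = FALSE)
}

#' Within-community validation by replicated tip exclusion
#'
#' Scores phylogeny-based trait prediction inside one community: in each
#' replicate, `round(fraction * n)` tips (at least one) are excluded uniformly
#' at random, and each excluded tip is predicted with [predict_tip()] using
#' only the non-excluded tips (one target at a time, never two unobserved tips
#' in the same pruned tree). Accuracy is the squared Pearson correlation
#' between per-taxon mean predictions (over the replicates in which each taxon
#' was excluded) and observed values.
#'
#' @inheritParams fit_bm
#' @param fraction fraction of tips excluded per replicate, in (0, 1).
#' @param reps number of replicates.
#' @param seed RNG seed; each replicate runs on a deterministic sub-seed drawn
#'   from it, so results are reproducible and replicate r is independent of
#'   the total replicate count.
#' @param keep_replicates if `TRUE`, the returned object additionally carries
#'   a `replicates` data frame with every per-replicate prediction (replicate
#'   index, sub-seed, excluded tip, predicted value).
#' @param method `"blup"` (default) evaluates each excluded tip's prediction
#'   through the dense conditional-Gaussian identity, sharing one covariance
#'   matrix across replicates; `"reroot"` runs the literal prune-and-reroot
#'   procedure per tip. The two are algebraically identical (and tested to
#'   agree); `"blup"` is much faster at validation scale.
#' @return an object of class `"exclusion_validation"`: list with `r_squared`,
#'   `per_taxon` (data frame: `tip`, `observed`, `mean_predicted`,
#'   `n_excluded`), `reps`, `fraction`, `n_excluded_per_rep`, `seed`.
#' @export
exclusion_validation <- function(tree, traits, fraction = 0.2, reps = 1000,
                                 seed = NULL, jitter = FALSE,
                                 keep_replicates = FALSE,
                                 method = c("blup", "reroot")) {
  method <- match.arg(method)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  tree <- as_phylopred_tree(tree)
  x <- .check_traits(prune_to_tips(tree, intersect(tree$tip.label, names(traits))),
                     traits, require_variance = TRUE)
  comm <- prune_to_tips(tree, names(x))
  n <- length(x)
  if (n < 5L) stop("need at least 5 observed tips")
  m <- max(1L, round(fraction * n))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  pred_sum <- stats::setNames(numeric(n), names(x))
  pred_n <- stats::setNames(integer(n), names(x))
  replicates <- if (keep_replicates) vector("list", reps) else NULL
  comm_checked <- .check_terminal_branches(comm, jitter = jitter)
  Vfull <- if (method == "blup") vcv_matrix(comm_checked) else NULL
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    excl <- sample(names(x), m)
    keep_x <- x[setdiff(names(x), excl)]
    if (method == "blup") {
      preds <- .blup_predict_core(Vfull, keep_x, excl)$predicted
    } else {
      preds <- vapply(excl, function(t) {
        sub <- if (m > 1L) ape::drop.tip(comm, setdiff(excl, t)) else comm
        .predict_on_tree(sub, keep_x, t, jitter = jitter)$predicted
      }, numeric(1))
    }
    pred_sum[excl] <- pred_sum[excl] + preds
    pred_n[excl] <- pred_n[excl] + 1L
    if (keep_replicates)
      replicates[[r]] <- data.frame(replicate = r, seed = rep_seeds[r],
                                    tip = excl, predicted = unname(preds),
                                    stringsAsFactors = FALSE)
  }
  used <- pred_n > 0L
  if (!all(used))
    warning(sum(!used), " tip(s) never excluded in any replicate; ",
            "dropped from the accuracy regression")
  mean_pred <- pred_sum[used] / pred_n[used]
  r2 <- stats::cor(mean_pred, x[used])^2
  structure(list(
    r_squared = unname(r2),
    per_taxon = data.frame(tip = names(x)[used], observed = unname(x[used]),
                           mean_predicted = unname(mean_pred),
                           n_excluded = unname(pred_n[used]),
                           stringsAsFactors = FALSE),
    reps = reps, fraction = fraction, n_excluded_per_rep = m, seed = seed,
    method = method,
    replicates = if (keep_replicates) do.call(rbind, replicates) else NULL
  ), class = "exclusion_validation")
}

#' @export
print.exclusion_validation <- function(x, ...) {
  cat(sprintf("Tip-exclusion validation: R^2 = %.4g\n", x$r_squared))
  cat(sprintf("  %d replicates, %d of %d tips excluded per replicate (fraction %.2g)\n",
              x$reps, x$n_excluded_per_rep, nrow(x$per_taxon), x$fraction))
  invisible(x)
}

#' Ordinary least-squares trend of prediction accuracy on a predictor
#'
#' Regresses accuracy values (e.g. exclusion-validation or cross-community
#' R-squared) on a predictor (Blomberg's K, or the ancestral-estimate
#' correlation r of community pairs) and reports the slope, its two-sided
#' p-value, and the fit's coefficient of determination.
#'
#' @param x numeric predictor (length >= 3, non-constant).
#' @param y numeric response, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
trend_regression <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = length(x))
}
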