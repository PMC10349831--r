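#' Run the full phylogeny-based trait-prediction analysis
#'
#' Orchestrates the whole workflow for a master tree and a multi-community
#' trait table: per community-condition cell it quantifies phylogenetic
#' signal (Blomberg's K with permutation p), estimates ancestral states, and
#' scores within-community prediction by tip-exclusion validation; per
#' ordered community pair and condition it computes shared ancestral nodes,
#' the correlation of ancestral estimates at those nodes, and cross-community
#' prediction accuracy; finally it fits the two meta-regressions (accuracy on
#' K; cross-accuracy on r). Cross-prediction is directional, so both
#' orderings of every pair are emitted.
#'
#' Five TSV files are written to `out_dir` as stages complete (partial output
#' is retained if a later stage fails): `signal_table.tsv`,
#' `ancestral_estimates.tsv`, `within_validation.tsv`, `cross_pairs.tsv`,
#' `meta_regressions.tsv`, plus a `run.log` recording package version, master
#' seed and per-stage sub-seeds. All randomness descends deterministically
#' from `seed`, so a rerun of the same configuration reproduces identical
#' files.
#'
#' @param config a named list, or the path to a YAML file, with entries:
#'   `tree` (Newick path or `"phylo"` object), `traits` (TSV path or data
#'   frame with `otu_id`/`community`/`condition`/`trait`), `out_dir`,
#'   `seed`, and optionally `communities`, `conditions` (selectors;
#'   default all), `fraction` (exclusion fraction, default 0.2), `reps`
#'   (exclusion replicates, default 1000), `nperm` (signal permutations,
#'   default 999), `jitter` (default `FALSE`).
#' @return invisibly, a list with the five result data frames and the output
#'   paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (field in c("tree", "traits", "out_dir", "seed"))
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  fraction <- config$fraction %||% 0.2
  reps <- config$reps %||% 1000L
  nperm <- config$nperm %||% 999L
  jitter <- isTRUE(config$jitter)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  master <- if (is.character(config$tree)) read_newick(config$tree)
            else as_phylopred_tree(config$tree)
  tab <- if (is.character(config$traits)) read_trait_table(config$traits)
         else config$traits
  communities <- config$communities %||% unique(tab$community)
  conditions <- config$conditions %||% unique(tab$condition)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  logline("phylopred %s | %s", as.character(utils::packageVersion("phylopred")),
          R.version.string)
  logline("master seed: %d", as.integer(config$seed))
  set.seed(config$seed)
  cells <- expand.grid(community = communities, condition = conditions,
                       stringsAsFactors = FALSE)
  cell_seed_k <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  cell_seed_v <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logline("stage %-18s ok (%.1fs)", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  xs <- lapply(seq_len(nrow(cells)), function(k) {
    x <- trait_vector(tab, cells$community[k], cells$condition[k])
    x[intersect(names(x), master$tip.label)]
  })

  signal <- stage("signal", {
    rows <- lapply(seq_len(nrow(cells)), function(k) {
      x <- xs[[k]]
      tr <- prune_to_tips(master, names(x))
      sig <- blomberg_k(tr, x, nperm = nperm, seed = cell_seed_k[k],
                        jitter = jitter)
      data.frame(community = cells$community[k], condition = cells$condition[k],
                 n_tips = sig$n, K = sig$K, p_value = sig$p_value,
                 n_permutations = sig$n_permutations, seed = cell_seed_k[k],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    .write_tsv(df, file.path(out_dir, "signal_table.tsv"))
    df
  })

  ancestral <- stage("ancestral", {
    rows <- lapply(seq_len(nrow(cells)), function(k) {
      x <- xs[[k]]
      tr <- prune_to_tips(master, names(x))
      est <- ancestral_estimates(tr, x, jitter = jitter)
      est$community <- cells$community[k]
      est$condition <- cells$condition[k]
      est
    })
    df <- do.call(rbind, rows)
    .write_tsv(df, file.path(out_dir, "ancestral_estimates.tsv"))
    df
  })

  within <- stage("within_validation", {
    rows <- lapply(seq_len(nrow(cells)), function(k) {
      x <- xs[[k]]
      val <- exclusion_validation(master, x, fraction = fraction, reps = reps,
                                  seed = cell_seed_v[k], jitter = jitter)
      data.frame(community = cells$community[k], condition = cells$condition[k],
                 n_tips = nrow(val$per_taxon), r_squared = val$r_squared,
                 reps = reps, fraction = fraction, seed = cell_seed_v[k],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    .write_tsv(df, file.path(out_dir, "within_validation.tsv"))
    df
  })

  cross <- stage("cross_prediction", {
    if (length(communities) < 2L) {
      df <- data.frame()
    } else {
      pairs <- expand.grid(predictor = communities, target = communities,
                           condition = conditions, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$predictor != pairs$target, ]
      rows <- lapply(seq_len(nrow(pairs)), function(k) {
        ka <- which(cells$community == pairs$predictor[k] &
                    cells$condition == pairs$condition[k])
        kb <- which(cells$community == pairs$target[k] &
                    cells$condition == pairs$condition[k])
        xa <- xs[[ka]]; xb <- xs[[kb]]
        cp <- cross_pair(master, xa, xb, jitter = jitter)
        data.frame(predictor = pairs$predictor[k], target = pairs$target[k],
                   condition = pairs$condition[k],
                   n_shared_tips = length(intersect(names(xa), names(xb))),
                   n_shared_nodes = cp$n_shared_nodes,
                   r = cp$r, r_p_value = cp$r_p_value,
                   r_squared = cp$r_squared,
                   n_substituted = cp$n_substituted,
                   n_phylogeny = cp$n_phylogeny,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
    }
    .write_tsv(df, file.path(out_dir, "cross_pairs.tsv"))
    df
  })

  meta <- stage("meta_regressions", {
    rows <- list()
    fit1 <- tryCatch(trend_regression(signal$K, within$r_squared),
                     error = function(e) NULL)
    if (!is.null(fit1))
      rows[[1L]] <- data.frame(response = "within_r_squared", predictor = "K",
                               slope = fit1$slope, intercept = fit1$intercept,
                               r_squared = fit1$r_squared,
                               p_value = fit1$p_value, n = fit1$n,
                               stringsAsFactors = FALSE)
    if (nrow(cross)) {
      fit2 <- tryCatch(trend_regression(cross$r, cross$r_squared),
                       error = function(e) NULL)
      if (!is.null(fit2))
        rows[[length(rows) + 1L]] <-
          data.frame(response = "cross_r_squared", predictor = "r",
                     slope = fit2$slope, intercept = fit2$intercept,
                     r_squared = fit2$r_squared, p_value = fit2$p_value,
                     n = fit2$n, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    .write_tsv(df, file.path(out_dir, "meta_regressions.tsv"))
    df
  })

  logline("done: %d cells, %d cross pairs", nrow(cells),
          if (is.null(nrow(cross))) 0L else nrow(cross))
  invisible(list(signal = signal, ancestral = ancestral, within = within,
                 cross = cross, meta = meta, out_dir = out_dir,
                 paths = file.path(out_dir, c(
                   "signal_table.tsv", "ancestral_estimates.tsv",
                   "within_validation.tsv", "cross_pairs.tsv",
                   "meta_regressions.tsv", "run.log"))))
}
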