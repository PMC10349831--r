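#' Read a tab-separated trait table
#'
#' Expects columns `otu_id`, `community`, `condition`, and either a single
#' `trait` column or replicate columns `trait_rep1`, `trait_rep2`, ...
#' Replicate columns are averaged per row (ignoring `NA`), matching the
#' convention that analyses operate on per-taxon mean trait values.
#'
#' @param path path to a TSV file.
#' @return data frame with columns `otu_id`, `community`, `condition`,
#'   `trait`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("otu_id", "community", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing column(s): ", paste(miss, collapse = ", "))
  if (!"trait" %in% names(df)) {
    reps <- grep("^trait_rep", names(df), value = TRUE)
    if (!length(reps))
      stop("trait table needs a 'trait' column or 'trait_rep*' columns")
    df$trait <- rowMeans(df[reps], na.rm = TRUE)
  }
  df[c("otu_id", "community", "condition", "trait")]
}

#' Extract one community-condition trait vector from a trait table
#'
#' @param table data frame as returned by [read_trait_table()] (or the
#'   `table` element of a [simulate_scenario()] result).
#' @param community,condition cell selectors.
#' @return named numeric vector (names = `otu_id`). Duplicated `otu_id`
#'   entries within the cell are averaged.
#' @export
trait_vector <- function(table, community, condition) {
  sub <- table[table$community == community & table$condition == condition, ]
  if (!nrow(sub)) stop("no rows for community '", community,
                       "', condition '", condition, "'")
  v <- tapply(sub$trait, sub$otu_id, mean)
  stats::setNames(as.numeric(v), names(v))
}

# write a TSV at full numeric precision
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
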