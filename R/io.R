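# Readers and writers for the normalized TSV dialect used by the pipeline.
# All on-disk tables are tab-separated with a header row; set-valued cells are
# ";"-delimited. Parsers validate eagerly and never silently drop rows: every
# input row is either returned, collapsed as a logged duplicate, or raises a
# format error naming the offending row.

#' Interaction layer tags
#'
#' The three interaction layers of the integrated gene network: undirected
#' protein physical interactions, directed enzyme-enzyme metabolic
#' interactions, and directed transcription-factor to target regulatory
#' interactions.
#'
#' @return Character vector of the three layer tags.
#' @export
interaction_layers <- function() c("ppi", "metabolic", "regulatory")

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_format("%s: file not found: %s", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_format("%s: missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  df
}

#' Canonicalize interaction records
#'
#' Orders the endpoints of undirected ppi edges so that `source <= target`
#' lexicographically, then collapses duplicate (source, target, layer) rows.
#' Directed layers are left as-is apart from deduplication.
#'
#' @param df data.frame with columns source, target, layer.
#' @return Deduplicated data.frame with attribute `n_collapsed` giving the
#'   number of rows removed as duplicates.
#' @export
canonicalize_interactions <- function(df) {
  stopifnot(all(c("source", "target", "layer") %in% names(df)))
  swap <- df$layer == "ppi" & df$source > df$target
  if (any(swap)) {
    tmp <- df$source[swap]
    df$source[swap] <- df$target[swap]
    df$target[swap] <- tmp
  }
  key <- paste(df$source, df$target, df$layer, sep = "\r")
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- sum(!keep)
  out
}

#' Read an interaction edge list
#'
#' Reads a TSV with columns `source`, `target`, `layer`; validates layer tags,
#' canonicalizes ppi edges (order-insensitive) and collapses duplicates.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns source, target, layer; one row per unique
#'   interaction. Attribute `n_collapsed` counts collapsed duplicate rows.
#' @examples
#' read_interactions(system.file("extdata", "interactions.tsv",
#'                               package = "morbnet"))
#' @export
read_interactions <- function(path) {
  df <- read_tsv_checked(path, c("source", "target", "layer"), "interactions")
  bad_layer <- which(!df$layer %in% interaction_layers())
  if (length(bad_layer) > 0L)
    stop_format("interactions: unknown layer tag '%s' at row %d",
                df$layer[bad_layer[1L]], bad_layer[1L])
  empty <- which(!nzchar(df$source) | !nzchar(df$target))
  if (length(empty) > 0L)
    stop_format("interactions: empty source or target at row %d", empty[1L])
  out <- canonicalize_interactions(df[, c("source", "target", "layer")])
  if (attr(out, "n_collapsed") > 0L)
    message(sprintf("read_interactions: collapsed %d duplicate row(s)",
                    attr(out, "n_collapsed")))
  out
}

split_set <- function(x) {
  v <- strsplit(x, ";", fixed = TRUE)
  lapply(v, function(s) unique(trimws(s[nzchar(trimws(s))])))
}

#' Read a stoichiometric reaction table
#'
#' Reads a TSV with columns `reaction_id`, `genes`, `reactants`, `products`.
#' Set-valued cells are ";"-delimited. The genes field may be empty
#' (a spontaneous reaction); reactants and products must be non-empty.
#'
#' @param path path to the TSV file.
#' @return data.frame with character `reaction_id` and list-columns `genes`,
#'   `reactants`, `products`.
#' @examples
#' rx <- read_reactions(system.file("extdata", "reactions.tsv",
#'                                  package = "morbnet"))
#' derive_metabolic_interactions(rx)
#' @export
read_reactions <- function(path) {
  df <- read_tsv_checked(path, c("reaction_id", "genes", "reactants",
                                 "products"), "reactions")
  genes <- split_set(df$genes)
  reactants <- split_set(df$reactants)
  products <- split_set(df$products)
  n_r <- lengths(reactants)
  n_p <- lengths(products)
  if (any(n_r == 0L))
    stop_format("reactions: empty reactants at row %d", which(n_r == 0L)[1L])
  if (any(n_p == 0L))
    stop_format("reactions: empty products at row %d", which(n_p == 0L)[1L])
  out <- data.frame(reaction_id = df$reaction_id, stringsAsFactors = FALSE)
  out$genes <- genes
  out$reactants <- reactants
  out$products <- products
  out
}

#' Read gene localization annotations
#'
#' Reads a TSV with columns `gene`, `term`; duplicates are collapsed.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns gene, term.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("gene", "term"), "annotations")
  if (nrow(df) == 0L)
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  empty <- which(!nzchar(df$gene))
  if (length(empty) > 0L)
    stop_format("annotations: empty gene at row %d", empty[1L])
  empty_t <- which(!nzchar(df$term))
  if (length(empty_t) > 0L)
    stop_format("annotations: empty term at row %d", empty_t[1L])
  out <- df[!duplicated(paste(df$gene, df$term, sep = "\r")),
            c("gene", "term"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-by-tissue expression matrix
#'
#' Reads a TSV whose first column is `gene` followed by exactly `n_tissues`
#' numeric columns of non-negative tpm values.
#'
#' @param path path to the TSV file.
#' @param n_tissues expected number of tissue columns (default 32).
#' @return data.frame with a `gene` column and `n_tissues` numeric columns.
#' @export
read_expression <- function(path, n_tissues = 32L) {
  stopifnot(n_tissues >= 1L)
  df <- read_tsv_checked(path, "gene", "expression")
  if (ncol(df) != n_tissues + 1L)
    stop_format("expression: expected %d tissue columns, found %d",
                n_tissues, ncol(df) - 1L)
  vals <- df[, -match("gene", names(df)), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v))
      stop_format("expression: non-numeric value in column '%s' at row %d",
                  names(vals)[j], which(is.na(v))[1L])
    if (any(v < 0))
      stop_format("expression: negative value in column '%s' at row %d",
                  names(vals)[j], which(v < 0)[1L])
    vals[[j]] <- v
  }
  out <- cbind(data.frame(gene = df$gene, stringsAsFactors = FALSE), vals)
  rownames(out) <- NULL
  out
}

#' Read a label list
#'
#' Reads a plain text file with one gene identifier per line (blank lines
#' ignored, duplicates collapsed).
#'
#' @param path path to the file.
#' @return Character vector of gene identifiers.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format("labels: file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

score_columns <- c("gene", "normal_median", "normal_min", "normal_max",
                   "shuffled_median", "shuffled_min", "shuffled_max",
                   "N", "W", "significant")

#' Write a gene score table
#'
#' Writes the genome-wide score table as TSV, sorted by normal median score
#' descending with ties broken by gene identifier ascending.
#'
#' @param table data.frame as returned by [score_genome_wide()].
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
write_scores <- function(table, path) {
  missing <- setdiff(score_columns, names(table))
  if (length(missing) > 0L)
    stop_format("scores: missing column(s): %s", paste(missing, collapse = ", "))
  tab <- table[, score_columns, drop = FALSE]
  tab <- tab[order(-tab$normal_median, tab$gene), , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_format("scores: cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a gene score table written by [write_scores()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the score-table columns.
#' @export
read_scores <- function(path) {
  df <- read_tsv_checked(path, score_columns, "scores")
  for (col in setdiff(score_columns, c("gene", "significant")))
    df[[col]] <- as.numeric(df[[col]])
  df$significant <- as.logical(df$significant)
  df[, score_columns, drop = FALSE]
}
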