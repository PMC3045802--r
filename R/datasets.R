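# Construction of the balanced training datasets: normal (known positives
# plus an equal-size random sample of unlabeled genes), shuffled-label null
# counterparts, and without-one-feature ablations.

dataset_provenance <- function(dataset) attr(dataset, "provenance")

make_dataset <- function(rows, provenance) {
  rownames(rows) <- NULL
  structure(rows, provenance = provenance, class = c("labeled_dataset",
                                                     "data.frame"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  p <- dataset_provenance(x)
  cat(sprintf(
    "Balanced %s dataset (%s), replicate %s: %d rows (%d positive), %d attributes\n",
    p$task %||% "?", p$variant %||% "?", p$replicate %||% "?",
    nrow(x), sum(x$label == "positive"),
    ncol(x) - 2L))
  if (!is.null(p$ablated) && !is.na(p$ablated))
    cat(sprintf("  ablated feature: %s\n", p$ablated))
  invisible(x)
}

#' Build balanced training datasets
#'
#' Creates `n_replicates` balanced datasets. Each one contains all positive
#' genes plus an equal-size uniform sample (without replacement, drawn
#' independently per replicate) of the remaining genes labelled negative --
#' the positive/unlabeled assumption: every gene not on the positive list is
#' treated as a de facto negative. Replicate seeds are derived
#' deterministically from `seed` via [derive_seed()].
#'
#' @param matrix feature matrix from [assemble_feature_matrix()].
#' @param positives character vector of positive gene identifiers (must be a
#'   subset of the matrix genes).
#' @param n_replicates number of datasets (default 10).
#' @param seed master integer seed.
#' @param task label for provenance, e.g. "morbidity" or "druggability".
#' @return List of `labeled_dataset` objects (data.frames with columns gene,
#'   label, and the feature columns), each with a `provenance` attribute.
#' @export
build_balanced_datasets <- function(matrix, positives, n_replicates = 10L,
                                    seed = 1L, task = "morbidity") {
  positives <- unique(as.character(positives))
  if (!all(positives %in% matrix$gene))
    stop("positives contains genes absent from the feature matrix",
         call. = FALSE)
  pool <- setdiff(matrix$gene, positives)
  if (length(pool) < length(positives))
    stop(sprintf(
      "negative pool (%d genes) smaller than the positive set (%d)",
      length(pool), length(positives)), call. = FALSE)
  lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed, r)
    neg <- with_seed(rs, sample(pool, length(positives), replace = FALSE))
    rows <- matrix[match(c(positives, neg), matrix$gene), , drop = FALSE]
    out <- data.frame(gene = rows$gene,
                      label = factor(rep(c("positive", "negative"),
                                         each = length(positives)),
                                     levels = c("negative", "positive")),
                      stringsAsFactors = FALSE, check.names = FALSE)
    feats <- setdiff(names(rows), "gene")
    out[feats] <- rows[, feats, drop = FALSE]
    make_dataset(out, list(task = task, variant = "normal", replicate = r,
                           seed = rs, ablated = NA_character_))
  })
}

#' Shuffle the class labels of a dataset
#'
#' Permutes the label column uniformly at random over the same rows; the
#' features are untouched and class counts are preserved. This is the null
#' condition: a classifier trained on shuffled labels can only learn traits of
#' random gene subsets.
#'
#' @param dataset a `labeled_dataset`.
#' @param seed integer seed for the permutation.
#' @return The shuffled `labeled_dataset` (variant set to "shuffled").
#' @export
shuffle_dataset_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  perm <- with_seed(seed, sample.int(nrow(dataset)))
  out <- dataset
  out$label <- dataset$label[perm]
  p <- dataset_provenance(dataset)
  p$variant <- "shuffled"
  p$shuffle_seed <- seed
  make_dataset(out, p)
}

#' Remove one learning attribute from datasets
#'
#' Drops the named feature column from each dataset, producing the
#' without-one-feature ablation family used to measure the contribution of an
#' individual attribute.
#'
#' @param datasets a `labeled_dataset` or list of them.
#' @param feature name of an attribute column to drop.
#' @return Same shape as the input, with the column removed and
#'   `ablated_feature` recorded in the provenance.
#' @export
ablate_feature <- function(datasets, feature) {
  single <- inherits(datasets, "labeled_dataset")
  if (single) datasets <- list(datasets)
  out <- lapply(datasets, function(d) {
    if (!feature %in% setdiff(names(d), c("gene", "label")))
      stop(sprintf("unknown feature column: '%s'", feature), call. = FALSE)
    p <- dataset_provenance(d)
    p$ablated <- feature
    make_dataset(d[, setdiff(names(d), feature), drop = FALSE], p)
  })
  if (single) out[[1L]] else out
}
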