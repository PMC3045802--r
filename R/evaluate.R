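# Classifier evaluation: recall / precision / AUC, stratified k-fold
# cross-validation, replicate summaries, paired condition comparison by the
# exact Wilcoxon signed-rank test, genome-wide probability scoring, and the
# score-histogram summary.

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "positive")
  as.numeric(labels) == 1
}

#' Recall, precision and AUC of probability predictions
#'
#' Recall = TP / (TP + FN) and precision = TP / (TP + FP) at the given
#' probability threshold. The AUC is the rank statistic with half credit for
#' ties -- the probability that a randomly chosen positive receives a higher
#' probability than a randomly chosen negative (Mann-Whitney formulation).
#'
#' @param labels binary labels ("positive"/"negative" or 0/1).
#' @param probabilities positive-class probabilities, same length.
#' @param threshold classification threshold (default 0.5).
#' @return Object of class `eval_result`: list with recall, precision, auc
#'   and the TP/FP/FN/TN confusion counts.
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  pos <- as_binary_labels(labels)
  if (all(pos) || !any(pos))
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  pred <- probabilities >= threshold
  tp <- sum(pos & pred)
  fp <- sum(!pos & pred)
  fn <- sum(pos & !pred)
  tn <- sum(!pos & !pred)
  r <- rank(probabilities)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(recall = tp / (tp + fn),
                 precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
                 auc = auc, TP = tp, FP = fp, FN = fn, TN = tn),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("recall %.3f  precision %.3f  AUC %.3f\n",
              x$recall, x$precision, x$auc))
  invisible(x)
}

stratified_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validate the voting meta-classifier on one dataset
#'
#' Stratified k-fold cross-validation: each row is held out exactly once; the
#' per-fold recall, precision and AUC are averaged into a single evaluation
#' result for the dataset.
#'
#' @param dataset a `labeled_dataset`.
#' @param config an [vote_control()] configuration.
#' @param folds number of folds (default 10).
#' @param seed integer seed driving the fold assignment and member training.
#' @param threshold classification threshold (default 0.5).
#' @param stratify stratify folds by class (default TRUE).
#' @return An `eval_result` with averaged measures; the per-fold table is
#'   attached as `$folds` and the dataset provenance as `$provenance`.
#' @export
cross_validate <- function(dataset, config = vote_control(), folds = 10L,
                           seed = 1L, threshold = 0.5, stratify = TRUE) {
  n <- nrow(dataset)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  y <- factor(as.character(dataset$label), levels = c("negative", "positive"))
  fold_of <- if (stratify) stratified_folds(y, folds, derive_seed(seed, 0L))
             else with_seed(derive_seed(seed, 0L),
                            sample(rep_len(seq_len(folds), n)))
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    test_idx <- which(fold_of == k)
    train <- dataset[-test_idx, , drop = FALSE]
    model <- vote_ensemble(train, config = config,
                           seed = derive_seed(seed, k))
    prob <- predict(model, dataset[test_idx, , drop = FALSE])
    per_fold[[k]] <- evaluate_predictions(y[test_idx], prob,
                                          threshold = threshold)
  }
  fold_tab <- data.frame(fold = seq_len(folds),
                         recall = vapply(per_fold, `[[`, 0, "recall"),
                         precision = vapply(per_fold, `[[`, 0, "precision"),
                         auc = vapply(per_fold, `[[`, 0, "auc"))
  out <- structure(list(recall = mean(fold_tab$recall),
                        precision = mean(fold_tab$precision),
                        auc = mean(fold_tab$auc),
                        TP = sum(vapply(per_fold, `[[`, 0L, "TP")),
                        FP = sum(vapply(per_fold, `[[`, 0L, "FP")),
                        FN = sum(vapply(per_fold, `[[`, 0L, "FN")),
                        TN = sum(vapply(per_fold, `[[`, 0L, "TN")),
                        folds = fold_tab,
                        provenance = attr(dataset, "provenance")),
                   class = "eval_result")
  out
}

#' Median / min / max summary over replicate evaluations
#'
#' @param results list of `eval_result` objects.
#' @param measures measures to summarize.
#' @return data.frame with one row per measure and columns median, min, max.
#' @export
summarize_evals <- function(results,
                            measures = c("recall", "precision", "auc")) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(measures, function(m) {
    v <- vapply(results, `[[`, 0, m)
    data.frame(measure = m, median = stats::median(v), min = min(v),
               max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two evaluation conditions with the Wilcoxon signed-rank test
#'
#' Pairs the per-replicate values of a measure by replicate index (taken from
#' each result's provenance when available, falling back to list order) and
#' applies the exact [wilcoxon_signed_rank()] test.
#'
#' @param normal,other lists of `eval_result` objects, one per replicate.
#' @param measure one of "recall", "precision", "auc".
#' @return A `wilcoxon_sr` result.
#' @export
compare_conditions <- function(normal, other, measure = "auc") {
  if (length(normal) != length(other))
    stop("conditions have different replicate counts", call. = FALSE)
  rep_of <- function(results) {
    idx <- vapply(seq_along(results), function(i) {
      p <- results[[i]]$provenance
      as.integer(p$replicate %||% i)
    }, integer(1L))
    idx
  }
  a <- vapply(normal, `[[`, 0, measure)[order(rep_of(normal))]
  b <- vapply(other, `[[`, 0, measure)[order(rep_of(other))]
  wilcoxon_signed_rank(a, b)
}

#' Genome-wide gene scoring
#'
#' Applies the replicate models trained on the normal datasets and on the
#' shuffled datasets to every gene of the feature matrix (labels removed).
#' Each gene receives its per-replicate positive-class probabilities; the
#' reported score is the median of the normal probabilities, with min/max
#' ranges, and each gene's normal and shuffled score vectors are compared by
#' the exact Wilcoxon signed-rank test over the paired replicates.
#'
#' @param models_normal list of fitted `vote_ensemble` models (normal
#'   condition), one per replicate.
#' @param models_shuffled list of fitted models of the shuffled condition,
#'   same length.
#' @param matrix feature matrix from [assemble_feature_matrix()].
#' @return data.frame (the gene score table) with columns gene,
#'   normal_median/min/max, shuffled_median/min/max, N, W, significant,
#'   sorted by normal_median descending (ties by gene ascending).
#' @export
score_genome_wide <- function(models_normal, models_shuffled, matrix) {
  stopifnot(length(models_normal) >= 1L,
            length(models_normal) == length(models_shuffled))
  pred_all <- function(models) {
    vapply(models, function(m) as.numeric(predict(m, matrix)),
           numeric(nrow(matrix)))
  }
  pn <- pred_all(models_normal)
  ps <- pred_all(models_shuffled)
  if (is.null(dim(pn))) {  # single-gene matrix
    pn <- rbind(pn)
    ps <- rbind(ps)
  }
  res <- lapply(seq_len(nrow(matrix)), function(i)
    wilcoxon_signed_rank(pn[i, ], ps[i, ]))
  out <- data.frame(
    gene = matrix$gene,
    normal_median = apply(pn, 1L, stats::median),
    normal_min = apply(pn, 1L, min),
    normal_max = apply(pn, 1L, max),
    shuffled_median = apply(ps, 1L, stats::median),
    shuffled_min = apply(ps, 1L, min),
    shuffled_max = apply(ps, 1L, max),
    N = vapply(res, `[[`, 0L, "N"),
    W = vapply(res, `[[`, 0, "W"),
    significant = vapply(res, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$normal_median, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of known positives over score bins
#'
#' Bins the normal scores into intervals of `bin_width` partitioning \[0, 1\]
#' and reports, per bin, the percentage of the known positives whose score
#' falls in it. The last bin is closed at 1.
#'
#' @param scores gene score table from [score_genome_wide()].
#' @param known_positives character vector of known positive genes.
#' @param bin_width bin width (default 0.2; must divide 1 evenly).
#' @return data.frame with columns bin_low, bin_high, percent; percents sum
#'   to 100 when any known positive is present.
#' @export
score_histogram <- function(scores, known_positives, bin_width = 0.2) {
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9)
    stop("bin_width must partition [0, 1] evenly", call. = FALSE)
  s <- scores$normal_median[scores$gene %in% known_positives]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  pct <- if (length(s) == 0L) rep(0, n_bins) else 100 * counts / length(s)
  data.frame(bin_low = breaks[-(n_bins + 1L)], bin_high = breaks[-1L],
             percent = pct)
}
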