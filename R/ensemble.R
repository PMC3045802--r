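# The bagged voting meta-classifier: every member is trained on bootstrap
# resamples and the ensemble's positive-class probability is the arithmetic
# mean of its members' (bag-averaged) probabilities -- the "average rule".

#' Configuration of the voting meta-classifier
#'
#' @param members list of member specifications (see [make_member()]);
#'   defaults to the seven-member roster of [default_members()].
#' @param bags bootstrap resamples per member (default 5).
#' @return An `ensemble_config` list.
#' @export
vote_control <- function(members = default_members(), bags = 5L) {
  stopifnot(length(members) >= 1L, bags >= 1L)
  for (m in members) {
    if (!is.list(m) || !all(c("name", "fit", "predict") %in% names(m)))
      stop("each member needs 'name', 'fit' and 'predict'", call. = FALSE)
  }
  structure(list(members = members, bags = as.integer(bags)),
            class = "ensemble_config")
}

dataset_xy <- function(data) {
  stopifnot("label" %in% names(data))
  feats <- setdiff(names(data), c("gene", "label"))
  x <- as.matrix(as.data.frame(lapply(data[feats], as.numeric),
                               check.names = FALSE))
  colnames(x) <- feats
  y <- factor(as.character(data$label), levels = c("negative", "positive"))
  list(x = x, y = y)
}

#' Fit the bagged voting meta-classifier
#'
#' Trains every member of the configuration on `bags` bootstrap resamples of
#' the dataset. Prediction averages the members' positive-class
#' probabilities, each member's probability being the mean over its bags.
#' Deterministic under a fixed seed.
#'
#' @param data a `labeled_dataset` (columns gene, label, features) or any
#'   data.frame with a `label` column of "positive"/"negative" plus numeric
#'   feature columns.
#' @param config an [vote_control()] configuration.
#' @param seed integer seed; per member-bag seeds are derived from it.
#' @return Object of class `vote_ensemble` with predict, print and summary
#'   methods.
#' @export
vote_ensemble <- function(data, config = vote_control(), seed = 1L) {
  if (nrow(data) == 0L) stop("empty training dataset", call. = FALSE)
  stopifnot(inherits(config, "ensemble_config"))
  xy <- dataset_xy(data)
  n <- nrow(xy$x)
  if (nlevels(droplevels(xy$y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  fits <- vector("list", length(config$members))
  for (mi in seq_along(config$members)) {
    member <- config$members[[mi]]
    bag_fits <- vector("list", config$bags)
    for (b in seq_len(config$bags)) {
      s <- derive_seed(seed, mi * 1009L + b)
      idx <- with_seed(s, {
        for (try in 1:50) {
          cand <- sample.int(n, n, replace = TRUE)
          if (length(unique(xy$y[cand])) == 2L) break
        }
        cand
      })
      bag_fits[[b]] <- member$fit(xy$x[idx, , drop = FALSE], xy$y[idx],
                                  seed = s)
    }
    probe <- member$predict(bag_fits[[1L]],
                            xy$x[seq_len(min(4L, n)), , drop = FALSE])
    if (!is.numeric(probe) || anyNA(probe) || any(probe < -1e-9) ||
        any(probe > 1 + 1e-9))
      stop(sprintf("member '%s' does not output class probabilities",
                   member$name), call. = FALSE)
    fits[[mi]] <- bag_fits
  }
  structure(list(fits = fits, config = config,
                 features = colnames(xy$x), n_train = n, seed = seed),
            class = "vote_ensemble")
}

ensemble_matrix <- function(object, newdata) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata,
                                                   check.names = FALSE)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L)
    stop(sprintf("newdata missing feature column(s): %s",
                 paste(utils::head(missing, 3L), collapse = ", ")),
         call. = FALSE)
  x <- as.matrix(as.data.frame(lapply(newdata[object$features], as.numeric),
                               check.names = FALSE))
  colnames(x) <- object$features
  x
}

#' Predict with the voting meta-classifier
#'
#' @param object a fitted `vote_ensemble`.
#' @param newdata data.frame (or matrix) containing the training feature
#'   columns; extra columns are ignored, missing ones are an error.
#' @param type "prob" for the positive-class probability (the average over
#'   members of each member's bag-mean probability) or "class" for hard
#'   labels at `threshold`.
#' @param threshold classification threshold for `type = "class"` (default
#'   0.5).
#' @param members logical; also return the per-member probability matrix as
#'   attribute "members".
#' @param ... unused.
#' @return Numeric probability vector, or character class vector.
#' @export
predict.vote_ensemble <- function(object, newdata, type = c("prob", "class"),
                                  threshold = 0.5, members = FALSE, ...) {
  type <- match.arg(type)
  x <- ensemble_matrix(object, newdata)
  specs <- object$config$members
  member_prob <- matrix(0, nrow(x), length(specs),
                        dimnames = list(NULL,
                                        vapply(specs, `[[`, "", "name")))
  for (mi in seq_along(specs)) {
    bp <- vapply(object$fits[[mi]],
                 function(f) as.numeric(specs[[mi]]$predict(f, x)),
                 numeric(nrow(x)))
    bp <- matrix(bp, nrow = nrow(x))
    member_prob[, mi] <- rowMeans(bp)
  }
  prob <- pmin(pmax(rowMeans(member_prob), 0), 1)
  out <- if (type == "prob") prob else
    ifelse(prob >= threshold, "positive", "negative")
  if (members) attr(out, "members") <- member_prob
  out
}

#' @export
print.vote_ensemble <- function(x, ...) {
  cat(sprintf(
    "Voting meta-classifier: %d members x %d bags, %d training rows\n",
    length(x$config$members), x$config$bags, x$n_train))
  cat("  members:", paste(vapply(x$config$members, `[[`, "", "name"),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vote_ensemble <- function(object, ...) {
  print(object)
  cat(sprintf("  features (%d): %s\n", length(object$features),
              paste(utils::head(object$features, 8L), collapse = ", ")))
  invisible(object)
}
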