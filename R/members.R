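# The seven tree-family member learners of the voting meta-classifier.
# Functional-class fidelity is the contract: each member is a decision-tree
# learner of the named family, realized with rpart / ranger where those cover
# the family, and hand-authored where they do not (the gain-ratio tree and
# the boosted decision stumps).

# rpart wants syntactic column names; rename positionally.
rpart_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df
}

fit_rpart_member <- function(x, y, control, parms = NULL) {
  df <- rpart_frame(x)
  df$.label <- y
  if (is.null(parms))
    rpart::rpart(.label ~ ., data = df, method = "class", control = control)
  else
    rpart::rpart(.label ~ ., data = df, method = "class", control = control,
                 parms = parms)
}

predict_rpart_member <- function(fit, x) {
  pr <- stats::predict(fit, rpart_frame(x), type = "prob")
  if ("positive" %in% colnames(pr)) pr[, "positive"] else rep(0, nrow(x))
}

#' Construct an ensemble member specification
#'
#' A member is a learner that can be fitted on a numeric feature matrix with
#' a binary factor response (levels negative/positive) and predicts the
#' positive-class probability.
#'
#' @param name short member name.
#' @param fit function(x, y, seed) returning a fitted model.
#' @param predict function(fit, x) returning probabilities in \[0, 1\].
#' @return A member specification list.
#' @export
make_member <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  list(name = name, fit = fit, predict = predict)
}

member_reptree <- function() {
  make_member("reptree",
    fit = function(x, y, seed) {
      fit_rpart_member(x, y,
        control = rpart::rpart.control(cp = 0.01, xval = 0L, minsplit = 10L,
                                       minbucket = 2L),
        parms = list(split = "information"))
    },
    predict = predict_rpart_member)
}

member_random_tree <- function() {
  make_member("random_tree",
    fit = function(x, y, seed) {
      k <- max(1L, ceiling(sqrt(ncol(x))))
      js <- with_seed(seed, sample.int(ncol(x), k))
      fit <- fit_rpart_member(x[, js, drop = FALSE], y,
        control = rpart::rpart.control(cp = 0, xval = 0L, minsplit = 4L,
                                       minbucket = 1L))
      list(fit = fit, js = js)
    },
    predict = function(model, x)
      predict_rpart_member(model$fit, x[, model$js, drop = FALSE]))
}

member_random_forest <- function(num_trees = 10L) {
  force(num_trees)
  make_member("random_forest",
    fit = function(x, y, seed) {
      df <- rpart_frame(x)
      ranger::ranger(x = df, y = y, num.trees = num_trees,
                     probability = TRUE, num.threads = 1L, seed = seed)
    },
    predict = function(fit, x) {
      pr <- stats::predict(fit, data = rpart_frame(x),
                           num.threads = 1L)$predictions
      if ("positive" %in% colnames(pr)) pr[, "positive"] else rep(0, nrow(x))
    })
}

member_c45 <- function(min_leaf = 32L) {
  force(min_leaf)
  make_member("c45",
    fit = function(x, y, seed) {
      df <- as.data.frame(x, check.names = FALSE)
      df$label <- y
      c45_tree(df, min_leaf = min_leaf, confidence = 0.25)
    },
    predict = function(fit, x)
      predict(fit, as.data.frame(x, check.names = FALSE), type = "prob"))
}

member_best_first <- function(min_terminal = 32L) {
  force(min_terminal)
  make_member("best_first",
    fit = function(x, y, seed) {
      fit_rpart_member(x, y,
        control = rpart::rpart.control(cp = 0.001, xval = 0L,
                                       minbucket = min_terminal,
                                       minsplit = 2L * min_terminal))
    },
    predict = predict_rpart_member)
}

member_logistic_tree <- function(max_depth = 5L) {
  force(max_depth)
  make_member("logistic_tree",
    fit = function(x, y, seed) {
      tree <- fit_rpart_member(x, y,
        control = rpart::rpart.control(cp = 0.005, xval = 0L,
                                       maxdepth = max_depth))
      p <- predict_rpart_member(tree, x)
      cal <- NULL
      if (stats::sd(p) > 1e-9) {
        y01 <- as.integer(y == "positive")
        cal <- tryCatch(
          suppressWarnings(stats::glm(y01 ~ p,
                                      family = stats::binomial())$coefficients),
          error = function(e) NULL)
        if (!is.null(cal) && anyNA(cal)) cal <- NULL
      }
      list(tree = tree, cal = cal)
    },
    predict = function(model, x) {
      p <- predict_rpart_member(model$tree, x)
      if (is.null(model$cal)) p
      else stats::plogis(model$cal[1L] + model$cal[2L] * p)
    })
}

# --- boosted decision stumps (alternating-decision-tree stand-in) ---------

# AdaBoost.M1 with exhaustive weighted stump search over all features and
# midpoint thresholds; the margin score is mapped to a probability with the
# usual logistic link p = 1 / (1 + exp(-2F)).
fit_boosted_stumps <- function(x, y, rounds = 25L) {
  n <- nrow(x)
  ypm <- ifelse(y == "positive", 1, -1)
  ords <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  w <- rep(1 / n, n)
  stumps <- list()
  for (m in seq_len(rounds)) {
    best <- list(err = Inf)
    for (j in seq_len(ncol(x))) {
      idx <- ords[[j]]
      vs <- x[idx, j]
      wp <- cumsum(w[idx] * (ypm[idx] > 0))
      wn <- cumsum(w[idx] * (ypm[idx] < 0))
      tp <- wp[n]
      tn <- wn[n]
      bounds <- c(0L, which(vs[-n] < vs[-1L]))
      # predict -1 left / +1 right at each boundary (and the reverse)
      left_p <- c(0, wp)[bounds + 1L]
      left_n <- c(0, wn)[bounds + 1L]
      err_a <- left_p + (tn - left_n)
      err_b <- left_n + (tp - left_p)
      k_a <- which.min(err_a)
      k_b <- which.min(err_b)
      cand <- if (err_a[k_a] <= err_b[k_b])
        list(err = err_a[k_a], k = bounds[k_a], pol = 1) else
        list(err = err_b[k_b], k = bounds[k_b], pol = -1)
      if (cand$err < best$err - 1e-12) {
        thr <- if (cand$k == 0L) -Inf else (vs[cand$k] + vs[cand$k + 1L]) / 2
        best <- list(err = cand$err, feature = j, threshold = thr,
                     polarity = cand$pol)
      }
    }
    if (!is.finite(best$err) || best$err >= 0.5 - 1e-9) break
    eps <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- ifelse(x[, best$feature] > best$threshold, 1, -1) * best$polarity
    w <- w * exp(-alpha * ypm * h)
    w <- w / sum(w)
    best$alpha <- alpha
    stumps[[length(stumps) + 1L]] <- best
  }
  stumps
}

predict_boosted_stumps <- function(stumps, x) {
  f <- numeric(nrow(x))
  for (s in stumps)
    f <- f + s$alpha * ifelse(x[, s$feature] > s$threshold, 1, -1) *
      s$polarity
  1 / (1 + exp(-2 * f))
}

member_boosted_stumps <- function(rounds = 25L) {
  force(rounds)
  make_member("boosted_stumps",
    fit = function(x, y, seed) fit_boosted_stumps(x, y, rounds = rounds),
    predict = predict_boosted_stumps)
}

#' The default seven-member roster of the voting meta-classifier
#'
#' Seven tree-family learners: (1) an information-gain pruned tree, (2) a
#' single randomized tree on a random feature subset, (3) a random forest,
#' (4) a gain-ratio tree with a minimum of 32 instances per leaf, (5) a tree
#' with a minimum of 32 instances at terminal nodes, (6) a depth-limited tree
#' with logistic calibration, and (7) 25 rounds of boosted decision stumps.
#'
#' @return List of seven member specifications.
#' @export
default_members <- function() {
  list(member_reptree(), member_random_tree(), member_random_forest(),
       member_c45(), member_best_first(), member_logistic_tree(),
       member_boosted_stumps())
}
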