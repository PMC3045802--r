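# Gain-ratio (C4.5-style) decision-tree induction with error-based pruning,
# and extraction of root-to-leaf cellular rules.
#
# Numeric attributes split binarily at midpoints between distinct adjacent
# values; binary 0/1 flags are displayed as equality tests. Candidate splits
# must leave at least `min_leaf` instances on each side and are scored by
# gain ratio, restricted (as in C4.5) to candidates whose information gain is
# at least the average positive gain. Pruning is bottom-up subtree
# replacement using the pessimistic binomial upper error bound at the given
# confidence.

entropy2 <- function(p) {
  # binary entropy in bits, 0 log 0 = 0 (clamp keeps log finite, the
  # multiplication by 0 then zeroes the term exactly)
  pc <- pmin(pmax(p, 1e-300), 1)
  qc <- pmin(pmax(1 - p, 1e-300), 1)
  -(p * log2(pc) + (1 - p) * log2(qc))
}

# C4.5 pessimistic upper bound on the error rate of a leaf with E errors out
# of N, at confidence cf; predicted errors are N * ucf(E, N, cf).
ucf <- function(e, n, cf) {
  if (n == 0) return(0)
  if (e >= n) return(1)
  stats::qbeta(1 - cf, e + 1, n - e)
}

best_split <- function(x, y_pos, idx, min_leaf) {
  n <- length(idx)
  p_tot <- sum(y_pos[idx])
  h_parent <- entropy2(p_tot / n)
  gain_l <- vector("list", ncol(x))
  gr_l <- vector("list", ncol(x))
  thr_l <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[idx, j]
    ord <- order(v)
    vs <- v[ord]
    cp <- cumsum(y_pos[idx][ord])
    i_all <- which(vs[-n] < vs[-1L])          # distinct-value boundaries
    i_all <- i_all[i_all >= min_leaf & (n - i_all) >= min_leaf]
    if (length(i_all) == 0L) next
    nl <- i_all
    nr <- n - i_all
    pl <- cp[i_all] / nl
    pr <- (p_tot - cp[i_all]) / nr
    gain <- h_parent - (nl / n) * entropy2(pl) - (nr / n) * entropy2(pr)
    keep <- gain > 1e-10
    if (!any(keep)) next
    si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
    i_all <- i_all[keep]
    gain_l[[j]] <- gain[keep]
    gr_l[[j]] <- gain[keep] / si[keep]
    thr_l[[j]] <- (vs[i_all] + vs[i_all + 1L]) / 2
  }
  all_gain <- unlist(gain_l)
  if (length(all_gain) == 0L) return(NULL)
  # C4.5 restriction: only candidates with at least average gain compete
  mean_gain <- mean(all_gain)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    g <- gain_l[[j]]
    if (is.null(g)) next
    ok <- which(g >= mean_gain - 1e-9)
    if (length(ok) == 0L) next
    k <- ok[order(-gr_l[[j]][ok], thr_l[[j]][ok])][1L]
    if (is.null(best) || gr_l[[j]][k] > best$gain_ratio + 1e-12) {
      best <- list(feature = j, threshold = thr_l[[j]][k],
                   gain = g[k], gain_ratio = gr_l[[j]][k])
    }
  }
  best
}

grow_node <- function(x, y_pos, idx, min_leaf, parent_class) {
  n <- length(idx)
  n_pos <- sum(y_pos[idx])
  n_neg <- n - n_pos
  class <- if (n_pos > n_neg) "positive"
           else if (n_neg > n_pos) "negative"
           else parent_class
  leaf <- list(type = "leaf", n = n, n_pos = n_pos, n_neg = n_neg,
               class = class, errors = if (class == "positive") n_neg
                                       else n_pos)
  if (n_pos == 0L || n_neg == 0L || n < 2L * min_leaf) return(leaf)
  sp <- best_split(x, y_pos, idx, min_leaf)
  if (is.null(sp)) return(leaf)
  v <- x[idx, sp$feature]
  left_idx <- idx[v <= sp$threshold]
  right_idx <- idx[v > sp$threshold]
  list(type = "split", n = n, n_pos = n_pos, n_neg = n_neg, class = class,
       feature = sp$feature, threshold = sp$threshold,
       left = grow_node(x, y_pos, left_idx, min_leaf, class),
       right = grow_node(x, y_pos, right_idx, min_leaf, class))
}

prune_node <- function(node, confidence) {
  as_leaf_errors <- min(node$n_pos, node$n_neg)
  if (node$type == "leaf") {
    node$est <- node$n * ucf(node$errors, node$n, confidence)
    return(node)
  }
  node$left <- prune_node(node$left, confidence)
  node$right <- prune_node(node$right, confidence)
  subtree_est <- node$left$est + node$right$est
  leaf_est <- node$n * ucf(as_leaf_errors, node$n, confidence)
  if (leaf_est <= subtree_est + 0.1) {
    return(list(type = "leaf", n = node$n, n_pos = node$n_pos,
                n_neg = node$n_neg, class = node$class,
                errors = as_leaf_errors, est = leaf_est))
  }
  node$est <- subtree_est
  node
}

#' Induce a gain-ratio decision tree
#'
#' Top-down C4.5-style induction on a labelled dataset: binary splits at
#' midpoints of numeric attributes (binary flags reduce to flag = 0 / flag =
#' 1), split selection by gain ratio among candidates with at least average
#' information gain, and bottom-up error-based pruning at the given
#' confidence. Leaves carry (total / incorrect) training counts.
#'
#' @param data a `labeled_dataset` (or data.frame with a `label` column plus
#'   numeric feature columns; a `gene` column is ignored).
#' @param min_leaf minimum instances on each side of a split (default 2).
#' @param confidence pruning confidence (default 0.25); lower prunes harder.
#' @param prune apply error-based pruning (default TRUE).
#' @return Object of class `c45_tree` with print and predict methods.
#' @export
c45_tree <- function(data, min_leaf = 2L, confidence = 0.25, prune = TRUE) {
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  stopifnot("label" %in% names(data), min_leaf >= 1L)
  feats <- setdiff(names(data), c("gene", "label"))
  x <- as.matrix(as.data.frame(lapply(data[feats], as.numeric),
                               check.names = FALSE))
  colnames(x) <- feats
  y_pos <- as.integer(data$label == "positive")
  root <- grow_node(x, y_pos, seq_len(nrow(x)), as.integer(min_leaf),
                    parent_class = "positive")
  if (prune) root <- prune_node(root, confidence)
  binary <- apply(x, 2L, function(v) all(v %in% c(0, 1)))
  structure(list(root = root, features = feats, binary = binary,
                 n = nrow(x), min_leaf = as.integer(min_leaf),
                 confidence = confidence,
                 provenance = attr(data, "provenance")),
            class = "c45_tree")
}

walk_leaves <- function(node, fn, path = list()) {
  if (node$type == "leaf") return(list(fn(node, path)))
  c(walk_leaves(node$left, fn,
                c(path, list(list(node = node, side = "left")))),
    walk_leaves(node$right, fn,
                c(path, list(list(node = node, side = "right")))))
}

n_leaves <- function(tree) {
  length(walk_leaves(tree$root, function(node, path) 1L))
}

#' Root feature of a decision tree
#'
#' @param tree a `c45_tree`.
#' @return The feature name tested at the root, or NA for a single-leaf tree.
#' @export
root_feature <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  if (tree$root$type == "leaf") NA_character_
  else tree$features[tree$root$feature]
}

condition_string <- function(tree, node, side) {
  f <- tree$features[node$feature]
  if (tree$binary[[f]] && isTRUE(all.equal(node$threshold, 0.5))) {
    sprintf("%s = %d", f, if (side == "left") 0L else 1L)
  } else if (side == "left") {
    sprintf("%s <= %g", f, node$threshold)
  } else {
    sprintf("%s > %g", f, node$threshold)
  }
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(sprintf("Gain-ratio decision tree: %d training instances, %d leaves\n",
              x$n, n_leaves(x)))
  rec <- function(node, depth) {
    pad <- strrep("|   ", depth)
    if (node$type == "leaf") {
      cat(sprintf("%s-> %s (%d/%d)\n", pad, node$class, node$n, node$errors))
      return(invisible())
    }
    for (side in c("left", "right")) {
      cat(sprintf("%s%s\n", pad, condition_string(x, node, side)))
      rec(node[[side]], depth + 1L)
    }
  }
  rec(x$root, 0L)
  invisible(x)
}

route_rows <- function(tree, newx) {
  # returns for each row the leaf node reached
  out <- vector("list", nrow(newx))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$type == "leaf") {
      for (i in idx) out[[i]] <<- node
      return(invisible())
    }
    v <- newx[idx, tree$features[node$feature]]
    rec(node$left, idx[v <= node$threshold])
    rec(node$right, idx[v > node$threshold])
  }
  rec(tree$root, seq_len(nrow(newx)))
  out
}

#' Predict from a gain-ratio decision tree
#'
#' @param object a `c45_tree`.
#' @param newdata data.frame containing the tree's feature columns.
#' @param type "class" for hard labels, "prob" for the Laplace-smoothed
#'   positive-class probability of the leaf reached.
#' @param ... unused.
#' @return Character vector of classes or numeric vector of probabilities.
#' @export
predict.c45_tree <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L)
    stop(sprintf("newdata missing feature column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  newx <- as.matrix(as.data.frame(lapply(newdata[object$features],
                                         as.numeric), check.names = FALSE))
  colnames(newx) <- object$features
  leaves <- route_rows(object, newx)
  if (type == "class") {
    vapply(leaves, `[[`, character(1L), "class")
  } else {
    vapply(leaves, function(l) (l$n_pos + 1) / (l$n + 2), numeric(1L))
  }
}

#' Extract root-to-leaf rules from a decision tree
#'
#' One rule per leaf, with conditions in path order, the predicted class, and
#' the leaf's (support / errors) training counts. Supports over all rules sum
#' to the training-set size.
#'
#' @param tree a `c45_tree`.
#' @return Object of class `c45_rules`: list of rules, each with elements
#'   `conditions` (data.frame feature, comparator, value), `class`,
#'   `support`, `errors`.
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  rules <- walk_leaves(tree$root, function(leaf, path) {
    conds <- if (length(path) == 0L) {
      data.frame(feature = character(), comparator = character(),
                 value = numeric(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(path, function(step) {
        data.frame(feature = tree$features[step$node$feature],
                   comparator = if (step$side == "left") "<=" else ">",
                   value = step$node$threshold, stringsAsFactors = FALSE)
      }))
    }
    list(conditions = conds, class = leaf$class, support = leaf$n,
         errors = leaf$errors)
  })
  structure(rules, class = "c45_rules", features = tree$features)
}

#' @export
print.c45_rules <- function(x, ...) {
  cat(sprintf("%d decision rules\n", length(x)))
  for (r in x) {
    lhs <- if (nrow(r$conditions) == 0L) "TRUE" else
      paste(sprintf("%s %s %g", r$conditions$feature,
                    r$conditions$comparator, r$conditions$value),
            collapse = " & ")
    cat(sprintf("  IF %s THEN %s (%d/%d)\n", lhs, r$class, r$support,
                r$errors))
  }
  invisible(x)
}

#' Classify rows with an extracted rule set
#'
#' Applies the (mutually exclusive, exhaustive) root-to-leaf rules to the
#' rows of `newdata`.
#'
#' @param object a `c45_rules` object.
#' @param newdata data.frame with the feature columns the rules test.
#' @param ... unused.
#' @return Character vector of predicted classes.
#' @export
predict.c45_rules <- function(object, newdata, ...) {
  out <- rep(NA_character_, nrow(newdata))
  for (r in object) {
    hit <- rep(TRUE, nrow(newdata))
    if (nrow(r$conditions) > 0L) {
      for (k in seq_len(nrow(r$conditions))) {
        v <- as.numeric(newdata[[r$conditions$feature[k]]])
        hit <- hit & if (r$conditions$comparator[k] == "<=")
          v <= r$conditions$value[k] else v > r$conditions$value[k]
      }
    }
    out[hit & is.na(out)] <- r$class
  }
  out
}

#' Select the best representative tree among replicate trees
#'
#' Restricts to the trees whose root feature is the modal root across
#' replicates, then returns the one with the highest paired cross-validation
#' AUC; ties are broken by smaller tree (fewer leaves), then by replicate
#' index.
#'
#' @param trees list of `c45_tree` objects, one per replicate.
#' @param evals list of evaluation results paired with `trees` (each with an
#'   `auc` element), or a numeric vector of AUCs.
#' @return The selected `c45_tree`.
#' @export
select_representative_tree <- function(trees, evals) {
  if (length(trees) == 0L) stop("empty tree list", call. = FALSE)
  if (length(trees) == 1L) return(trees[[1L]])
  auc <- if (is.numeric(evals)) evals
         else vapply(evals, function(e) e$auc, numeric(1L))
  stopifnot(length(auc) == length(trees))
  roots <- vapply(trees, root_feature, character(1L))
  roots[is.na(roots)] <- "(leaf)"
  tab <- sort(table(roots), decreasing = TRUE)
  modal <- names(tab)[1L]
  cand <- which(roots == modal)
  leaves <- vapply(trees[cand], n_leaves, integer(1L))
  ord <- order(-auc[cand], leaves, cand)
  trees[[cand[ord[1L]]]]
}
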