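test_that("recall, precision and tie-aware AUC follow their definitions", {
  labels <- c(rep("positive", 4L), rep("negative", 4L))
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.4, 0.3, 0.1)
  ev <- evaluate_predictions(labels, prob)
  expect_equal(ev$recall, 3 / 4)          # TP = 3, FN = 1
  expect_equal(ev$precision, 3 / 4)       # TP = 3, FP = 1
  perfect <- evaluate_predictions(labels, c(0.9, 0.8, 0.7, 0.6,
                                            0.4, 0.3, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  tied <- evaluate_predictions(labels, rep(0.5, 8L))
  expect_equal(tied$auc, 0.5)
  expect_error(evaluate_predictions(rep("positive", 4L), runif(4L)),
               "single class")
})

test_that("AUC equals the brute-force Mann-Whitney count", {
  set.seed(5)
  for (case in 1:25) {
    n_pos <- sample(2:25, 1L)
    n_neg <- sample(2:25, 1L)
    labels <- c(rep("positive", n_pos), rep("negative", n_neg))
    prob <- round(runif(n_pos + n_neg), sample(1:3, 1L))  # force ties
    got <- evaluate_predictions(labels, prob)$auc
    u <- 0
    for (p in prob[1:n_pos]) for (q in prob[(n_pos + 1):(n_pos + n_neg)])
      u <- u + (p > q) + 0.5 * (p == q)
    expect_equal(got, u / (n_pos * n_neg), tolerance = 1e-12)
  }
})

test_that("cross-validation partitions rows and averages fold measures", {
  d <- sep_dataset(60L, seed = 2L, noise = 0.5)
  cfg <- vote_control(members = default_members()[c(1L, 7L)], bags = 2L)
  # fold assignment is a partition: every row validated exactly once
  y <- d$label
  folds <- morbnet:::stratified_folds(y, 10L, seed = 3L)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), nrow(d))
  expect_true(all(table(folds, y) >= 2L))  # stratified
  cv <- cross_validate(d, config = cfg, folds = 5L, seed = 3L)
  expect_equal(cv$auc, mean(cv$folds$auc))
  expect_gt(cv$auc, 0.9)                   # separable signal
  expect_error(cross_validate(d[1:4, ], config = cfg, folds = 10L),
               "more folds")
})

test_that("replicate summaries use median, min and max", {
  res <- lapply(c(0.7, 0.9, 0.8), function(a)
    structure(list(recall = a, precision = a / 2, auc = a),
              class = "eval_result"))
  s <- summarize_evals(res)
  expect_equal(s$median[s$measure == "auc"], 0.8)
  expect_equal(s$min[s$measure == "auc"], 0.7)
  expect_equal(s$max[s$measure == "auc"], 0.9)
  one <- summarize_evals(res[1L])
  expect_true(all(one$median == one$min & one$min == one$max))
  even <- summarize_evals(res[c(1L, 2L)])
  expect_equal(even$median[even$measure == "auc"], 0.8)
})

test_that("condition comparison pairs replicates by index, not order", {
  mk <- function(auc, rep) structure(
    list(auc = auc, provenance = list(replicate = rep)),
    class = "eval_result")
  normal <- list(mk(0.9, 1L), mk(0.8, 2L), mk(0.7, 3L))
  other <- list(mk(0.7, 3L), mk(0.9, 1L), mk(0.8, 2L))  # scrambled order
  res <- compare_conditions(normal, other, "auc")
  expect_equal(res$N, 0L)   # identical after pairing by replicate
  expect_false(res$significant)
  shifted <- list(mk(0.6, 2L), mk(0.5, 1L), mk(0.55, 3L))
  res2 <- compare_conditions(normal, shifted, "auc")
  expect_equal(res2$W, 0)
  expect_error(compare_conditions(normal, shifted[1:2], "auc"), "replicate")
})

test_that("genome-wide scoring medians, per-gene tests and ordering", {
  fm <- data.frame(gene = c("hi", "mid", "lo"), check.names = FALSE)
  for (col in c("x1", "x2")) fm[[col]] <- c(1, 0.5, 0)
  # ensembles of constant stubs for the "all 0.5" case
  cfgs <- vote_control(members = list(stub_member(0.5)), bags = 1L)
  d <- data.frame(gene = fm$gene,
                  label = factor(c("positive", "negative", "positive"),
                                 levels = c("negative", "positive")),
                  x1 = fm$x1, x2 = fm$x2)
  flat <- replicate(10L, vote_ensemble(d, config = cfgs, seed = 1L),
                    simplify = FALSE)
  tab <- score_genome_wide(flat, flat, fm)
  expect_true(all(tab$normal_median == 0.5))
  expect_true(all(!tab$significant))
  # planted separation: normal scores track x1, shuffled sit at 0.5
  mk_cfg <- function(bias) vote_control(members = list(
    make_member("lin", fit = function(x, y, seed) bias,
                predict = function(f, x) pmin(1, pmax(0, x[, "x1"] * f)))),
    bags = 1L)
  normal <- lapply(seq(0.85, 0.94, by = 0.01),
                   function(b) vote_ensemble(d, config = mk_cfg(b), seed = 1))
  tab2 <- score_genome_wide(normal, flat, fm)
  expect_equal(tab2$gene, c("hi", "mid", "lo"))  # sorted by normal median
  expect_true(tab2$significant[tab2$gene == "hi"])
  expect_equal(tab2$W[tab2$gene == "hi"], 0)
  expect_equal(tab2$N[tab2$gene == "hi"], 10L)
  expect_true(all(tab2$normal_median >= tab2$normal_min &
                    tab2$normal_median <= tab2$normal_max))
})

test_that("score histogram reports percent of known positives per bin", {
  sc <- data.frame(gene = sprintf("g%02d", 1:10),
                   normal_median = c(rep(0.9, 4L), rep(0.1, 4L), 0.5, 0.3))
  h <- score_histogram(sc, known_positives = sprintf("g%02d", 1:4))
  expect_equal(nrow(h), 5L)
  expect_equal(h$percent[5L], 100)
  expect_equal(sum(h$percent), 100)
  set.seed(2)
  sc2 <- data.frame(gene = sprintf("u%03d", 1:500),
                    normal_median = runif(500))
  h2 <- score_histogram(sc2, known_positives = sc2$gene)
  expect_equal(sum(h2$percent), 100)
  expect_true(all(abs(h2$percent - 20) < 8))   # near-uniform
  expect_error(score_histogram(sc, sc$gene, bin_width = 0.3), "evenly")
})
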