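path_net <- function() {
  # undirected path a - b - c in the ppi layer
  assemble_inhgi(ppi = data.frame(source = c("a", "b"),
                                  target = c("b", "c"), layer = "ppi"))
}

test_that("degree features count distinct per-layer partners", {
  net <- assemble_inhgi(
    ppi = data.frame(source = c("g", "g"), target = c("a", "b"),
                     layer = "ppi"),
    regulatory = data.frame(source = "t", target = "g",
                            layer = "regulatory"),
    genes = "iso")
  d <- degree_features(net, "g")
  expect_equal(unlist(d[, -1L]), c(ppi = 2L, metin = 0L, metout = 0L,
                                   regin = 1L, regout = 0L))
  dt <- degree_features(net, "t")
  expect_equal(dt$regout, 1L)
  expect_equal(dt$regin, 0L)
  expect_equal(unlist(degree_features(net, "iso")[, -1L]),
               c(ppi = 0L, metin = 0L, metout = 0L, regin = 0L, regout = 0L))
  expect_error(degree_features(net, "nope"), "not in network")
})

test_that("degree sums equal directed layer edge counts", {
  for (seed in 1:10) {
    net <- random_small_inhgi(7L, seed)
    d <- degree_features(net)
    n_reg <- sum(net$edges$layer == "regulatory")
    n_met <- sum(net$edges$layer == "metabolic")
    expect_equal(sum(d$regin), n_reg)
    expect_equal(sum(d$regout), n_reg)
    expect_equal(sum(d$metin), n_met)
    expect_equal(sum(d$metout), n_met)
  }
})

test_that("clustering coefficient counts neighbour pairs on the projection", {
  tri <- assemble_inhgi(ppi = data.frame(source = c("a", "b", "a"),
                                         target = c("b", "c", "c"),
                                         layer = "ppi"))
  expect_equal(unname(clustering_coefficient(tri, "a")), 1)
  star <- assemble_inhgi(ppi = data.frame(source = "h",
                                          target = c("x", "y", "z"),
                                          layer = "ppi"))
  expect_equal(unname(clustering_coefficient(star, "h")), 0)
  # g with neighbours a, b, c and a single a-b link among them: 1 of 3 pairs
  g13 <- assemble_inhgi(ppi = data.frame(source = c("g", "g", "g", "a"),
                                         target = c("a", "b", "c", "b"),
                                         layer = "ppi"))
  expect_equal(unname(clustering_coefficient(g13, "g")), 1 / 3)
})

test_that("betweenness follows layer and direction semantics", {
  expect_equal(unname(betweenness_centrality(path_net(), "ppi")),
               c(0, 1, 0)[match(path_net()$genes, c("a", "b", "c"))])
  chain <- assemble_inhgi(regulatory = data.frame(
    source = c("t1", "g"), target = c("g", "t2"), layer = "regulatory"))
  b <- betweenness_centrality(chain, "regulatory")
  expect_equal(unname(b["g"]), 1)
  k4 <- t(combn(letters[1:4], 2L))
  complete <- assemble_inhgi(ppi = data.frame(source = k4[, 1L],
                                              target = k4[, 2L],
                                              layer = "ppi"))
  expect_true(all(betweenness_centrality(complete, "all") == 0))
  expect_error(betweenness_centrality(path_net(), "friendship"))
})

test_that("closeness is the mean distance to reachable genes", {
  net <- path_net()
  cent <- closeness_centrality(net)
  expect_equal(unname(cent["b"]), 1)
  expect_equal(unname(cent["a"]), 1.5)
  iso <- assemble_inhgi(ppi = data.frame(source = "a", target = "b",
                                         layer = "ppi"), genes = "lone")
  expect_equal(unname(closeness_centrality(iso, "lone")), 0)
})

test_that("identicalness counts genes with matching feature vectors", {
  star <- assemble_inhgi(ppi = data.frame(source = "h",
                                          target = c("x", "y", "z"),
                                          layer = "ppi"))
  topo <- compute_topology(star)
  idc <- stats::setNames(topo$identicalness, topo$gene)
  expect_equal(unname(idc["h"]), 1L)
  expect_equal(unname(idc[c("x", "y", "z")]), c(3L, 3L, 3L))

  # two disjoint identical triangles: all six genes interchangeable
  tri2 <- assemble_inhgi(ppi = data.frame(
    source = c("a", "b", "a", "d", "e", "d"),
    target = c("b", "c", "c", "e", "f", "f"), layer = "ppi"))
  topo2 <- compute_topology(tri2)
  expect_equal(topo2$identicalness, rep(6L, 6L))

  # sums over equivalence classes equal squared class sizes
  for (seed in 1:8) {
    net <- random_small_inhgi(6L, seed)
    topo <- compute_topology(net)
    cls <- split(topo$identicalness, oracle_identicalness(topo))
    for (sz in names(cls))
      expect_equal(sum(cls[[sz]]), as.integer(sz)^2 *
                     (length(cls[[sz]]) / as.integer(sz)))
  }
})

test_that("all twelve features match brute-force oracles on random graphs", {
  for (seed in 1:40) {
    n <- sample(4:8, 1L)
    net <- random_small_inhgi(n, seed + 1000L)
    topo <- compute_topology(net)
    any_directed <- any(net$edges$layer != "ppi")
    expect_equal(stats::setNames(topo$inbet, topo$gene),
                 oracle_betweenness(net$genes, net$edges, "combined",
                                    ordered = any_directed),
                 tolerance = 1e-9)
    expect_equal(stats::setNames(topo$inbetppi, topo$gene),
                 oracle_betweenness(net$genes, net$edges, "ppi",
                                    ordered = FALSE), tolerance = 1e-9)
    expect_equal(stats::setNames(topo$inbetmet, topo$gene),
                 oracle_betweenness(net$genes, net$edges, "metabolic",
                                    ordered = TRUE), tolerance = 1e-9)
    expect_equal(stats::setNames(topo$inbetreg, topo$gene),
                 oracle_betweenness(net$genes, net$edges, "regulatory",
                                    ordered = TRUE), tolerance = 1e-9)
    expect_equal(stats::setNames(topo$cent, topo$gene),
                 oracle_closeness(net$genes, net$edges), tolerance = 1e-9)
    expect_equal(stats::setNames(topo$c, topo$gene),
                 oracle_clustering(net$genes, net$edges), tolerance = 1e-9)
    expect_equal(stats::setNames(topo$identicalness, topo$gene),
                 oracle_identicalness(topo))
  }
})

test_that("adding an edge never decreases a degree feature", {
  net <- random_small_inhgi(6L, 77L)
  d0 <- degree_features(net)
  extra <- data.frame(source = "a", target = "f", layer = "metabolic")
  net2 <- assemble_inhgi(net$edges[net$edges$layer == "ppi", ],
                         rbind(net$edges[net$edges$layer == "metabolic", ],
                               extra),
                         net$edges[net$edges$layer == "regulatory", ],
                         genes = net$genes)
  d1 <- degree_features(net2)
  for (col in c("ppi", "metin", "metout", "regin", "regout"))
    expect_true(all(d1[[col]][match(d0$gene, d1$gene)] >= d0[[col]]))
})

test_that("topology table is complete: one full row per gene", {
  net <- assemble_inhgi(ppi = data.frame(source = "a", target = "b",
                                         layer = "ppi"), genes = "iso")
  topo <- compute_topology(net)
  expect_equal(nrow(topo), 3L)
  expect_equal(names(topo), c("gene", "ppi", "metin", "metout", "regin",
                              "regout", "c", "identicalness", "cent",
                              "inbet", "inbetppi", "inbetmet", "inbetreg"))
  iso_row <- topo[topo$gene == "iso", -1L]
  expect_equal(iso_row$identicalness, 1L)
  expect_true(all(unlist(iso_row[setdiff(names(iso_row),
                                         "identicalness")]) == 0))
})
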