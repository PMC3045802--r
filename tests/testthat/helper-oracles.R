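# Independent brute-force oracles for the topology features: breadth-first
# shortest-path enumeration for betweenness and closeness, neighbour-pair
# counting for clustering, and pairwise vector comparison for identicalness.
# These deliberately share no code with the package implementations.

# adjacency list (integer indices) for a gene set and edge table
oracle_adjacency <- function(genes, edges, mode) {
  adj <- rep(list(integer()), length(genes))
  add_arc <- function(a, b) {
    i <- match(a, genes); j <- match(b, genes)
    if (i != j) adj[[i]] <<- union(adj[[i]], j)
  }
  for (k in seq_len(nrow(edges))) {
    s <- edges$source[k]; t <- edges$target[k]; l <- edges$layer[k]
    if (mode == "projection") {
      add_arc(s, t); add_arc(t, s)
    } else if (mode == "combined") {
      add_arc(s, t)
      if (l == "ppi") add_arc(t, s)
    } else if (l == mode) {
      add_arc(s, t)
      if (l == "ppi") add_arc(t, s)
    }
  }
  adj
}

oracle_bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer()
    for (v in frontier) for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# all shortest paths s -> t as lists of vertex indices
oracle_shortest_paths <- function(adj, s, t) {
  dist <- oracle_bfs_dist(adj, s)
  if (!is.finite(dist[t])) return(list())
  walk <- function(v) {
    if (v == t) return(list(v))
    out <- list()
    for (w in adj[[v]]) {
      if (dist[w] == dist[v] + 1 && dist[w] <= dist[t]) {
        for (tail in walk(w)) out[[length(out) + 1L]] <- c(v, tail)
      }
    }
    out
  }
  paths <- walk(s)
  Filter(function(p) p[length(p)] == t, paths)
}

# unnormalized betweenness; ordered = sum over ordered pairs
oracle_betweenness <- function(genes, edges, mode, ordered) {
  adj <- oracle_adjacency(genes, edges, mode)
  n <- length(genes)
  b <- numeric(n)
  pairs <- if (ordered) {
    subset(expand.grid(s = 1:n, t = 1:n), s != t)
  } else {
    subset(expand.grid(s = 1:n, t = 1:n), s < t)
  }
  for (k in seq_len(nrow(pairs))) {
    paths <- oracle_shortest_paths(adj, pairs$s[k], pairs$t[k])
    if (length(paths) == 0L) next
    for (v in seq_len(n)) {
      if (v == pairs$s[k] || v == pairs$t[k]) next
      hit <- sum(vapply(paths, function(p) v %in% p, logical(1L)))
      b[v] <- b[v] + hit / length(paths)
    }
  }
  stats::setNames(b, genes)
}

oracle_closeness <- function(genes, edges) {
  adj <- oracle_adjacency(genes, edges, "combined")
  out <- vapply(seq_along(genes), function(s) {
    d <- oracle_bfs_dist(adj, s)[-s]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else mean(d)
  }, numeric(1L))
  stats::setNames(out, genes)
}

oracle_clustering <- function(genes, edges) {
  adj <- oracle_adjacency(genes, edges, "projection")
  out <- vapply(seq_along(genes), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (nb[b] %in% adj[[nb[a]]]) links <- links + 1L
    links / (k * (k - 1L) / 2)
  }, numeric(1L))
  stats::setNames(out, genes)
}

oracle_identicalness <- function(features) {
  cols <- setdiff(names(features), c("gene", "identicalness"))
  m <- round(as.matrix(features[cols]), 9L)
  out <- vapply(seq_len(nrow(m)), function(i)
    sum(vapply(seq_len(nrow(m)), function(j) all(m[i, ] == m[j, ]),
               logical(1L))), integer(1L))
  stats::setNames(out, features$gene)
}

# random small multi-layer network for oracle property tests
random_small_inhgi <- function(n_nodes, seed) {
  set.seed(seed)
  genes <- letters[seq_len(n_nodes)]
  n_edges <- sample(2:(2L * n_nodes), 1L)
  src <- sample(genes, n_edges, replace = TRUE)
  tgt <- sample(genes, n_edges, replace = TRUE)
  keep <- src != tgt
  layer <- sample(c("ppi", "metabolic", "regulatory"), n_edges,
                  replace = TRUE)
  df <- data.frame(source = src[keep], target = tgt[keep],
                   layer = layer[keep], stringsAsFactors = FALSE)
  assemble_inhgi(ppi = df[df$layer == "ppi", ],
                 metabolic = df[df$layer == "metabolic", ],
                 regulatory = df[df$layer == "regulatory", ],
                 genes = genes)
}

# exhaustive 2^N signed-rank enumeration oracle (statistic W distribution for
# given, possibly tied, ranks)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  list(W = w_obs, p = min(1, 2 * mean(w_plus <= w_obs)))
}
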