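# The twelve per-gene topological features of the integrated network:
# five layer-specific degrees, clustering coefficient, identicalness,
# closeness (mean shortest-path length to reachable genes), and betweenness
# on the combined network and on each single layer.
#
# Combined-graph semantics: traversal respects edge direction, with ppi edges
# traversable in both directions. Clustering and identicalness use the
# undirected projection of all layers.

topology_feature_names <- function() {
  c("ppi", "metin", "metout", "regin", "regout", "c", "identicalness",
    "cent", "inbet", "inbetppi", "inbetmet", "inbetreg")
}

# igraph over all genes of `net`; combined = directed with ppi doubled.
graph_combined <- function(net) {
  e <- net$edges
  ppi <- e[e$layer == "ppi", , drop = FALSE]
  dir <- e[e$layer != "ppi", , drop = FALSE]
  ends <- rbind(cbind(ppi$source, ppi$target), cbind(ppi$target, ppi$source),
                cbind(dir$source, dir$target))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L]),
    directed = TRUE, vertices = net$genes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

graph_layer <- function(net, layer) {
  e <- net$edges[net$edges$layer == layer, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target),
    directed = layer != "ppi", vertices = net$genes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

graph_projection <- function(net) {
  e <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target),
    directed = FALSE, vertices = net$genes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

check_genes <- function(net, gene) {
  missing <- setdiff(gene, net$genes)
  if (length(missing) > 0L)
    stop(sprintf("gene(s) not in network: %s",
                 paste(utils::head(missing, 3L), collapse = ", ")),
         call. = FALSE)
}

#' Layer-specific degree features
#'
#' For each gene: `ppi` = number of distinct ppi partners; `metin`/`metout` =
#' distinct metabolic predecessors/successors; `regin`/`regout` = distinct
#' regulatory predecessors (transcription factors regulating the gene) and
#' successors (targets it regulates).
#'
#' @param net an `inhgi` object.
#' @param gene optional gene identifier(s) to restrict to (error if absent
#'   from the network).
#' @return data.frame with columns gene, ppi, metin, metout, regin, regout.
#' @export
degree_features <- function(net, gene = NULL) {
  stopifnot(inherits(net, "inhgi"))
  genes <- net$genes
  zero <- stats::setNames(integer(length(genes)), genes)
  count_in <- function(e) {
    # distinct predecessors per target
    if (nrow(e) == 0L) return(zero)
    e <- e[!duplicated(paste(e$source, e$target, sep = "\r")), , drop = FALSE]
    tab <- table(e$target)
    out <- zero
    out[names(tab)] <- as.integer(tab)
    out
  }
  count_out <- function(e) {
    if (nrow(e) == 0L) return(zero)
    e <- e[!duplicated(paste(e$source, e$target, sep = "\r")), , drop = FALSE]
    tab <- table(e$source)
    out <- zero
    out[names(tab)] <- as.integer(tab)
    out
  }
  ed <- net$edges
  ppi_e <- ed[ed$layer == "ppi", , drop = FALSE]
  # ppi partners: count each canonical undirected edge once per endpoint
  ppi_deg <- zero
  if (nrow(ppi_e) > 0L) {
    tab <- table(c(ppi_e$source, ppi_e$target))
    ppi_deg[names(tab)] <- as.integer(tab)
  }
  met <- ed[ed$layer == "metabolic", , drop = FALSE]
  reg <- ed[ed$layer == "regulatory", , drop = FALSE]
  out <- data.frame(gene = genes,
                    ppi = unname(ppi_deg),
                    metin = unname(count_in(met)),
                    metout = unname(count_out(met)),
                    regin = unname(count_in(reg)),
                    regout = unname(count_out(reg)),
                    stringsAsFactors = FALSE)
  if (!is.null(gene)) {
    check_genes(net, gene)
    out <- out[match(gene, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Clustering coefficient
#'
#' Local clustering on the undirected projection of all layers: the number of
#' edges among a gene's neighbours divided by the number of neighbour pairs.
#' Genes with fewer than two neighbours score 0.
#'
#' @inheritParams degree_features
#' @return Named numeric vector over the requested genes.
#' @export
clustering_coefficient <- function(net, gene = NULL) {
  stopifnot(inherits(net, "inhgi"))
  g <- graph_projection(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  names(cc) <- net$genes
  if (!is.null(gene)) {
    check_genes(net, gene)
    cc <- cc[gene]
  }
  cc
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness. With `scope = "all"` it is computed
#' on the combined graph (ppi edges traversable in both directions, metabolic
#' and regulatory edges directed), summing over ordered source-target pairs.
#' With a layer scope it is computed on that layer's subgraph over all genes:
#' unordered pairs for the undirected ppi layer, ordered pairs for the
#' directed layers.
#'
#' @param net an `inhgi` object.
#' @param scope one of "all", "ppi", "metabolic", "regulatory".
#' @return Named numeric vector over all genes.
#' @export
betweenness_centrality <- function(net,
                                   scope = c("all", "ppi", "metabolic",
                                             "regulatory")) {
  stopifnot(inherits(net, "inhgi"))
  scope <- match.arg(scope)
  g <- if (scope == "all") {
    # a network with only ppi edges is purely undirected: pairs are unordered
    if (all(net$edges$layer == "ppi")) graph_layer(net, "ppi")
    else graph_combined(net)
  } else {
    graph_layer(net, scope)
  }
  b <- igraph::betweenness(g, directed = igraph::is_directed(g))
  stats::setNames(as.numeric(b), net$genes)
}

#' Closeness centrality as mean shortest-path length
#'
#' For each gene, the mean (direction-respecting) shortest-path length on the
#' combined graph from the gene to every gene reachable from it; 0 when
#' nothing is reachable. Note this is a *distance*, so smaller values mean a
#' more central gene.
#'
#' @inheritParams degree_features
#' @param chunk number of source genes per distance-matrix block (memory
#'   control on large networks).
#' @return Named numeric vector over the requested genes.
#' @export
closeness_centrality <- function(net, gene = NULL, chunk = 512L) {
  stopifnot(inherits(net, "inhgi"))
  g <- graph_combined(net)
  targets <- if (is.null(gene)) net$genes else {
    check_genes(net, gene)
    gene
  }
  out <- numeric(length(targets))
  for (start in seq(1L, length(targets), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(targets))
    d <- igraph::distances(g, v = targets[idx], mode = "out")
    diag_self <- match(targets[idx], colnames(d))
    for (k in seq_along(idx)) {
      row <- d[k, -diag_self[k]]
      row <- row[is.finite(row)]
      out[idx[k]] <- if (length(row) == 0L) 0 else mean(row)
    }
  }
  stats::setNames(out, targets)
}

#' Identicalness
#'
#' For each gene, the number of genes (including itself) whose vector of the
#' other eleven topological features matches exactly, after rounding real
#' values to 9 decimal places.
#'
#' @param features data.frame with a `gene` column and the eleven feature
#'   columns (everything in [topology_feature_names()] except
#'   `identicalness`).
#' @return Named integer vector (minimum 1) over the genes of `features`.
#' @export
identicalness <- function(features) {
  cols <- setdiff(topology_feature_names(), "identicalness")
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L)
    stop(sprintf("features missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  keys <- do.call(paste, c(lapply(features[cols], function(v)
    format(round(as.numeric(v), 9L), scientific = FALSE, trim = TRUE)),
    sep = "\r"))
  tab <- table(keys)
  stats::setNames(as.integer(tab[keys]), features$gene)
}

#' Compute the full topology feature table
#'
#' One row per network gene with the twelve topological features, in the
#' canonical column order `ppi, metin, metout, regin, regout, c,
#' identicalness, cent, inbet, inbetppi, inbetmet, inbetreg`.
#'
#' @param net an `inhgi` object.
#' @return data.frame with a `gene` column plus the twelve features.
#' @export
compute_topology <- function(net) {
  stopifnot(inherits(net, "inhgi"))
  deg <- degree_features(net)
  out <- data.frame(gene = net$genes, stringsAsFactors = FALSE)
  out$ppi <- deg$ppi
  out$metin <- deg$metin
  out$metout <- deg$metout
  out$regin <- deg$regin
  out$regout <- deg$regout
  out$c <- unname(clustering_coefficient(net))
  out$cent <- unname(closeness_centrality(net))
  out$inbet <- unname(betweenness_centrality(net, "all"))
  out$inbetppi <- unname(betweenness_centrality(net, "ppi"))
  out$inbetmet <- unname(betweenness_centrality(net, "metabolic"))
  out$inbetreg <- unname(betweenness_centrality(net, "regulatory"))
  out$identicalness <- unname(identicalness(out))
  out[, c("gene", topology_feature_names())]
}

#' Write the topology feature table as TSV
#'
#' @param topology data.frame from [compute_topology()].
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
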