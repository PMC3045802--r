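# Construction of the integrated multi-layer gene network: identifier
# normalization, metabolite-coupling derivation of the metabolic layer with
# currency-metabolite removal, and assembly of the three layers.

#' Normalize gene identifiers in interaction records
#'
#' Replaces every gene name by its canonical identifier using a many-to-one
#' synonym map. Records whose source or target has no mapping are dropped (and
#' counted); records that become self-loops after mapping are dropped; ppi
#' edges are re-canonicalized and duplicates re-collapsed.
#'
#' @param records interaction data.frame (source, target, layer).
#' @param idmap either a named character vector (names = synonyms, values =
#'   canonical ids) or a two-column data.frame (from, to).
#' @return Normalized interaction data.frame with a `summary` attribute listing
#'   `dropped_unmapped`, `dropped_selfloop` and `collapsed` counts.
#' @export
normalize_ids <- function(records, idmap) {
  if (is.data.frame(idmap)) {
    stopifnot(ncol(idmap) >= 2L)
    idmap <- stats::setNames(as.character(idmap[[2L]]),
                             as.character(idmap[[1L]]))
  }
  if (anyDuplicated(names(idmap)))
    stop("idmap: duplicate synonym entries", call. = FALSE)
  src <- unname(idmap[records$source])
  tgt <- unname(idmap[records$target])
  unmapped <- is.na(src) | is.na(tgt)
  selfloop <- !unmapped & src == tgt
  keep <- !unmapped & !selfloop
  out <- data.frame(source = src[keep], target = tgt[keep],
                    layer = records$layer[keep], stringsAsFactors = FALSE)
  out <- canonicalize_interactions(out)
  attr(out, "summary") <- list(dropped_unmapped = sum(unmapped),
                               dropped_selfloop = sum(selfloop),
                               collapsed = attr(out, "n_collapsed"))
  out
}

#' The default currency metabolites
#'
#' The eight ubiquitous metabolites excluded before deriving enzyme-enzyme
#' metabolic interactions. Being present throughout the cell most of the time,
#' they impose no real constraint on pathway structure and would otherwise
#' create spurious dense connectivity.
#'
#' @return Character vector of eight metabolite names.
#' @export
currency_metabolites <- function() {
  c("ADP", "ATP", "H+", "H2O", "NADP+", "NADPH",
    "orthophosphate", "pyrophosphate")
}

#' Select the most-connected metabolites of a reaction table
#'
#' Ranks metabolites by the number of reactions they participate in (as
#' reactant or product, counted once per reaction) and returns the top `k`,
#' breaking ties lexicographically. This is the data-driven alternative to the
#' fixed [currency_metabolites()] list.
#'
#' @param reactions reaction data.frame as returned by [read_reactions()].
#' @param k number of metabolites to select.
#' @return Character vector of `k` metabolite identifiers.
#' @export
select_currency_metabolites <- function(reactions, k) {
  stopifnot(nrow(reactions) > 0L, k >= 1L)
  per_reaction <- mapply(function(r, p) unique(c(r, p)),
                         reactions$reactants, reactions$products,
                         SIMPLIFY = FALSE)
  counts <- table(unlist(per_reaction))
  if (k > length(counts))
    stop(sprintf("k = %d exceeds the %d distinct metabolites", k,
                 length(counts)), call. = FALSE)
  ord <- order(-as.integer(counts), names(counts))
  names(counts)[ord][seq_len(k)]
}

#' Derive enzyme-enzyme metabolic interactions
#'
#' Creates a directed metabolic edge g1 -> g2 whenever a product of a reaction
#' catalyzed by g1 is a reactant of a reaction catalyzed by g2, the shared
#' metabolite is not a currency metabolite, and g1 != g2. Duplicate edges are
#' collapsed.
#'
#' @param reactions reaction data.frame as returned by [read_reactions()].
#' @param currency character vector of metabolites to exclude
#'   (default [currency_metabolites()]).
#' @return Interaction data.frame with layer "metabolic".
#' @export
derive_metabolic_interactions <- function(reactions,
                                          currency = currency_metabolites()) {
  empty <- data.frame(source = character(), target = character(),
                      layer = character(), stringsAsFactors = FALSE)
  if (nrow(reactions) == 0L) return(empty)
  # metabolite -> set of producing / consuming genes
  producers <- new.env(parent = emptyenv())
  consumers <- new.env(parent = emptyenv())
  add <- function(env, mets, genes) {
    for (m in mets) {
      if (m %in% currency) next
      assign(m, c(get0(m, envir = env, ifnotfound = character()), genes),
             envir = env)
    }
  }
  for (i in seq_len(nrow(reactions))) {
    g <- reactions$genes[[i]]
    if (length(g) == 0L) next
    add(producers, reactions$products[[i]], g)
    add(consumers, reactions$reactants[[i]], g)
  }
  mets <- intersect(ls(producers), ls(consumers))
  if (length(mets) == 0L) return(empty)
  pieces <- lapply(mets, function(m) {
    p <- unique(get(m, envir = producers))
    q <- unique(get(m, envir = consumers))
    expand.grid(source = p, target = q, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[out$source != out$target, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$layer <- "metabolic"
  out <- canonicalize_interactions(out)
  attr(out, "n_collapsed") <- NULL
  rownames(out) <- NULL
  out
}

#' Assemble the integrated multi-layer gene network
#'
#' Merges the ppi (undirected), metabolic (directed) and regulatory (directed)
#' interaction layers into one network over the union of their genes. The same
#' gene pair may carry edges in several layers; within a layer each pair
#' appears at most once and self-loops are excluded.
#'
#' @param ppi,metabolic,regulatory interaction data.frames (source, target,
#'   layer) or NULL for an absent layer. The layer column, when present, must
#'   match the argument.
#' @param genes optional additional gene identifiers to include as isolated
#'   vertices.
#' @return An object of class `inhgi` with elements `genes` (character vector)
#'   and `edges` (data.frame source, target, layer).
#' @export
assemble_inhgi <- function(ppi = NULL, metabolic = NULL, regulatory = NULL,
                           genes = character()) {
  one <- function(df, tag) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(source = character(), target = character(),
                        layer = character(), stringsAsFactors = FALSE))
    stopifnot(all(c("source", "target") %in% names(df)))
    if ("layer" %in% names(df) && any(df$layer != tag))
      stop(sprintf("layer column disagrees with the '%s' argument", tag),
           call. = FALSE)
    out <- data.frame(source = as.character(df$source),
                      target = as.character(df$target),
                      layer = tag, stringsAsFactors = FALSE)
    out <- out[out$source != out$target, , drop = FALSE]
    out <- canonicalize_interactions(out)
    attr(out, "n_collapsed") <- NULL
    out
  }
  edges <- rbind(one(ppi, "ppi"), one(metabolic, "metabolic"),
                 one(regulatory, "regulatory"))
  rownames(edges) <- NULL
  all_genes <- sort(unique(c(edges$source, edges$target,
                             as.character(genes))))
  structure(list(genes = all_genes, edges = edges), class = "inhgi")
}

#' @export
print.inhgi <- function(x, ...) {
  counts <- table(factor(x$edges$layer, levels = interaction_layers()))
  cat("Integrated gene interaction network\n")
  cat(sprintf("  genes: %d\n", length(x$genes)))
  cat(sprintf("  edges: %d (ppi %d, metabolic %d, regulatory %d)\n",
              nrow(x$edges), counts[["ppi"]], counts[["metabolic"]],
              counts[["regulatory"]]))
  invisible(x)
}

#' Build summary of an assembled network
#'
#' Per-layer edge counts and gene total, suitable for serialization as a
#' build-report sidecar.
#'
#' @param net an `inhgi` object.
#' @return Named list with `genes`, per-layer edge counts and `edges_total`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "inhgi"))
  counts <- table(factor(net$edges$layer, levels = interaction_layers()))
  list(genes = length(net$genes),
       ppi = unname(counts[["ppi"]]),
       metabolic = unname(counts[["metabolic"]]),
       regulatory = unname(counts[["regulatory"]]),
       edges_total = nrow(net$edges))
}

#' Write the assembled network as an edge-list TSV
#'
#' @param net an `inhgi` object.
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
write_inhgi <- function(net, path) {
  stopifnot(inherits(net, "inhgi"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
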