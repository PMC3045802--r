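# Subcellular-localization and tissue-expression learning attributes, and
# assembly of the full 24-column feature matrix (12 topology + 2 expression +
# 10 localization flags).

#' Subcellular localization categories
#'
#' The ten localization flags used as learning attributes: the eight
#' high-level cellular-component slim terms, plus "Other localization" for
#' any other annotated compartment and "Unknown" for genes with no
#' cellular-component annotation at all.
#'
#' @return Character vector of the ten category (column) names.
#' @export
localization_categories <- function() {
  c("Cytoplasm", "Endoplasmic reticulum", "Mitochondrion", "Nucleus",
    "Extracellular space", "Golgi apparatus", "Plasma membrane",
    "Cellular component", "Other localization", "Unknown")
}

#' The 24 learning-attribute column names, in canonical order
#'
#' Twelve topology features, then `numtissuesexp` and `avegexptec`, then the
#' ten localization flags.
#'
#' @return Character vector of 24 column names.
#' @export
feature_columns <- function() {
  c(topology_feature_names(), "numtissuesexp", "avegexptec",
    localization_categories())
}

#' Multi-hot localization flags
#'
#' Maps annotation terms onto the ten localization categories. A term is
#' routed through `remap` when provided there, kept when it already names one
#' of the eight concrete categories (case-insensitive), and sent to
#' "Other localization" otherwise. Genes with no annotation get Unknown = 1.
#' A gene may carry several category flags.
#'
#' @param annotations data.frame (gene, term) as from [read_annotations()].
#' @param genes character vector of genes the output must cover.
#' @param remap optional data.frame (term, category) rerouting terms; the
#'   category must be one of [localization_categories()] other than
#'   "Unknown".
#' @return data.frame with a `gene` column and ten 0/1 flag columns.
#' @export
localization_features <- function(annotations, genes, remap = NULL) {
  cats <- localization_categories()
  concrete <- setdiff(cats, c("Other localization", "Unknown"))
  route <- function(term) {
    if (!is.null(remap)) {
      hit <- match(term, remap[[1L]])
      if (!is.na(hit)) {
        cat <- as.character(remap[[2L]][hit])
        if (!cat %in% setdiff(cats, "Unknown"))
          stop(sprintf("remap routes '%s' to unknown category '%s'",
                       term, cat), call. = FALSE)
        return(cat)
      }
    }
    hit <- match(tolower(term), tolower(concrete))
    if (!is.na(hit)) concrete[hit] else "Other localization"
  }
  flags <- matrix(0L, nrow = length(genes), ncol = length(cats),
                  dimnames = list(NULL, cats))
  if (nrow(annotations) > 0L) {
    ann <- annotations[annotations$gene %in% genes, , drop = FALSE]
    if (nrow(ann) > 0L) {
      cat_of <- vapply(ann$term, route, character(1L), USE.NAMES = FALSE)
      gi <- match(ann$gene, genes)
      flags[cbind(gi, match(cat_of, cats))] <- 1L
    }
  }
  no_ann <- rowSums(flags) == 0L
  flags[no_ann, "Unknown"] <- 1L
  out <- data.frame(gene = genes, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[cats] <- as.data.frame(flags)
  out
}

#' Tissue-expression features
#'
#' For each gene: `numtissuesexp` = the number of tissues in which the gene is
#' expressed at or above the tpm threshold, and `avegexptec` = the mean tpm
#' over those tissues (0 when no tissue qualifies).
#'
#' @param expression data.frame from [read_expression()] (gene column plus
#'   tissue columns).
#' @param threshold tpm threshold for calling a gene expressed (default 5).
#' @return data.frame with columns gene, numtissuesexp, avegexptec.
#' @export
expression_features <- function(expression, threshold = 5) {
  vals <- as.matrix(expression[, setdiff(names(expression), "gene"),
                               drop = FALSE])
  hit <- vals >= threshold
  n <- rowSums(hit)
  avg <- ifelse(n > 0L, rowSums(vals * hit) / pmax(n, 1L), 0)
  data.frame(gene = expression$gene, numtissuesexp = as.integer(n),
             avegexptec = as.numeric(avg), stringsAsFactors = FALSE)
}

#' Assemble the full feature matrix
#'
#' Joins topology (mandatory for every gene), expression and localization
#' features into the 24-column learning matrix. Genes missing from the
#' expression table get (0, 0); genes missing localization get Unknown = 1.
#'
#' @param topology data.frame from [compute_topology()].
#' @param localization data.frame from [localization_features()] or NULL.
#' @param expression data.frame from [expression_features()] or NULL.
#' @param genes genes to cover (default: the topology genes). Every gene must
#'   have a topology row.
#' @return data.frame with a `gene` column followed by the 24 attribute
#'   columns in [feature_columns()] order.
#' @export
assemble_feature_matrix <- function(topology, localization = NULL,
                                    expression = NULL, genes = NULL) {
  genes <- as.character(genes %||% topology$gene)
  ti <- match(genes, topology$gene)
  if (anyNA(ti))
    stop(sprintf("no topology row for gene(s): %s",
                 paste(utils::head(genes[is.na(ti)], 3L), collapse = ", ")),
         call. = FALSE)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in topology_feature_names())
    out[[col]] <- topology[[col]][ti]
  out$numtissuesexp <- 0L
  out$avegexptec <- 0
  if (!is.null(expression)) {
    ei <- match(genes, expression$gene)
    hit <- !is.na(ei)
    out$numtissuesexp[hit] <- expression$numtissuesexp[ei[hit]]
    out$avegexptec[hit] <- expression$avegexptec[ei[hit]]
  }
  cats <- localization_categories()
  for (col in cats) out[[col]] <- 0L
  out$Unknown <- 1L
  if (!is.null(localization)) {
    li <- match(genes, localization$gene)
    hit <- which(!is.na(li))
    for (col in cats)
      out[[col]][hit] <- localization[[col]][li[hit]]
  }
  out[, c("gene", feature_columns())]
}
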