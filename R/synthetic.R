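# Synthetic data generator emulating the joint structure of the pipeline's
# inputs: a heavy-tailed undirected protein-interaction layer, a directed
# transcription-factor layer, a metabolic layer realized as reaction chains
# (so enzyme-enzyme edges arise through the same metabolite-coupling
# derivation as on real data), multi-label subcellular localization,
# log-normal tissue expression with per-gene breadth, and class labels
# planted by a logistic rule on named feature columns.

#' Specification of a synthetic study
#'
#' Defaults mirror the scale of the real integrated human network: 10,241
#' genes, a preferential-attachment ppi layer, on the order of a hundred
#' transcription factors, ~1,500 metabolic reactions over a shared metabolite
#' pool (currency metabolites included so their removal is exercised), 32
#' tissues, and labels planted by a logistic rule on standardized feature
#' columns, calibrated to a target prevalence.
#'
#' @param n_genes number of genes.
#' @param ppi_m edges added per vertex in the preferential-attachment ppi
#'   layer.
#' @param n_tf number of transcription-factor genes.
#' @param tf_targets_mu mean number of targets per transcription factor
#'   (negative-binomially dispersed).
#' @param n_reactions number of metabolic reactions.
#' @param n_metabolites size of the non-currency metabolite pool.
#' @param n_enzymes number of genes eligible to catalyze reactions.
#' @param currency_prob probability that a reaction additionally consumes and
#'   produces a currency metabolite.
#' @param loc_probs named vector of per-category localization probabilities
#'   (independent draws; genes with no draw become Unknown).
#' @param n_tissues number of tissues.
#' @param expr_meanlog,expr_sdlog log-normal parameters of tpm in expressed
#'   tissues (values are offset above the 5-tpm threshold).
#' @param breadth_shape1,breadth_shape2 beta parameters of the per-gene
#'   fraction of tissues in which it is expressed.
#' @param beta named coefficient vector of the logistic label rule over
#'   feature columns (applied to within-column standardized values).
#' @param beta0 logistic intercept; NULL (default) auto-calibrates it so the
#'   expected prevalence matches `prevalence`.
#' @param prevalence target fraction of positive genes, in (0, 0.5].
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 10241L, ppi_m = 4L, n_tf = 120L,
                           tf_targets_mu = 25, n_reactions = 1500L,
                           n_metabolites = 600L, n_enzymes = 2000L,
                           currency_prob = 0.5,
                           loc_probs = c(
                             "Cytoplasm" = 0.30, "Nucleus" = 0.25,
                             "Plasma membrane" = 0.20,
                             "Extracellular space" = 0.10,
                             "Mitochondrion" = 0.10,
                             "Endoplasmic reticulum" = 0.07,
                             "Golgi apparatus" = 0.05,
                             "Cellular component" = 0.10,
                             "Other localization" = 0.08),
                           n_tissues = 32L, expr_meanlog = log(40),
                           expr_sdlog = 1, breadth_shape1 = 1.2,
                           breadth_shape2 = 1.2,
                           beta = c(regin = 1), beta0 = NULL,
                           prevalence = 0.14, seed = 1L) {
  stopifnot(n_genes >= 10L, prevalence > 0, prevalence <= 0.5,
            all(loc_probs >= 0), all(loc_probs <= 1))
  if (n_tf > n_genes) stop("n_tf exceeds n_genes", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), ppi_m = ppi_m, n_tf = n_tf,
                 tf_targets_mu = tf_targets_mu,
                 n_reactions = as.integer(n_reactions),
                 n_metabolites = as.integer(n_metabolites),
                 n_enzymes = as.integer(n_enzymes),
                 currency_prob = currency_prob, loc_probs = loc_probs,
                 n_tissues = as.integer(n_tissues),
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 breadth_shape1 = breadth_shape1,
                 breadth_shape2 = breadth_shape2,
                 beta = beta, beta0 = beta0, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Morbidity-flavoured synthetic specification
#'
#' Plants a strong positive effect on the number of regulating transcription
#' factors, with secondary effects on metabolic betweenness and extracellular
#' localization; target prevalence matches the 1,412 known morbid genes out
#' of 10,241 network genes.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
morbidity_like_spec <- function(seed = 1L, ...) {
  args <- list(beta = c(regin = 3, inbetmet = 1, "Extracellular space" = 1),
               prevalence = 1412 / 10241, seed = seed)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

#' Druggability-flavoured synthetic specification
#'
#' Plants a strong positive effect on plasma-membrane localization, with
#' secondary effects on regulatory betweenness and metabolic in-degree;
#' target prevalence matches the 257 known druggable genes out of 10,241
#' network genes.
#'
#' @inheritParams morbidity_like_spec
#' @return A `synthetic_spec`.
#' @export
druggability_like_spec <- function(seed = 1L, ...) {
  args <- list(beta = c("Plasma membrane" = 3, inbetreg = 1, metin = 1),
               prevalence = 257 / 10241, seed = seed)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

synthetic_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic multi-layer network
#'
#' The ppi layer grows by preferential attachment (heavy-tailed degrees); the
#' regulatory layer connects `n_tf` transcription-factor genes to random
#' targets; the metabolic layer is realized as a reaction table whose
#' enzyme-enzyme edges are derived with [derive_metabolic_interactions()]
#' under currency-metabolite removal. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `network` (an `inhgi`), `reactions` (the
#'   reaction table) and `layers` (the three edge lists).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- synthetic_gene_ids(spec$n_genes)
  with_seed(derive_seed(spec$seed, 101L), {
    g <- igraph::sample_pa(spec$n_genes, m = spec$ppi_m, directed = FALSE)
    ends <- igraph::as_edgelist(g, names = FALSE)
    perm <- sample.int(spec$n_genes)  # detach degree from vertex index order
    ppi <- data.frame(source = genes[perm[ends[, 1L]]],
                      target = genes[perm[ends[, 2L]]],
                      layer = "ppi", stringsAsFactors = FALSE)

    reg <- NULL
    if (spec$n_tf > 0L) {
      tfs <- sample(genes, spec$n_tf)
      n_targets <- pmax(1L, stats::rnbinom(spec$n_tf, mu = spec$tf_targets_mu,
                                           size = 2))
      reg <- do.call(rbind, lapply(seq_len(spec$n_tf), function(i) {
        data.frame(source = tfs[i],
                   target = sample(setdiff(genes, tfs[i]),
                                   min(n_targets[i], spec$n_genes - 1L)),
                   layer = "regulatory", stringsAsFactors = FALSE)
      }))
    }

    mets <- sprintf("m%04d", seq_len(spec$n_metabolites))
    enzymes <- sample(genes, min(spec$n_enzymes, spec$n_genes))
    currency <- currency_metabolites()
    reactions <- data.frame(
      reaction_id = sprintf("R%05d", seq_len(spec$n_reactions)),
      stringsAsFactors = FALSE)
    reactions$genes <- replicate(spec$n_reactions,
                                 sample(enzymes, sample(1:2, 1L)),
                                 simplify = FALSE)
    draw_side <- function() {
      side <- sample(mets, sample(1:2, 1L))
      if (stats::runif(1L) < spec$currency_prob)
        side <- c(side, sample(currency, 1L))
      side
    }
    reactions$reactants <- replicate(spec$n_reactions, draw_side(),
                                     simplify = FALSE)
    reactions$products <- replicate(spec$n_reactions, draw_side(),
                                    simplify = FALSE)
    met <- derive_metabolic_interactions(reactions, currency)
    net <- assemble_inhgi(ppi = ppi, metabolic = met, regulatory = reg,
                          genes = genes)
    list(network = net, reactions = reactions,
         layers = list(ppi = ppi, metabolic = met, regulatory = reg))
  })
}

#' Generate synthetic annotations and expression profiles
#'
#' Localization: each concrete category is drawn as an independent Bernoulli
#' with its spec probability; genes with no draw carry no annotation (and
#' will be flagged Unknown downstream). Expression: each gene has a beta-
#' distributed tissue breadth; expressed tissues receive log-normal tpm
#' offset above the 5-tpm threshold, unexpressed tissues sub-threshold
#' values.
#'
#' @param spec a [synthetic_spec()].
#' @param genes character vector of gene identifiers.
#' @return List with `annotations` (gene, term) and `expression` (gene +
#'   tissue columns).
#' @export
generate_annotations_expression <- function(spec, genes) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- length(genes)
  with_seed(derive_seed(spec$seed, 202L), {
    ann <- do.call(rbind, lapply(names(spec$loc_probs), function(cat) {
      hit <- stats::runif(n) < spec$loc_probs[[cat]]
      if (!any(hit)) return(NULL)
      data.frame(gene = genes[hit], term = cat, stringsAsFactors = FALSE)
    }))
    if (is.null(ann))
      ann <- data.frame(gene = character(), term = character(),
                        stringsAsFactors = FALSE)
    ann <- ann[order(ann$gene, ann$term), , drop = FALSE]
    rownames(ann) <- NULL

    breadth <- stats::rbeta(n, spec$breadth_shape1, spec$breadth_shape2)
    expressed <- matrix(stats::runif(n * spec$n_tissues) < breadth,
                        nrow = n)  # recycles breadth down columns
    tpm <- matrix(stats::runif(n * spec$n_tissues, 0, 4.9), nrow = n)
    n_on <- sum(expressed)
    tpm[expressed] <- 5 + stats::rlnorm(n_on, spec$expr_meanlog,
                                        spec$expr_sdlog)
    expr <- data.frame(gene = genes, stringsAsFactors = FALSE)
    expr[sprintf("t%02d", seq_len(spec$n_tissues))] <-
      as.data.frame(round(tpm, 3L))
    list(annotations = ann, expression = expr)
  })
}

#' Plant class labels by a logistic rule on feature columns
#'
#' Standardizes each named feature column (z-score; binary flags with zero
#' variance are left as-is), forms the linear predictor beta0 + beta . x and
#' draws labels Bernoulli(logistic(.)). When `beta0` is NULL it is calibrated
#' by root finding so the expected prevalence equals the spec target.
#'
#' @param matrix feature matrix from [assemble_feature_matrix()].
#' @param spec a [synthetic_spec()].
#' @return Character vector of positive gene identifiers, with the realized
#'   `beta0` attached as attribute "beta0".
#' @export
plant_labels <- function(matrix, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  beta <- spec$beta
  missing <- setdiff(names(beta), names(matrix))
  if (length(missing) > 0L)
    stop(sprintf("beta names not in the feature matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  eta <- numeric(nrow(matrix))
  for (f in names(beta)) {
    v <- as.numeric(matrix[[f]])
    s <- stats::sd(v)
    z <- if (s > 1e-12) (v - mean(v)) / s else v
    eta <- eta + beta[[f]] * z
  }
  beta0 <- spec$beta0
  if (is.null(beta0)) {
    f <- function(b0) mean(stats::plogis(b0 + eta)) - spec$prevalence
    beta0 <- stats::uniroot(f, c(-30, 30))$root
  }
  p <- stats::plogis(beta0 + eta)
  pos <- with_seed(derive_seed(spec$seed, 303L),
                   matrix$gene[stats::runif(nrow(matrix)) < p])
  structure(pos, beta0 = beta0)
}

#' Run the full synthetic-study generator
#'
#' Generates the network, annotations and expression, computes topology and
#' the feature matrix, and plants labels -- one call producing everything the
#' learning pipeline consumes.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `network`, `reactions`, `annotations`, `expression`,
#'   `topology`, `features` (the feature matrix) and `positives`.
#' @export
simulate_study <- function(spec) {
  net <- generate_network(spec)
  ae <- generate_annotations_expression(spec, net$network$genes)
  topo <- compute_topology(net$network)
  loc <- localization_features(ae$annotations, net$network$genes)
  ef <- expression_features(ae$expression)
  fm <- assemble_feature_matrix(topo, localization = loc, expression = ef)
  pos <- plant_labels(fm, spec)
  list(network = net$network, reactions = net$reactions,
       annotations = ae$annotations, expression = ae$expression,
       topology = topo, features = fm, positives = pos)
}
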