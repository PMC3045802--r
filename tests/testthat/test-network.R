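mk_reactions <- function(...) {
  rx <- list(...)
  out <- data.frame(reaction_id = vapply(rx, `[[`, "", 1L),
                    stringsAsFactors = FALSE)
  out$genes <- lapply(rx, `[[`, 2L)
  out$reactants <- lapply(rx, `[[`, 3L)
  out$products <- lapply(rx, `[[`, 4L)
  out
}

test_that("id normalization collapses synonyms, drops unmapped and self-loops", {
  rec <- data.frame(source = c("X1", "X2", "Y", "Z1"),
                    target = c("b", "b", "q", "Z2"),
                    layer = "ppi", stringsAsFactors = FALSE)
  idmap <- c(X1 = "G1", X2 = "G1", b = "G2", Z1 = "G3", Z2 = "G3")
  out <- normalize_ids(rec, idmap)
  expect_equal(nrow(out), 1L)
  expect_equal(out$source, "G1")
  expect_equal(out$target, "G2")
  s <- attr(out, "summary")
  expect_equal(s$dropped_unmapped, 1L)   # Y/q unmapped
  expect_equal(s$dropped_selfloop, 1L)   # Z1 -> Z2 both map to G3
  expect_equal(s$collapsed, 1L)          # X1/X2 duplicate edge to b
})

test_that("currency selection: fixed default list and top-k by connectivity", {
  expect_equal(currency_metabolites(),
               c("ADP", "ATP", "H+", "H2O", "NADP+", "NADPH",
                 "orthophosphate", "pyrophosphate"))
  rx <- mk_reactions(list("R1", "g1", "X", "A"), list("R2", "g1", "X", "B"),
                     list("R3", "g2", "X", "C"), list("R4", "g2", "B", "X"),
                     list("R5", "g3", "X", "D"))
  expect_equal(select_currency_metabolites(rx, 1L), "X")
  # X in 5 reactions, B in 2; tie between A, C, D broken lexicographically
  expect_equal(select_currency_metabolites(rx, 3L), c("X", "B", "A"))
  expect_error(select_currency_metabolites(rx, 99L), "exceeds")
})

test_that("metabolic derivation follows product-to-reactant coupling", {
  rx <- mk_reactions(list("R1", "g1", "A", "B"), list("R2", "g2", "B", "C"))
  out <- derive_metabolic_interactions(rx, currency = character())
  expect_equal(out[, c("source", "target")],
               data.frame(source = "g1", target = "g2",
                          stringsAsFactors = FALSE))
  # shared metabolite on the currency list produces nothing
  expect_equal(nrow(derive_metabolic_interactions(rx, currency = "B")), 0L)
  # the same enzyme on both sides is a self-loop, excluded
  rx2 <- mk_reactions(list("R1", "g1", "A", "B"), list("R2", "g1", "B", "C"))
  expect_equal(nrow(derive_metabolic_interactions(rx2, character())), 0L)
})

test_that("metabolic derivation matches a brute-force reaction-pair scan", {
  for (seed in 1:20) {
    set.seed(seed)
    n_rx <- sample(3:15, 1L)
    mets <- LETTERS[1:6]
    gs <- paste0("g", 1:5)
    rx <- mk_reactions()
    rx <- do.call(mk_reactions, lapply(seq_len(n_rx), function(i) {
      list(paste0("R", i),
           sample(gs, sample(0:2, 1L)),
           sample(mets, sample(1:2, 1L)),
           sample(mets, sample(1:2, 1L)))
    }))
    currency <- sample(mets, sample(0:2, 1L))
    got <- derive_metabolic_interactions(rx, currency)
    # oracle: double loop over ordered reaction pairs
    want <- character()
    for (i in seq_len(n_rx)) for (j in seq_len(n_rx)) {
      shared <- setdiff(intersect(rx$products[[i]], rx$reactants[[j]]),
                        currency)
      if (length(shared) == 0L) next
      for (a in rx$genes[[i]]) for (b in rx$genes[[j]])
        if (a != b) want <- c(want, paste(a, b))
    }
    want <- sort(unique(want))
    expect_equal(sort(paste(got$source, got$target)), want)
  }
})

test_that("removing currency metabolites never increases metabolic edges", {
  set.seed(42)
  rx <- do.call(mk_reactions, lapply(1:20, function(i) {
    list(paste0("R", i), sample(paste0("g", 1:6), sample(1:2, 1L)),
         sample(LETTERS[1:5], sample(1:2, 1L)),
         sample(LETTERS[1:5], sample(1:2, 1L)))
  }))
  n_prev <- nrow(derive_metabolic_interactions(rx, character()))
  removed <- character()
  for (m in LETTERS[1:5]) {
    removed <- c(removed, m)
    n_now <- nrow(derive_metabolic_interactions(rx, removed))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("network assembly unions layers and keeps per-layer multiplicity", {
  ppi <- data.frame(source = "a", target = "b", layer = "ppi")
  met <- data.frame(source = "b", target = "c", layer = "metabolic")
  reg <- data.frame(source = "c", target = "a", layer = "regulatory")
  net <- assemble_inhgi(ppi, met, reg)
  expect_s3_class(net, "inhgi")
  expect_equal(net$genes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 3L)
  expect_equal(sort(unique(net$edges$layer)), sort(interaction_layers()))

  # same pair in two layers -> both edges retained
  reg2 <- data.frame(source = "a", target = "b", layer = "regulatory")
  net2 <- assemble_inhgi(ppi, NULL, reg2)
  expect_equal(nrow(net2$edges), 2L)

  # empty layer is fine; per-layer dedup counts add up
  net3 <- assemble_inhgi(rbind(ppi, data.frame(source = "b", target = "a",
                                               layer = "ppi")), met, NULL)
  expect_equal(nrow(net3$edges), 2L)  # ppi duplicate collapsed
})

test_that("network summary reports per-layer counts", {
  net <- assemble_inhgi(
    ppi = data.frame(source = c("a", "b"), target = c("b", "c"),
                     layer = "ppi"),
    regulatory = data.frame(source = "c", target = "a",
                            layer = "regulatory"))
  s <- network_summary(net)
  expect_equal(s$genes, 3L)
  expect_equal(s$ppi, 2L)
  expect_equal(s$metabolic, 0L)
  expect_equal(s$regulatory, 1L)
  expect_equal(s$edges_total, 3L)
})

test_that("edge-list round trip through write_inhgi is lossless", {
  net <- random_small_inhgi(6L, seed = 9L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_inhgi(net, path)
  back <- suppressMessages(read_interactions(path))
  net2 <- assemble_inhgi(back[back$layer == "ppi", ],
                         back[back$layer == "metabolic", ],
                         back[back$layer == "regulatory", ])
  expect_equal(net2$edges, net$edges)
})
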