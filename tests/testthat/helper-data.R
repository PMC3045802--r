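# Shared small fixtures: separable toy datasets and constant-output members.

sep_dataset <- function(n = 60L, seed = 1L, noise = 0) {
  set.seed(seed)
  x1 <- c(rnorm(n / 2, -2), rnorm(n / 2, 2)) + rnorm(n, 0, noise)
  d <- data.frame(gene = sprintf("g%03d", 1:n),
                  label = factor(rep(c("negative", "positive"),
                                     each = n / 2),
                                 levels = c("negative", "positive")),
                  x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  structure(d, class = c("labeled_dataset", "data.frame"),
            provenance = list(task = "toy", variant = "normal",
                              replicate = 1L))
}

stub_member <- function(p) {
  make_member(paste0("const", p),
              fit = function(x, y, seed) p,
              predict = function(fit, x) rep(fit, nrow(x)))
}
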