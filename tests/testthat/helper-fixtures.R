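# Small builders shared across tests; everything is generated in code.

tiny_grid <- c(10L, 10L, 8L)

tiny_spec <- function(..., seed = 7L) {
  synthetic_spec(n_group1 = 3L, n_group2 = 3L, grid_dims = tiny_grid,
                 n_timepoints = 60L, seed = seed, ...)
}

tiny_roi <- function(band = standard_bands()[["slow-4"]], g1 = 1.5, g2 = 1.0,
                     base = 1) {
  roi_box("roi-a", c(3L, 3L, 3L), c(6L, 6L, 5L), band, base, g1, g2)
}

# Independently coded split-plot oracle: cell-means ANOVA via stats::aov with
# an Error(subject) stratum.  Returns the three F statistics.
aov_splitplot_F <- function(y4, y5, group) {
  n <- length(group)
  dat <- data.frame(
    y = c(y4, y5),
    band = factor(rep(c("b4", "b5"), each = n)),
    subject = factor(rep(seq_len(n), 2L)),
    group = factor(rep(group, 2L)))
  s <- summary(stats::aov(y ~ group * band + Error(subject / band),
                          data = dat))
  between <- s[["Error: subject"]][[1L]]
  within <- s[["Error: subject:band"]][[1L]]
  c(group = between["group", "F value"],
    band = within["band", "F value"],
    interaction = within["group:band", "F value"])
}
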