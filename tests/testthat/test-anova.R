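test_that("the worked 2x2 example reproduces the known t statistics", {
  # group 1 subjects: slow-4 {3, 5}, slow-5 {1, 2}; group 2: {5, 7}, {5, 6}
  res <- mixed_anova_2x2(c(3, 5, 5, 7), c(1, 2, 5, 6), c(1, 1, 2, 2))
  expect_equal(res$t[res$effect == "interaction"], 2.8284, tolerance = 1e-4)
  expect_equal(res$t[res$effect == "band"], 4.2426, tolerance = 1e-4)
  expect_equal(res$t[res$effect == "group"], -2.8284, tolerance = 1e-4)
  expect_true(all(res$df == 2))
  # against the independently coded split-plot oracle
  F <- aov_splitplot_F(c(3, 5, 5, 7), c(1, 2, 5, 6), c(1, 1, 2, 2))
  expect_equal(unname(res$t^2),
               unname(F[c("group", "band", "interaction")]),
               tolerance = 1e-8)
})

test_that("t^2 equals the split-plot F on random balanced designs", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:20, 1)
    group <- rep(c(1L, 2L), each = n)
    y4 <- rnorm(2 * n, mean = rep(c(0, 0.5), each = n))
    y5 <- rnorm(2 * n)
    res <- mixed_anova_2x2(y4, y5, group)
    F <- aov_splitplot_F(y4, y5, group)
    expect_equal(unname(res$t^2),
                 unname(F[c("group", "band", "interaction")]),
                 tolerance = 1e-8)
  }
})

test_that("swapping group labels flips group and interaction signs only", {
  set.seed(5)
  y4 <- rnorm(10); y5 <- rnorm(10); g <- rep(c(1L, 2L), each = 5)
  a <- mixed_anova_2x2(y4, y5, g)
  b <- mixed_anova_2x2(y4, y5, 3L - g)
  expect_equal(b$t[b$effect == "group"], -a$t[a$effect == "group"])
  expect_equal(b$t[b$effect == "interaction"],
               -a$t[a$effect == "interaction"])
  expect_equal(b$t[b$effect == "band"], a$t[a$effect == "band"])
})

test_that("degenerate and undersized inputs error", {
  expect_error(mixed_anova_2x2(c(1, 1, 1, 1), c(2, 2, 2, 2), c(1, 1, 2, 2)),
               "degenerate")
  expect_error(mixed_anova_2x2(c(1, 2, 3), c(1, 2, 3), c(1, 2, 2)),
               ">= 2 subjects")
})

test_that("voxelwise ANOVA matches the scalar routine per voxel and flags degenerate voxels", {
  set.seed(6)
  mask <- array(TRUE, c(3, 2, 2))
  nvox <- 12; n <- 8
  g <- rep(c(1L, 2L), each = 4)
  y4 <- matrix(rnorm(nvox * n), nvox, n)
  y5 <- matrix(rnorm(nvox * n), nvox, n)
  y4[5, ] <- 1; y5[5, ] <- 0   # zero variance voxel
  sm <- voxelwise_mixed_anova(y4, y5, g, mask)
  expect_equal(sm$df, 6)
  expect_true(sm$degenerate[5])
  expect_true(is.na(sm$t_group[mask][5]))
  for (v in c(1, 3, 12)) {
    ref <- mixed_anova_2x2(y4[v, ], y5[v, ], g)
    expect_equal(sm$t_group[mask][v], ref$t[ref$effect == "group"],
                 tolerance = 1e-12)
    expect_equal(sm$t_band[mask][v], ref$t[ref$effect == "band"],
                 tolerance = 1e-12)
    expect_equal(sm$t_interaction[mask][v],
                 ref$t[ref$effect == "interaction"], tolerance = 1e-12)
  }
})

test_that("group labels are exchangeable under the null: permuted max |t| matches in distribution", {
  set.seed(99)
  nvox <- 300; n <- 12
  y4 <- matrix(rnorm(nvox * n), nvox, n)
  y5 <- matrix(rnorm(nvox * n), nvox, n)
  mask <- array(TRUE, c(nvox, 1, 1))
  max_t <- function(perm) {
    g <- integer(n); g[perm] <- 1L; g[-perm] <- 2L
    an <- voxelwise_mixed_anova(y4, y5, g, mask)
    max(abs(an$t_interaction), na.rm = TRUE)
  }
  batch <- function(k) vapply(seq_len(k), function(i)
    max_t(sample.int(n, n / 2)), numeric(1))
  ks <- suppressWarnings(ks.test(batch(100), batch(100)))
  expect_gt(ks$p.value, 0.01)
})

test_that("critical_t matches the t quantile and its limits", {
  expect_equal(critical_t(0.05, 78), qt(0.975, 78))
  expect_equal(round(critical_t(0.05, 78), 4), 1.9908)
  expect_equal(critical_t(0.05, 1e6), 1.96, tolerance = 1e-3)
  expect_lt(critical_t(0.999, 50), 0.01)   # p -> 1 drives the threshold to 0
  expect_error(critical_t(0, 10), "p_two_tailed")
  expect_error(critical_t(0.05, 0), "df")
})
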