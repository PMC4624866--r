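test_that("connected components match hand-enumerated cases", {
  slab <- array(FALSE, c(3, 3, 1))
  slab[1, 1, 1] <- slab[1, 2, 1] <- slab[3, 2, 1] <- slab[3, 3, 1] <- TRUE
  for (conn in c(6, 18, 26)) {
    cl <- find_clusters(slab, conn)
    expect_equal(cl$n_clusters, 2)
    expect_equal(cl$sizes, c(2L, 2L))
  }

  diag2 <- array(FALSE, c(2, 2, 1))
  diag2[1, 1, 1] <- diag2[2, 2, 1] <- TRUE
  expect_equal(find_clusters(diag2, 26)$n_clusters, 1)
  expect_equal(find_clusters(diag2, 6)$n_clusters, 2)

  expect_equal(find_clusters(array(TRUE, c(4, 4, 4)), 6)$sizes, 64L)
  empty <- find_clusters(array(FALSE, c(3, 3, 3)), 26)
  expect_equal(empty$n_clusters, 0)

  # labels are deterministic scan-order
  two <- array(FALSE, c(5, 1, 1)); two[c(1, 4)] <- TRUE
  lab <- find_clusters(two, 6)$labels
  expect_equal(lab[1, 1, 1], 1L)
  expect_equal(lab[4, 1, 1], 2L)
})

test_that("strict mm^3 rule converts to 134 voxels at 27 mm^3", {
  expect_equal(cluster_threshold_from_mm3(3591, 27), 134L)
  expect_equal(cluster_threshold_from_mm3(3590, 27), 133L)  # 133*27 = 3591 > 3590
  expect_equal(cluster_threshold_from_mm3(3591.5, 27), 134L)
  expect_equal(cluster_threshold_from_mm3(26, 27), 1L)
})

test_that("threshold_statmap keeps only clusters at or above the extent threshold", {
  grid <- volume_grid(c(12, 12, 12), 3)
  df <- 78
  tc <- critical_t(0.05, df)
  tmap <- array(0, c(12, 12, 12))
  tmap[2:6, 2:7, 2:7] <- tc + 1          # 5*6*6 = 180 voxels
  tmap[9:11, 9:11, 9:11] <- -(tc + 2)    # 27 voxels
  rep_ <- threshold_statmap(tmap, df, 0.05, 140, grid)
  expect_equal(nrow(rep_$table), 1)
  expect_equal(rep_$table$size_voxels, 180)
  expect_equal(rep_$table$size_mm3, 180 * 27)
  expect_equal(rep_$table$sign, "positive")

  rep2 <- threshold_statmap(tmap, df, 0.05, 20, grid)
  expect_equal(nrow(rep2$table), 2)
  expect_equal(sort(rep2$table$size_voxels), c(27, 180))

  # sign flip swaps positive and negative excursions exactly
  rep3 <- threshold_statmap(-tmap, df, 0.05, 20, grid)
  expect_equal(sort(rep3$table$size_voxels), sort(rep2$table$size_voxels))
  expect_equal(sort(rep3$table$peak_t), sort(-rep2$table$peak_t))
  expect_setequal(rep3$table$sign, c("positive", "negative"))

  # empty result is a valid report
  rep4 <- threshold_statmap(array(0, c(12, 12, 12)), df, 0.05, 10, grid)
  expect_equal(nrow(rep4$table), 0)
})

test_that("peak coordinates are 0-based indices with matching mm", {
  grid <- volume_grid(c(8, 8, 8), 3, origin_mm = c(-12, -12, -12))
  tmap <- array(0, c(8, 8, 8))
  tmap[3:5, 3:5, 3:5] <- 3
  tmap[4, 4, 5] <- 9                      # peak
  rep_ <- threshold_statmap(tmap, 30, 0.05, 1, grid)
  expect_equal(rep_$table$peak_t, 9)
  expect_equal(c(rep_$table$peak_i, rep_$table$peak_j, rep_$table$peak_k),
               c(3, 3, 4))
  expect_equal(c(rep_$table$peak_x_mm, rep_$table$peak_y_mm,
                 rep_$table$peak_z_mm), c(-3, -3, 0))
})

test_that("alphasim: unsmoothed strict threshold gives tiny clusters, limits and determinism hold", {
  mask <- array(TRUE, c(20, 20, 20))
  res <- alphasim_threshold(mask, voxel_p = 0.001, alpha = 0.05,
                            n_iterations = 1000, fwhm_mm = 0, seed = 13)
  # ~8 isolated supra-threshold voxels expected; adjacency is rare
  expect_lte(res$threshold_voxels, 3)

  # alpha -> 1 limit: once alpha exceeds P(any suprathreshold voxel), a
  # single voxel suffices (needs a strict voxel_p so that probability < 1)
  resa1 <- alphasim_threshold(array(TRUE, c(8, 8, 8)), voxel_p = 1e-4,
                              alpha = 0.999, n_iterations = 100,
                              fwhm_mm = 0, seed = 14)
  expect_equal(resa1$threshold_voxels, 1L)

  r1 <- alphasim_threshold(mask, n_iterations = 100, fwhm_mm = 6, seed = 15)
  r2 <- alphasim_threshold(mask, n_iterations = 100, fwhm_mm = 6, seed = 15)
  expect_identical(r1$max_cluster_sizes, r2$max_cluster_sizes)
  expect_identical(r1$threshold_voxels, r2$threshold_voxels)

  # smoothing enlarges null clusters
  r0 <- alphasim_threshold(mask, n_iterations = 100, fwhm_mm = 0, seed = 15)
  expect_gte(r1$threshold_voxels, r0$threshold_voxels)

  # a stricter voxel p gives a smaller or equal extent threshold
  rstrict <- alphasim_threshold(mask, voxel_p = 0.01, n_iterations = 100,
                                fwhm_mm = 6, seed = 15)
  expect_lte(rstrict$threshold_voxels, r1$threshold_voxels)

  expect_error(alphasim_threshold(array(FALSE, c(4, 4, 4))), "empty")
  expect_error(alphasim_threshold(mask, n_iterations = 10), "100 iterations")
})

test_that("dice_overlap is 1 on identity, 0 on disjoint sets", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(dice_overlap(a, a), 1)
  expect_equal(dice_overlap(a, b), 0)
  expect_equal(dice_overlap(a, a | b), 2 * 8 / (8 + 16))
})
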