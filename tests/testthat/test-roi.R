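test_that("sphere masks match exhaustive enumeration in world space", {
  grid <- voxel_grid(c(20, 20, 15), c(2, 2, 2), origin_mm = c(-10, -10, -5))

  # degenerate sphere on a voxel centre
  m0 <- sphere_mask(grid, c(0, 0, 1), 0)
  expect_identical(nrow(m0$voxels), 1L)
  expect_equal(as.integer(m0$voxels[1, ]), c(6L, 6L, 4L))

  # radius 10 mm: compare against brute force over the whole grid
  center <- c(1.5, -2, 4)
  m <- sphere_mask(grid, center, 10)
  all_vox <- as.matrix(expand.grid(i = 1:20, j = 1:20, k = 1:15))
  ctr <- sweep(sweep(all_vox - 1, 2, grid$voxel_size_mm, `*`), 2,
               grid$origin_mm, `+`)
  inside <- rowSums(sweep(ctr, 2, center, `-`)^2) <= 100 + 1e-9
  expect_identical(nrow(m$voxels), sum(inside))
  expect_setequal(apply(m$voxels, 1, paste, collapse = ","),
                  apply(all_vox[inside, , drop = FALSE], 1, paste,
                        collapse = ","))

  # determinism and monotonicity in the radius
  expect_identical(sphere_mask(grid, center, 5)$voxels,
                   sphere_mask(grid, center, 5)$voxels)
  for (r in c(0, 2, 4, 6, 8)) {
    small <- apply(sphere_mask(grid, center, r)$voxels, 1, paste,
                   collapse = ",")
    big <- apply(sphere_mask(grid, center, r + 2)$voxels, 1, paste,
                 collapse = ",")
    expect_true(all(small %in% big))
  }

  # far off-grid centre gives an empty mask, not an error
  expect_identical(nrow(sphere_mask(grid, c(500, 500, 500), 10)$voxels), 0L)
  # anisotropic EPI-like voxels
  aniso <- voxel_grid(c(10, 10, 10), c(3.13, 3.13, 3.6))
  ma <- sphere_mask(aniso, c(15, 15, 18), 5)
  ctr_a <- sweep(sweep(as.matrix(expand.grid(i = 1:10, j = 1:10, k = 1:10)) -
                         1, 2, aniso$voxel_size_mm, `*`), 2, c(0, 0, 0), `+`)
  expect_identical(nrow(ma$voxels),
                   sum(rowSums(sweep(ctr_a, 2, c(15, 15, 18), `-`)^2) <=
                         25 + 1e-9))
})

test_that("threshold intersection keeps strictly supra-threshold voxels", {
  grid <- voxel_grid(c(6, 6, 6))
  m <- sphere_mask(grid, c(2.5, 2.5, 2.5), 2)
  set.seed(1)
  tmap <- array(rnorm(216), c(6, 6, 6))

  expect_identical(intersect_with_threshold(m, tmap, -Inf)$voxels, m$voxels)
  expect_identical(
    nrow(intersect_with_threshold(m, tmap, max(tmap))$voxels), 0L)

  thr <- 0.3
  kept <- intersect_with_threshold(m, tmap, thr)
  manual <- m$voxels[tmap[m$voxels] > thr, , drop = FALSE]
  expect_identical(kept$voxels, manual)

  wrong <- array(0, c(5, 6, 6))
  expect_error(intersect_with_threshold(m, wrong, 0), "dimensions")
})

test_that("template fit score is inside-minus-outside mean intensity", {
  grid <- voxel_grid(c(4, 4, 4))
  s1 <- voxel_mask(grid, rbind(c(1, 1, 1), c(2, 1, 1)))
  s2 <- voxel_mask(grid, rbind(c(4, 4, 4), c(2, 1, 1)))  # overlaps s1

  ind <- array(0, c(4, 4, 4))
  ind[rbind(c(1, 1, 1), c(2, 1, 1), c(4, 4, 4))] <- 1
  expect_equal(template_fit_score(ind, list(s1, s2)), 1)
  expect_equal(template_fit_score(array(7, c(4, 4, 4)), list(s1, s2)), 0)

  set.seed(2)
  m <- array(rnorm(64), c(4, 4, 4))
  inside <- rbind(c(1, 1, 1), c(2, 1, 1), c(4, 4, 4))
  manual <- mean(m[inside]) - mean(m[-c(1, 2, 64)])
  expect_equal(template_fit_score(m, list(s1, s2)), manual)

  # shift invariance and linear scaling
  expect_equal(template_fit_score(m + 5, list(s1, s2)),
               template_fit_score(m, list(s1, s2)))
  expect_equal(template_fit_score(3 * m, list(s1, s2)),
               3 * template_fit_score(m, list(s1, s2)))
})

test_that("best-fit component selection maximises the score, ties low", {
  grid <- voxel_grid(c(4, 4, 4))
  sph <- list(voxel_mask(grid, rbind(c(2, 2, 2), c(3, 2, 2))))
  base <- array(0, c(4, 4, 4))
  good <- base; good[2, 2, 2] <- good[3, 2, 2] <- 5
  weak <- base; weak[2, 2, 2] <- 1
  sel <- select_best_component(list(weak, good, weak), sph)
  expect_identical(sel$index, 2L)
  tie <- select_best_component(list(good, good), sph)
  expect_identical(tie$index, 1L)
})

test_that("ROI extraction averages mask voxels per time point", {
  grid <- voxel_grid(c(3, 3, 3))
  set.seed(3)
  vol <- array(rnorm(27 * 5), c(3, 3, 3, 5))

  single <- voxel_mask(grid, rbind(c(2, 3, 1)))
  expect_equal(extract_roi_timeseries(vol, single), vol[2, 3, 1, ])

  const <- array(4.2, c(3, 3, 3, 5))
  m <- voxel_mask(grid, rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  expect_equal(extract_roi_timeseries(const, m), rep(4.2, 5))

  manual <- sapply(1:5, function(t)
    mean(c(vol[1, 1, 1, t], vol[2, 2, 2, t], vol[3, 3, 3, t])))
  expect_equal(extract_roi_timeseries(vol, m), manual)

  empty <- voxel_mask(grid, matrix(integer(0), 0, 3))
  expect_error(extract_roi_timeseries(vol, empty), "empty")
})

test_that("masks serialize to JSON and back unchanged", {
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2), c(-8, -8, -8))
  m <- sphere_mask(grid, c(0, 0, 0), 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_mask_json(m, path)
  back <- read_mask_json(path)
  expect_identical(back$voxels, m$voxels)
  expect_equal(back$grid$voxel_size_mm, m$grid$voxel_size_mm)
  expect_equal(back$grid$origin_mm, m$grid$origin_mm)
})
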