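# The morphology oracle: brute-force neighborhood scans on the same array,
# independent of the EBImage-based implementation path.
brute_morph <- function(m, kernel, fun) {
  r <- (ncol(kernel) - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- max(1, i - r):min(nrow(m), i + r)
    jj <- max(1, j - r):min(ncol(m), j + r)
    k <- kernel[ii - i + r + 1, jj - j + r + 1, drop = FALSE]
    out[i, j] <- fun(m[ii, jj][k == 1])
  }
  out
}

disk_img <- function(n, cx, cy, r, bg = 0, fg = 255) {
  m <- matrix(bg, n, n)
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  m[d2 <= r^2] <- fg
  m
}

test_that("prepare_channel downsamples and rescales to 8 bits", {
  set.seed(1)
  img <- toy_image(DNA1 = matrix(runif(100 * 100, 0, 1023), 100))
  cfg <- artifact_config(downsample_factor = 4, rescale = "minmax")
  p <- prepare_channel(img, "DNA1", cfg)
  expect_equal(dim(p), c(25, 25))
  expect_equal(min(p), 0)
  expect_equal(max(p), 255)
  # constant channel degenerates to all zeros
  cimg <- toy_image(DNA1 = matrix(7, 40, 40))
  expect_true(all(prepare_channel(cimg, "DNA1", cfg) == 0))
})

test_that("rescaling preserves rank order of distinct block means", {
  ramp <- toy_image(DNA1 = matrix(seq(0, 1023, length.out = 1600), 40, 40))
  cfg <- artifact_config(downsample_factor = 4, rescale = "minmax")
  p <- prepare_channel(ramp, "DNA1", cfg)
  blocks <- mplexqc:::.block_mean(ramp$pixels[, , 1], 4)
  expect_identical(order(as.numeric(p)), order(as.numeric(blocks)))
})

test_that("the morphological transform matches a brute-force oracle", {
  cfg <- artifact_config(downsample_factor = 1, kernel_diameter = 5)
  # constant image is unchanged
  const <- matrix(100, 30, 30)
  expect_true(all(abs(transform_channel(const, cfg, kernel = 5) - 100) < 1e-9))
  # a single bright pixel is erased by erosion
  spot <- matrix(0, 30, 30); spot[15, 15] <- 255
  expect_lt(max(transform_channel(spot, cfg, kernel = 5)), 1)
  # a large bright disk survives with comparable area
  d <- disk_img(60, 30, 30, 15.5)
  t <- transform_channel(d, cfg, kernel = 5)
  expect_lt(abs(sum(t > 128) - sum(d > 128)) / sum(d > 128), 0.15)
  # oracle comparison in the interior, away from border effects
  set.seed(2)
  g <- matrix(runif(625, 0, 255), 25, 25)
  k <- mplexqc:::.disk_kernel(5)
  oracle <- brute_morph(brute_morph(brute_morph(g, k, min), k, mean), k, max)
  mine <- transform_channel(g, cfg, kernel = 5)
  inner <- 7:19
  expect_equal(mine[inner, inner], oracle[inner, inner], tolerance = 2)
})

test_that("seed finding matches an exhaustive local-maximum scan", {
  cfg <- artifact_config(downsample_factor = 1, kernel_diameter = 3,
                         seed_kernel_scale = 2)
  flat <- matrix(5, 40, 40)
  expect_equal(nrow(find_seeds(flat, cfg, kernel = 3)), 0)

  one <- disk_img(60, 20, 20, 6, bg = 2)
  t1 <- transform_channel(one, cfg, kernel = 3)
  s1 <- find_seeds(t1, cfg, kernel = 3)
  expect_equal(nrow(s1), 1)
  # oracle: the argmax of the transformed image
  peak <- which(t1 == max(t1), arr.ind = TRUE)
  expect_lte(min(sqrt((s1$row - peak[, 1])^2 + (s1$col - peak[, 2])^2)), 7)

  two <- pmax(disk_img(80, 20, 20, 6, bg = 2), disk_img(80, 60, 60, 6, bg = 2))
  t2 <- transform_channel(two, cfg, kernel = 3)
  expect_equal(nrow(find_seeds(t2, cfg, kernel = 3)), 2)
})

test_that("flood fill follows the threshold-component oracle", {
  cfg <- artifact_config(downsample_factor = 1, kernel_diameter = 3,
                         tolerance = 50, tolerance_mode = "absolute",
                         min_region_area = 5, flood_mad_k = NULL,
                         mask_dilate = 0)
  img <- disk_img(100, 50, 50, 20, bg = 10, fg = 200)
  seeds <- tibble::tibble(row = 50L, col = 50L, value = 200)
  m <- flood_fill_mask(img, seeds, cfg, kernel = 3)
  # oracle: pixels >= 150 connected to the seed
  expect_lt(abs(sum(m$mask) - pi * 20^2) / (pi * 20^2), 0.05)
  expect_true(all(img[m$mask] >= 150))

  # tolerance 0 keeps exactly the seed-valued connected set
  cfg0 <- artifact_config(downsample_factor = 1, tolerance = 0,
                          tolerance_mode = "absolute", min_region_area = 1,
                          flood_mad_k = NULL, mask_dilate = 0)
  m0 <- flood_fill_mask(img, seeds, cfg0, kernel = 3)
  expect_true(all(img[m0$mask] == 200))
  expect_equal(sum(m0$mask), sum(img == 200))

  # two disjoint blobs with a seed in each give two components
  img2 <- pmax(disk_img(100, 25, 25, 10, bg = 10, fg = 200),
               disk_img(100, 75, 75, 10, bg = 10, fg = 200))
  seeds2 <- tibble::tibble(row = c(25L, 75L), col = c(25L, 75L),
                           value = c(200, 200))
  m2 <- flood_fill_mask(img2, seeds2, cfg, kernel = 3)
  expect_equal(nrow(m2$regions), 2)
})

test_that("masks are monotone in tolerance for fixed seeds", {
  set.seed(3)
  img <- disk_img(80, 40, 40, 15, bg = 20, fg = 180) +
    matrix(rnorm(6400, 0, 10), 80)
  seeds <- tibble::tibble(row = 40L, col = 40L, value = img[40, 40])
  prev <- NULL
  for (tol in c(10, 30, 60, 120)) {
    cfg <- artifact_config(downsample_factor = 1, tolerance = tol,
                           tolerance_mode = "absolute", min_region_area = 1,
                           flood_mad_k = NULL, mask_dilate = 0)
    m <- flood_fill_mask(img, seeds, cfg, kernel = 3)$mask
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("a constant image yields no artifacts end to end", {
  img <- toy_image(DNA1 = matrix(42, 80, 80))
  masks <- detect_artifacts(img, config = artifact_config(downsample_factor = 2))
  expect_equal(sum(masks$DNA1$mask), 0)
})

test_that("cells are dropped by centroid membership in the upscaled mask", {
  mask <- structure(list(channel = "x",
                         mask = rbind(c(TRUE, FALSE), c(FALSE, FALSE)),
                         downsample_factor = 10,
                         regions = tibble::tibble()),
                    class = "artifact_mask")
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:3,
                       x = c(5, 15, 5), y = c(5, 5, 15),
                       area = 1, status = "retained")
  out <- drop_cells_in_mask(tb, mask, c(20, 20))
  expect_identical(out$status, c("dropped_roi", "retained", "retained"))
  # empty mask leaves the table unchanged
  mask$mask[] <- FALSE
  out2 <- drop_cells_in_mask(tb, mask, c(20, 20))
  expect_identical(out2$status, tb$status)
})

test_that("the detector redacts aggregate-affected cells on a phantom", {
  ph <- generate_phantom(phantom_spec(
    seed = 31, artifacts = phantom_artifacts()["aggregate"]))
  aff <- ph$truth$affected_cells$aggregate
  skip_if(length(aff) < 10)
  u <- combine_masks(detect_artifacts(ph$image, config = artifact_config()))
  tb <- drop_cells_in_mask(ph$table, u, dim(ph$mask))
  sc <- score_redaction(tb, aff)
  expect_gte(sc$recall, 0.9)
  expect_lte(sc$false_drop, 0.02)
})
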