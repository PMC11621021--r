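test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(phantom_spec(image_size = 200, seed = 9))
  b <- generate_phantom(phantom_spec(image_size = 200, seed = 9))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
})

test_that("feature table is consistent with the rendered image and mask", {
  ph <- full_phantom()
  lp <- which(ph$mask > 0)
  labs <- ph$mask[lp]
  for (ch in c("DNA1", "CD45", "panCK")) {
    v <- ph$image$pixels[, , ch]
    m <- rowsum(v[lp], labs)[, 1] / tabulate(labs)[sort(unique(labs))]
    expect_equal(unname(m), ph$table[[ch]], tolerance = 1e-12)
  }
  # areas equal mask pixel counts; centroids are 0-based means
  expect_equal(ph$table$area, as.numeric(tabulate(labs)[sort(unique(labs))]))
  expect_true(all(ph$table$x >= 0 & ph$table$x < ncol(ph$mask)))
  expect_true(all(ph$table$y >= 0 & ph$table$y < nrow(ph$mask)))
})

test_that("nuclei respect the Poisson-disk minimum spacing", {
  ph <- clean_phantom()
  pts <- cbind(ph$table$x, ph$table$y)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  # centroids shift from the placed centres where neighbouring disks
  # contest pixels (first-placed wins), by at most ~1 px
  expect_gte(min(d), ph$spec$min_spacing - 1.5)
})

test_that("impossible density errors out", {
  expect_error(
    generate_phantom(phantom_spec(image_size = 100, cell_density = 0.05,
                                  min_spacing = 8, seed = 1, artifacts = "none")),
    "density"
  )
})

test_that("fold cells are brighter than matched clean cells in every channel", {
  ph <- generate_phantom(phantom_spec(seed = 3,
                                      artifacts = phantom_artifacts()["fold"]))
  fold_ids <- ph$truth$affected_cells$fold
  skip_if(length(fold_ids) < 5)
  tb <- ph$table
  in_fold <- tb$cell_id %in% fold_ids
  for (ch in intensity_channels(tb)) {
    ratio <- mean(tb[[ch]][in_fold]) / mean(tb[[ch]][!in_fold])
    expect_gte(ratio, 1.5)
  }
})

test_that("artifact-free phantom reproduces the type means", {
  ph <- clean_phantom()
  types <- ph$spec$cell_types
  tb <- dplyr::left_join(ph$table, ph$truth$true_type, by = "cell_id")
  for (i in seq_len(nrow(types))) {
    sel <- tb$type == types$name[i]
    n <- sum(sel)
    skip_if(n < 10)
    for (m in ph$spec$markers) {
      obs <- mean(log10(tb[[m]][sel]))
      # cell-to-cell sd shrinks by sqrt(n); background adds a small positive bias
      expect_lt(abs(obs - types[[m]][i]), 3 * ph$spec$marker_sd / sqrt(n) + 0.05)
    }
  }
})

test_that("affected cell sets equal centroid-in-map membership", {
  ph <- full_phantom()
  H <- nrow(ph$mask); W <- ncol(ph$mask)
  for (cls in c("fold", "aggregate", "cell_loss")) {
    map <- ph$truth$artifact_map[[cls]]
    ridx <- pmin(pmax(round(ph$table$y) + 1L, 1L), H)
    cidx <- pmin(pmax(round(ph$table$x) + 1L, 1L), W)
    expect_setequal(ph$truth$affected_cells[[cls]],
                    ph$table$cell_id[map[cbind(ridx, cidx)]])
  }
})

test_that("cell loss dims late DNA cycles by the configured factor", {
  ph <- generate_phantom(phantom_spec(
    seed = 4, artifacts = phantom_artifacts()["cell_loss"]))
  tb <- ph$table
  lost <- tb$cell_id %in% ph$truth$lost_cells
  r <- log10(tb$DNA1 / tb$DNA3)
  expect_equal(median(r[lost]), log10(1 / 0.05), tolerance = 0.05)
  expect_equal(median(r[!lost]), 0, tolerance = 0.05)
})

test_that("scoring helpers behave at the extremes", {
  truth <- matrix(FALSE, 20, 20); truth[5:10, 5:10] <- TRUE
  expect_equal(score_mask_iou(truth, truth), 1)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(score_mask_iou(empty, truth), 0)
  # random mask of equal area has IoU near a/(2-a), the independence value
  set.seed(1)
  a <- mean(truth)
  ious <- replicate(200, {
    m <- matrix(sample(c(TRUE, FALSE), 400, TRUE, c(a, 1 - a)), 20)
    score_mask_iou(m, truth)
  })
  expect_lt(abs(mean(ious) - a / (2 - a)), 0.01)

  tb <- tibble::tibble(sample_id = "s", cell_id = 1:10, x = 0, y = 0,
                       area = 1, status = c(rep("dropped_roi", 5),
                                            rep("retained", 5)))
  sc <- score_redaction(tb, affected_ids = 1:5)
  expect_equal(sc$recall, 1)
  expect_equal(sc$false_drop, 0)
  sc2 <- score_redaction(tb, affected_ids = 6:10)
  expect_equal(sc2$recall, 0)
})

test_that("exemplar tree is complete, loadable and regeneration-identical", {
  dir1 <- withr::local_tempdir()
  man <- make_exemplar(dir1, n_specimens = 2, size = 150, seed = 5,
                       artifacts = phantom_artifacts()["aggregate"])
  files <- list.files(dir1)
  expect_length(grep("_image.tif$", files), 2)
  expect_length(grep("_mask.tif$", files), 2)
  expect_length(grep("_boundary.tif$", files), 2)
  expect_length(grep("_cells.csv$", files), 2)
  expect_true("manifest.yml" %in% files)

  e <- man$specimens[[1]]
  sp <- load_specimen(e$image, e$mask, e$table,
                      c(e, list(id_col = "CellID")))
  expect_s3_class(sp$table, "tbl_df")
  expect_gt(nrow(sp$table), 0)

  dir2 <- withr::local_tempdir()
  make_exemplar(dir2, n_specimens = 2, size = 150, seed = 5,
                artifacts = phantom_artifacts()["aggregate"])
  for (f in grep("tif$|csv$", files, value = TRUE)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7), label = f)
  }
})
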