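# a feature table of k well-separated synthetic phenotypes
phenotype_table <- function(n_per = 150, k = 2, p = 6, sep = 2, seed = 3) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * p), k, p) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(n_per * p, 0, 0.15), n_per, p) +
        matrix(centers[i, ], n_per, p, byrow = TRUE)
    }))
    colnames(x) <- paste0("M", seq_len(p))
    tb <- tibble::tibble(sample_id = "s", cell_id = seq_len(nrow(x)),
                         x = 0, y = 0, area = 1)
    tb <- dplyr::bind_cols(tb, tibble::as_tibble(x))
    tb$status <- "retained"
    list(table = tb, labels = rep(seq_len(k) - 1, each = n_per))
  })
}

test_that("parallel analysis counts planted factors and clamps to 2..3", {
  withr::with_seed(1, noise <- matrix(rnorm(5000), 500, 10))
  hp <- horns_parallel(noise, n_iter = 100, seed = 1)
  expect_equal(hp$raw_count, 0)
  expect_equal(hp$n_components, 2)       # clamped up

  plant <- function(k, seed) {
    withr::with_seed(seed, {
      L <- qr.Q(qr(matrix(rnorm(10 * k), 10, k)))
      matrix(rnorm(500 * k), 500, k) %*% t(L) * 3 +
        matrix(rnorm(5000), 500, 10)
    })
  }
  expect_equal(horns_parallel(plant(3, 2), n_iter = 100, seed = 2)$n_components, 3)
  expect_equal(horns_parallel(plant(2, 3), n_iter = 100, seed = 3)$n_components, 2)

  with_const <- cbind(noise, C = 1)
  expect_warning(horns_parallel(with_const, n_iter = 100, seed = 4), "constant")
  expect_error(horns_parallel(noise, n_iter = 50), "100")
})

test_that("subsampling is uniform, seeded and the identity when small", {
  tb <- phenotype_table()$table
  expect_identical(subsample_cells(tb, nrow(tb) + 100, seed = 1), tb)
  s1 <- subsample_cells(tb, 50, seed = 1)
  s2 <- subsample_cells(tb, 50, seed = 1)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50)
  expect_false(identical(s1, subsample_cells(tb, 50, seed = 2)))
})

test_that("the embedding separates phenotypes and is reproducible", {
  pt <- phenotype_table(n_per = 150, k = 2, sep = 3)
  emb <- embed_cells(pt$table, seed = 5)
  e <- cbind(emb$embed_1, emb$embed_2)
  cent <- rowsum(e, pt$labels) / as.numeric(table(pt$labels))
  inter <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  intra <- sapply(0:1, function(l) {
    ee <- e[pt$labels == l, ]
    as.numeric(quantile(dist(ee[sample(nrow(ee), 80), ]), 0.95))
  })
  expect_gt(inter, max(intra))

  emb2 <- embed_cells(pt$table, seed = 5)
  expect_identical(emb$embed_1, emb2$embed_1)

  # duplicated rows land on near-coincident points
  dup <- pt$table[c(1, 1, 1:198), ]
  dup$cell_id <- seq_len(nrow(dup))
  ed <- embed_cells(dup, seed = 5)
  d12 <- sqrt((ed$embed_1[1] - ed$embed_1[2])^2 +
              (ed$embed_2[1] - ed$embed_2[2])^2)
  expect_lt(d12, median(dist(cbind(ed$embed_1, ed$embed_2)[1:100, ])))
  expect_error(embed_cells(pt$table[1:5, ]), "10 cells")
})

test_that("silhouette scores behave at the reference points", {
  b <- two_blobs(n = 100, sep = 12, sd = 0.5)
  s <- silhouette_scores(b$x, b$labels)
  expect_gt(mean(s), 0.9)
  expect_error(silhouette_scores(b$x, rep(0L, nrow(b$x))), "undefined")
  # a point equidistant from two tight clusters scores near zero
  x <- rbind(matrix(c(0, 0), 50, 2, byrow = TRUE) + rnorm(100, 0, 1e-3),
             matrix(c(10, 0), 50, 2, byrow = TRUE) + rnorm(100, 0, 1e-3),
             c(5, 0))
  lab <- c(rep(0L, 50), rep(1L, 50), 0L)
  s2 <- silhouette_scores(x, lab)
  expect_lt(abs(s2[101]), 0.05)
  # unclustered cells get NA
  lab[1] <- -1L
  expect_true(is.na(silhouette_scores(x, lab)[1]))
})

test_that("cluster profiles normalise rows to [0,1] and z-score correctly", {
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:6, x = 0, y = 0, area = 1,
                       M1 = c(2, 2, 4, 4, 6, 6),
                       M2 = c(5, 5, 5, 5, 5, 5),
                       status = "retained",
                       cluster = c(0L, 0L, 1L, 1L, 2L, 2L))
  prof <- cluster_profile(tb, channels = c("M1", "M2"))
  expect_equal(unname(prof$normalized["M1", ]), c(0, 0.5, 1))
  expect_equal(unname(prof$normalized["M2", ]), c(0, 0, 0))
  expect_equal(unname(prof$zscore["M1", ]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unname(prof$zscore["M2", ]), c(0, 0, 0))
  expect_true(all(prof$normalized >= 0 & prof$normalized <= 1))
  expect_equal(mean(prof$zscore["M1", ]), 0, tolerance = 1e-12)
})

test_that("meta-clustering groups profile blocks as planted", {
  # two blocks of clusters with distinct mean vectors
  mean_i <- cbind(c(10, 10, 0), c(10.2, 9.9, 0.1), c(0, 0.1, 9.9),
                  c(0.2, 0, 10))
  rownames(mean_i) <- c("A", "B", "C")
  colnames(mean_i) <- 0:3
  prof <- structure(list(mean_intensity = mean_i), class = "cluster_profile")
  mc <- meta_cluster(prof, k = 2)
  expect_identical(mc$meta_cluster[1], mc$meta_cluster[2])
  expect_identical(mc$meta_cluster[3], mc$meta_cluster[4])
  expect_false(mc$meta_cluster[1] == mc$meta_cluster[3])
  # identity partition at k = number of clusters
  expect_equal(length(unique(meta_cluster(prof, k = 4)$meta_cluster)), 4)
  # identical profiles merge at height zero
  two_same <- structure(list(mean_intensity = mean_i[, c(1, 1)]),
                        class = "cluster_profile")
  hc <- attr(meta_cluster(two_same, k = 1), "hclust")
  expect_equal(hc$height[1], 0)
  expect_error(meta_cluster(prof), "exactly one")
})

test_that("frequency statistics detect planted enrichment and agree with a
           permutation oracle", {
  make_counts <- function(freqs, n = 1000, seed) {
    withr::with_seed(seed, {
      rows <- list()
      for (s in seq_along(freqs[[1]])) {
        for (k in seq_along(freqs)) {
          m <- round(n * freqs[[k]][s] * runif(1, 0.9, 1.1))
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = paste0("s", s), cluster = k - 1L,
            cell_id = seq_len(m))
        }
      }
      dplyr::bind_rows(rows)
    })
  }
  # cluster 0 enriched 3x in the test arm; cluster 1 flat; cluster 2 is a
  # large background population absorbing the compositional constraint
  freqs <- list(c(0.15, 0.16, 0.14, 0.15, 0.15, 0.05, 0.06, 0.05, 0.05, 0.04),
                c(0.10, 0.09, 0.11, 0.10, 0.09, 0.10, 0.10, 0.09, 0.11, 0.10),
                c(0.75, 0.75, 0.75, 0.75, 0.76, 0.85, 0.84, 0.86, 0.84, 0.86))
  tb <- make_counts(freqs, seed = 1)
  md <- tibble::tibble(sample_id = paste0("s", 1:10),
                       condition = rep(c("test", "control"), each = 5))
  fs <- frequency_stats(tb, md)
  expect_lt(fs$q_value[fs$cluster == 0], 0.05)
  expect_gt(fs$q_value[fs$cluster == 1], 0.05)
  expect_gt(fs$log2_ratio[fs$cluster == 0], 1)

  # permutation oracle on the enriched cluster
  totals <- table(tb$sample_id)
  f0 <- as.numeric(table(factor(tb$sample_id[tb$cluster == 0],
                                levels = names(totals)))) / as.numeric(totals)
  cond <- md$condition[match(names(totals), md$sample_id)]
  obs <- abs(mean(f0[cond == "test"]) - mean(f0[cond == "control"]))
  perm <- withr::with_seed(2, replicate(2000, {
    pc <- sample(cond)
    abs(mean(f0[pc == "test"]) - mean(f0[pc == "control"]))
  }))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(fs$p_value[fs$cluster == 0] - p_perm),
            0.02 + 3 * sqrt(p_perm * (1 - p_perm) / 2000))

  # identical frequencies give ratio ~0 and q near 1
  flat <- list(c(0.3, 0.3, 0.3, 0.3), c(0.2, 0.2, 0.2, 0.2))
  tb2 <- make_counts(lapply(flat, function(f) rep(f, length.out = 4)),
                     seed = 3)
  md2 <- tibble::tibble(sample_id = paste0("s", 1:4),
                        condition = rep(c("a", "b"), each = 2))
  fs2 <- frequency_stats(tb2, md2)
  expect_lt(abs(fs2$log2_ratio[1]), 0.3)
  expect_gt(min(fs2$q_value), 0.2)

  md_bad <- tibble::tibble(sample_id = paste0("s", 1:4),
                           condition = c("a", "b", "b", "b"))
  expect_error(frequency_stats(tb2, md_bad), "2 samples")
})

test_that("contrast limits come from the reference image and flag constants", {
  img <- toy_image(DNA1 = matrix(seq(0, 255, length.out = 1e4), 100),
                   CD4 = matrix(3, 100, 100))
  cl <- set_contrast(img, percentiles = c(0, 100))
  expect_equal(cl$lower[cl$channel == "DNA1"], 0)
  expect_equal(cl$upper[cl$channel == "DNA1"], 255)
  expect_true(cl$constant[cl$channel == "CD4"])
  expect_false(cl$constant[cl$channel == "DNA1"])
})

test_that("thumbnails are fixed-size windows with top-3 marker composites", {
  ph <- clean_phantom()
  tb <- log_transform(aggregate_samples(list(ph)))
  cl <- cluster_cells(tb, min_cluster_size = 20, seed = 4, silhouette = FALSE)
  tb$cluster <- cl$cells$cluster
  skip_if(cl$fit$n_clusters < 2)
  gal <- curate_thumbnails(ph$image, ph$mask, tb, n_per_cluster = 3, seed = 6)
  # 20 um at 0.65 um/px is a 30x30 window
  expect_equal(attr(gal, "window"), 30)
  expect_true(all(vapply(gal$patch, function(p) all(dim(p) == c(30, 30, 3)),
                         logical(1))))
  expect_true(all(vapply(gal$markers, length, integer(1)) == 3))
  expect_true(all(vapply(gal$patch, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
  # seeded repeat picks identical cells
  gal2 <- curate_thumbnails(ph$image, ph$mask, tb, n_per_cluster = 3, seed = 6)
  expect_identical(gal$cell_id, gal2$cell_id)
  # a centroid at the image corner still yields a full-size (padded) patch
  tb2 <- tb
  tb2$x[1] <- 0; tb2$y[1] <- 0; tb2$cluster <- -1L
  tb2$cluster[1] <- 0L
  gal3 <- curate_thumbnails(ph$image, ph$mask, tb2, n_per_cluster = 1, seed = 1)
  expect_equal(dim(gal3$patch[[1]]), c(30, 30, 3))
})

test_that("top-3 markers come from the normalised profile column", {
  norm <- matrix(c(0.9, 0.2, 0.8, 0.7), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "0"))
  top3 <- names(sort(norm[, "0"], decreasing = TRUE))[1:3]
  expect_identical(top3, c("a", "c", "d"))
})
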