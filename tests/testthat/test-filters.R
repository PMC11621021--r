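# grid-search posterior-crossing oracle for a two-component mixture
posterior_crossing <- function(w_d, mu_d, sd_d, mu_v, sd_v) {
  g <- seq(mu_d - 3 * sd_d, mu_v, length.out = 20000)
  g[which.min(abs(w_d * dnorm(g, mu_d, sd_d) -
                  (1 - w_d) * dnorm(g, mu_v, sd_v)))]
}

test_that("a single-component fit recovers the closed-form normal quantiles", {
  withr::with_seed(1, x <- rnorm(5000, 3, 0.2))
  th <- fit_gmm_thresholds(x, n_components = 1)
  expect_equal(th$lower, 3 - 2.576 * 0.2, tolerance = 0.02)
  expect_equal(th$upper, 3 + 2.576 * 0.2, tolerance = 0.02)
  expect_identical(th$source, "gmm")
})

test_that("a two-component fit separates the dim population", {
  withr::with_seed(2, {
    x <- c(rnorm(400, 1.0, 0.1), rnorm(1600, 2.5, 0.15))
  })
  th <- fit_gmm_thresholds(x, n_components = 2)
  expect_gt(th$lower, 1.5)
  expect_lt(th$lower, 2.2)
  cross <- posterior_crossing(0.2, 1.0, 0.1, 2.5, 0.15)
  expect_gt(cross, 1.5); expect_lt(cross, 2.2)
})

test_that("degenerate inputs to the mixture fit error out", {
  expect_error(fit_gmm_thresholds(rep(3, 100)), "degenerate")
  expect_error(fit_gmm_thresholds(rnorm(10)), "at least 50")
  expect_error(fit_gmm_thresholds(rep(c(1, 2), 50), n_components = 3),
               "distinct")
  expect_error(gate(2, 1), "lower")
})

test_that("interval gates act only on out-of-bounds, still-retained cells", {
  ph <- clean_phantom()
  tb <- aggregate_samples(list(ph))
  wide <- gate(-Inf, Inf)
  expect_identical(gate_dna_intensity(tb, wide)$status, tb$status)

  below <- gate(max(tb$DNA1) + 1, Inf)
  all_dropped <- gate_dna_intensity(tb, below)
  expect_true(all(all_dropped$status == "dropped_dna_intensity"))

  # min/max bounds drop nothing (inclusive interval)
  exact <- gate(min(tb$area), max(tb$area))
  expect_identical(gate_area(tb, exact)$status, tb$status)

  # gates are monotone: widening never drops more
  mid <- gate(quantile(tb$DNA1, 0.25), quantile(tb$DNA1, 0.75),
              source = "manual")
  wide2 <- gate(quantile(tb$DNA1, 0.05), quantile(tb$DNA1, 0.95),
                source = "manual")
  n_mid <- sum(gate_dna_intensity(tb, mid)$status != "retained")
  n_wide <- sum(gate_dna_intensity(tb, wide2)$status != "retained")
  expect_lte(n_wide, n_mid)
})

test_that("dim truncated nuclei are caught by the fitted DNA gate", {
  ph <- generate_phantom(phantom_spec(
    seed = 21, artifacts = phantom_artifacts()["dim_nuclei"]))
  tb <- aggregate_samples(list(ph))
  th <- fit_gmm_thresholds(tb$DNA1, n_components = 2, transform = "log10")
  out <- gate_dna_intensity(tb, th)
  sc <- score_redaction(out, ph$truth$affected_cells$dim_nuclei)
  expect_gte(sc$recall, 0.9)
  expect_lte(sc$false_drop, 0.02)
})

test_that("segmentation errors are caught by the fitted area gate", {
  ph <- generate_phantom(phantom_spec(
    seed = 22, artifacts = phantom_artifacts()[c("overseg", "underseg")]))
  tb <- aggregate_samples(list(ph))
  th <- fit_gmm_thresholds(tb$area, n_components = 3, transform = "log10")
  out <- gate_area(tb, th)
  merged <- ph$truth$misseg_cells$merged
  split <- ph$truth$misseg_cells$split
  expect_gte(mean(out$status[out$cell_id %in% merged] == "dropped_area"), 0.9)
  # fragments well below modal area always fail the lower gate; fragments
  # near half the modal area straddle it
  modal <- median(tb$area)
  small_frag <- intersect(split, tb$cell_id[tb$area < 0.45 * modal])
  expect_gte(mean(out$status[out$cell_id %in% small_frag] == "dropped_area"),
             0.95)
  expect_gte(mean(out$status[out$cell_id %in% split] == "dropped_area"), 0.7)
})

test_that("the cycle ratio is exactly log10(first/last)", {
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:4, x = 0, y = 0, area = 1,
                       DNA1 = c(100, 1000, 50, 7),
                       DNA3 = c(100, 10, 0, 3),
                       status = "retained")
  out <- compute_cycle_ratio(tb, c("DNA1", "DNA2", "DNA3"))
  expect_identical(out$cycle_ratio[1], 0)
  expect_identical(out$cycle_ratio[2], 2)
  expect_identical(out$cycle_ratio[3], Inf)
  expect_identical(out$cycle_ratio[4], log10(7 / 3))
  expect_error(compute_cycle_ratio(tb[, -7], c("DNA1", "DNA3")), "DNA3")
})

test_that("stability gating drops the discrete positive-ratio peak", {
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:4, x = 0, y = 0, area = 1,
                       cycle_ratio = c(-0.05, 0.02, 1.4, 0.01),
                       status = "retained")
  out <- gate_stable_cells(tb, gate(-0.3, 0.3))
  expect_identical(out$status,
                   c("retained", "retained", "dropped_unstable", "retained"))
})

test_that("simulated detachment is gated with high recall, low false drop", {
  ph <- generate_phantom(phantom_spec(
    seed = 23, artifacts = phantom_artifacts()["cell_loss"]))
  tb <- compute_cycle_ratio(aggregate_samples(list(ph)), ph$image$dna_channels)
  out <- gate_stable_cells(tb, fit_ratio_bounds(tb))
  sc <- score_redaction(out, ph$truth$lost_cells)
  expect_gte(sc$recall, 0.95)
  expect_lte(sc$false_drop, 0.02)
})

test_that("without injected loss, the default bounds drop almost nothing", {
  ph <- clean_phantom()
  tb <- compute_cycle_ratio(aggregate_samples(list(ph)), ph$image$dna_channels)
  out <- gate_stable_cells(tb, fit_gmm_thresholds(tb$cycle_ratio,
                                                  n_components = 1))
  expect_lte(mean(out$status != "retained"), 0.01)
})

test_that("log transform is a finite, rank-preserving log10", {
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:3, x = 0, y = 0, area = 1,
                       CD4 = c(1000, 0, 10), status = "retained")
  out <- log_transform(tb, "CD4")
  expect_equal(out$CD4[1], 3, tolerance = 1e-2)
  expect_true(is.finite(out$CD4[2]))
  expect_identical(order(out$CD4), order(tb$CD4))
  tb$CD4[1] <- -5
  expect_error(log_transform(tb, "CD4"), "negative")
})

test_that("percentile pruning matches a sort-and-count oracle exactly", {
  # the worked example: integers 0..100, cutoffs at the 5th/95th percentile
  tb <- tibble::tibble(sample_id = "s", cell_id = 1:101, x = 0, y = 0,
                       area = 1, CD4 = 0:100, status = "retained")
  out <- prune_percentile_outliers(tb, "CD4", p_lo = 5, p_hi = 95)
  expect_equal(sum(out$status == "dropped_outlier"), 10)
  expect_setequal(out$cell_id[out$status == "dropped_outlier"],
                  tb$cell_id[tb$CD4 < 5 | tb$CD4 > 95])

  # identity at (0, 100)
  out0 <- prune_percentile_outliers(tb, "CD4", p_lo = 0, p_hi = 100)
  expect_identical(out0$status, tb$status)
  expect_error(prune_percentile_outliers(tb, "CD4", p_lo = 50, p_hi = 50))

  # exact oracle equivalence on random values
  withr::with_seed(5, v <- rnorm(10000))
  tb2 <- tibble::tibble(sample_id = "s", cell_id = seq_along(v), x = 0, y = 0,
                        area = 1, CD4 = v, status = "retained")
  out2 <- prune_percentile_outliers(tb2, "CD4", p_lo = 1, p_hi = 99)
  srt <- sort(v)
  q7 <- function(p) {                    # linear interpolation between order stats
    h <- (length(v) - 1) * p + 1
    srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  }
  oracle <- tb2$cell_id[v < q7(0.01) | v > q7(0.99)]
  expect_setequal(out2$cell_id[out2$status == "dropped_outlier"], oracle)
})

test_that("per-sample pruning computes cutoffs within each sample", {
  tb <- tibble::tibble(sample_id = rep(c("a", "b"), each = 101),
                       cell_id = rep(1:101, 2), x = 0, y = 0, area = 1,
                       CD4 = c(0:100, 1000 + 0:100), status = "retained")
  out <- prune_percentile_outliers(tb, "CD4", p_lo = 5, p_hi = 95,
                                   per_sample = TRUE)
  drops <- table(out$sample_id[out$status == "dropped_outlier"])
  expect_equal(as.integer(drops), c(10, 10))
})
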