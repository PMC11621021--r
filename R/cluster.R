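# Post-QC phenotyping and review: Horn's parallel analysis for choosing the
# number of principal components, random subsampling, 2-D embedding
# (UMAP/t-SNE), HDBSCAN clustering of the embedding, silhouette scoring,
# cluster expression profiles with row-wise normalisation and agglomerative
# meta-clusters, per-condition cluster-frequency statistics, reference-image
# contrast limits and thumbnail galleries.

#' Horn's parallel analysis
#'
#' Counts eigenvalues of the observed correlation matrix that exceed the
#' 95th percentile of eigenvalues obtained from column-permuted copies of
#' the data, then clamps the count to the 2--3 components that a 2-D/3-D
#' embedding can use.
#'
#' @param data Matrix or data frame of intensity channels (cells x channels);
#'   non-numeric columns are ignored, constant columns dropped with a warning.
#' @param n_iter Number of permuted datasets (>= 100).
#' @param seed Seed for the permutations.
#' @param quantile Null percentile (default 0.95).
#' @return A `"horns_pa"` list: `n_components` (2 or 3), `raw_count`,
#'   `eigenvalues` and `null_quantiles`.
#' @export
horns_parallel <- function(data, n_iter = 200, seed = 1, quantile = 0.95) {
  if (is.data.frame(data)) data <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  if (n_iter < 100) abort("n_iter must be at least 100")
  const <- apply(data, 2, function(v) var(v) <= .Machine$double.eps)
  if (any(const)) {
    warn(paste0("dropping constant channel(s): ",
                paste(colnames(data)[const], collapse = ", ")))
    data <- data[, !const, drop = FALSE]
  }
  if (ncol(data) < 3) abort("need at least 3 non-constant channels")
  obs <- eigen(cor(data), symmetric = TRUE, only.values = TRUE)$values
  null <- .with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      perm <- apply(data, 2, sample)
      eigen(cor(perm), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(ncol(data)))
  })
  qs <- apply(null, 1, .quantile7, p = quantile)
  raw <- sum(obs > qs)
  structure(list(n_components = as.integer(.clamp(raw, 2, 3)),
                 raw_count = as.integer(raw), eigenvalues = obs,
                 null_quantiles = qs, n_iter = n_iter, seed = seed),
            class = "horns_pa")
}

#' @export
print.horns_pa <- function(x, ...) {
  cat(sprintf("<horns_pa> %d components above the permutation null (using %d)\n",
              x$raw_count, x$n_components))
  invisible(x)
}

#' Random subsample of cells
#'
#' Uniform sampling without replacement, seeded; the identity when `n_max`
#' is at least the number of rows. Used to keep embedding time tractable on
#' very large aggregated tables.
#'
#' @param table Spatial feature table (any tibble).
#' @param n_max Maximum rows to keep.
#' @param seed Sampling seed.
#' @return The subsampled tibble (original row order preserved).
#' @export
subsample_cells <- function(table, n_max, seed = 1) {
  stopifnot(n_max > 0)
  if (nrow(table) <= n_max) return(table)
  idx <- .with_seed(seed, sort(sample.int(nrow(table), n_max)))
  table[idx, ]
}

#' Embed cells in two dimensions
#'
#' @param table Spatial feature table (>= 10 cells), channels already
#'   log-transformed.
#' @param channels Channels to embed on; defaults to all non-DNA channels.
#' @param method `"umap"` or `"tsne"`.
#' @param n_neighbors UMAP neighbourhood size.
#' @param perplexity t-SNE perplexity.
#' @param pca Optional number of principal components to pre-reduce to
#'   (e.g. from [horns_parallel()]).
#' @param seed Seed; embeddings are reproducible for a fixed seed.
#' @return The table with `embed_1`, `embed_2` columns appended.
#' @export
embed_cells <- function(table, channels = NULL, method = c("umap", "tsne"),
                        n_neighbors = 15, perplexity = 30, pca = NULL,
                        seed = 1) {
  method <- match.arg(method)
  if (nrow(table) < 10) abort("need at least 10 cells to embed")
  channels <- channels %||% intensity_channels(table, markers_only = TRUE)
  x <- as.matrix(table[channels])
  if (!is.null(pca)) {
    x <- prcomp(x, center = TRUE, scale. = TRUE)$x[, seq_len(pca), drop = FALSE]
  }
  emb <- .with_seed(seed, {
    if (method == "umap") {
      uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1),
                 n_components = 2, n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE)
    } else {
      if (!requireNamespace("Rtsne", quietly = TRUE)) {
        abort("t-SNE embedding requires the Rtsne package")
      }
      Rtsne::Rtsne(x, dims = 2, check_duplicates = FALSE,
                   perplexity = min(perplexity, (nrow(x) - 1) / 3.5),
                   verbose = FALSE, num_threads = 1)$Y
    }
  })
  table$embed_1 <- emb[, 1]
  table$embed_2 <- emb[, 2]
  attr(table, "embed_params") <- list(method = method, channels = channels,
                                      n_neighbors = n_neighbors,
                                      perplexity = perplexity,
                                      pca = pca, seed = seed)
  table
}

#' Silhouette scores for clustered cells
#'
#' Standard silhouette on the clustered cells only (label `-1` is excluded
#' and scores `NA`). Negative scores flag likely misassignment.
#'
#' @param x Matrix/data frame of coordinates (embedding by default) with one
#'   row per cell.
#' @param labels Integer cluster labels (`-1` = unclustered).
#' @return Numeric vector of per-cell scores in `[-1, 1]`, `NA` for
#'   unclustered cells.
#' @export
silhouette_scores <- function(x, labels) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  keep <- labels != -1L
  if (length(unique(labels[keep])) < 2) {
    abort("silhouette undefined: fewer than 2 clusters")
  }
  sil <- cluster::silhouette(labels[keep], dist(x[keep, , drop = FALSE]))
  out <- rep(NA_real_, length(labels))
  out[keep] <- sil[, "sil_width"]
  out
}

#' Embed, cluster and score cells in one step
#'
#' Convenience wrapper: [embed_cells()] then [hdbscan_cluster()] on the
#' embedding (density clustering in the embedded space, matching the way
#' clusters are reviewed on the embedding) and [silhouette_scores()].
#'
#' @inheritParams embed_cells
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @param cluster_on `"embedding"` (default) or `"channels"`.
#' @param silhouette Compute silhouette scores (skipped automatically when
#'   fewer than 2 clusters are found).
#' @return A `"cell_clusters"` object: `cells` tibble (keys, embedding,
#'   `cluster`, `silhouette`), the `hdbscan_fit`, and all parameters.
#' @export
cluster_cells <- function(table, channels = NULL, method = "umap",
                          n_neighbors = 15, perplexity = 30, pca = NULL,
                          min_cluster_size = 25, cluster_on = c("embedding", "channels"),
                          silhouette = TRUE, seed = 1) {
  cluster_on <- match.arg(cluster_on)
  channels <- channels %||% intensity_channels(table, markers_only = TRUE)
  x <- as.matrix(table[channels])
  if (nrow(unique(x)) == 1) {
    # a pool of identical cells is one degenerate cluster, not noise
    table$embed_1 <- 0; table$embed_2 <- 0
    table$cluster <- 0L
    table$silhouette <- NA_real_
    fit <- structure(list(labels = rep(0L, nrow(table)), n_clusters = 1L,
                          cluster_stability = numeric(0),
                          min_cluster_size = min_cluster_size,
                          min_samples = min_cluster_size),
                     class = "hdbscan_fit")
    return(structure(list(cells = table, fit = fit,
                          params = list(min_cluster_size = min_cluster_size,
                                        cluster_on = cluster_on)),
                     class = "cell_clusters"))
  }
  emb <- embed_cells(table, channels, method = method,
                     n_neighbors = n_neighbors, perplexity = perplexity,
                     pca = pca, seed = seed)
  feat <- if (cluster_on == "embedding") emb[c("embed_1", "embed_2")]
          else emb[channels]
  fit <- hdbscan_cluster(feat, min_cluster_size = min_cluster_size)
  emb$cluster <- fit$labels
  emb$silhouette <- if (silhouette && fit$n_clusters >= 2) {
    silhouette_scores(emb[c("embed_1", "embed_2")], fit$labels)
  } else NA_real_
  structure(list(cells = emb, fit = fit,
                 params = c(attr(emb, "embed_params"),
                            list(min_cluster_size = min_cluster_size,
                                 cluster_on = cluster_on))),
            class = "cell_clusters")
}

#' @export
print.cell_clusters <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
tidy.cell_clusters <- function(x, ...) {
  cols <- intersect(c("sample_id", "cell_id", "embed_1", "embed_2",
                      "cluster", "silhouette"), names(x$cells))
  x$cells[cols]
}

#' @export
glance.cell_clusters <- function(x, ...) {
  g <- glance(x$fit)
  g$mean_silhouette <- mean(x$cells$silhouette, na.rm = TRUE)
  g$method <- x$params$method
  g
}

#' Cluster expression profiles
#'
#' Mean intensity per marker per cluster (unclustered cells excluded), a
#' row-wise min--max normalisation across clusters in `[0, 1]` (a constant
#' row maps to all zeros), and a row-wise z-score variant (population sd).
#'
#' @param table Spatial feature table carrying a `cluster` column, or a
#'   `"cell_clusters"` object plus the original table via `data`.
#' @param channels Channels to profile; defaults to non-DNA channels.
#' @param cluster Name of the cluster-label column.
#' @return A `"cluster_profile"`: `mean_intensity`, `normalized`, `zscore`
#'   (marker x cluster matrices) and `n_cells` per cluster.
#' @export
cluster_profile <- function(table, channels = NULL, cluster = "cluster") {
  if (inherits(table, "cell_clusters")) table <- table$cells
  if (!cluster %in% names(table)) abort("no cluster column; cluster first")
  channels <- channels %||% intensity_channels(table, markers_only = TRUE)
  keep <- table[[cluster]] != -1L
  labs <- table[[cluster]][keep]
  x <- as.matrix(table[keep, channels])
  cl <- sort(unique(labs))
  mean_i <- vapply(cl, function(k) colMeans(x[labs == k, , drop = FALSE]),
                   numeric(length(channels)))
  mean_i <- matrix(mean_i, nrow = length(channels),
                   dimnames = list(channels, cl))
  rng <- apply(mean_i, 1, function(r) diff(range(r)))
  norm <- (mean_i - apply(mean_i, 1, min)) /
    ifelse(rng > 0, rng, 1)
  norm[rng == 0, ] <- 0
  mu <- rowMeans(mean_i)
  sdp <- apply(mean_i, 1, function(r) sqrt(mean((r - mean(r))^2)))
  z <- (mean_i - mu) / ifelse(sdp > 0, sdp, 1)
  z[sdp == 0, ] <- 0
  structure(list(mean_intensity = mean_i, normalized = norm, zscore = z,
                 n_cells = table(labs)),
            class = "cluster_profile")
}

#' @export
tidy.cluster_profile <- function(x, ...) {
  long <- function(m, name) {
    t <- tibble::as_tibble(m, rownames = "marker")
    t <- tidyr::pivot_longer(t, -"marker", names_to = "cluster",
                             values_to = name)
    t$cluster <- as.integer(t$cluster)
    t
  }
  out <- long(x$mean_intensity, "mean_intensity")
  out$normalized <- long(x$normalized, "normalized")$normalized
  out$zscore <- long(x$zscore, "zscore")$zscore
  out
}

#' Agglomerative meta-clusters of cluster profiles
#'
#' Average-linkage Euclidean agglomeration of the cluster mean-intensity
#' vectors, cut at `k` groups or height `h`. Meta-clusters group phenotype
#' clusters into broader lineages (e.g. tumor/stromal/immune compartments).
#'
#' @param profile A `"cluster_profile"`.
#' @param k Number of meta-clusters (or `h`, a cut height; exactly one).
#' @param h Cut height.
#' @return Tibble `cluster`, `meta_cluster` plus attributes `hclust` and
#'   `order` (dendrogram order, for heatmap layout).
#' @export
meta_cluster <- function(profile, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) abort("supply exactly one of k or h")
  prof <- t(profile$mean_intensity)   # clusters as rows
  hc <- hclust(dist(prof, method = "euclidean"), method = "average")
  cut <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  out <- tibble::tibble(cluster = as.integer(rownames(prof)),
                        meta_cluster = LETTERS[cut])
  attr(out, "hclust") <- hc
  attr(out, "order") <- as.integer(rownames(prof))[hc$order]
  out
}

#' Cluster-frequency statistics between two conditions
#'
#' Per cluster, each sample's frequency (cluster cells / total sample cells)
#' is logit-transformed (with a small pseudo-count so empty clusters stay
#' finite) and compared between the two conditions with a two-sided Welch
#' t-test; p-values are Benjamini--Hochberg adjusted across clusters.
#'
#' @param table Table carrying `sample_id` and a `cluster` column.
#' @param sample_metadata Tibble with `sample_id` and `condition` (exactly 2
#'   levels, each with >= 2 samples).
#' @param cluster Cluster-label column name.
#' @param eps Pseudo-count on the frequency scale.
#' @return Tibble per cluster: per-condition mean frequencies, `log2_ratio`,
#'   `statistic`, `p_value`, `q_value`.
#' @export
frequency_stats <- function(table, sample_metadata, cluster = "cluster",
                            eps = 1e-6) {
  if (inherits(table, "cell_clusters")) table <- table$cells
  if (!cluster %in% names(table)) abort("no cluster column; cluster first")
  md <- sample_metadata
  lev <- unique(md$condition)
  if (length(lev) != 2) abort("need exactly 2 conditions")
  counts <- table(md$condition[match(unique(table$sample_id), md$sample_id)])
  if (any(counts < 2)) abort("need at least 2 samples per condition")
  logit <- function(p) log(.clamp(p + eps, eps, 1 - eps) /
                           (1 - .clamp(p + eps, eps, 1 - eps)))
  totals <- table(table$sample_id)
  clusters <- sort(setdiff(unique(table[[cluster]]), -1L))
  rows <- lapply(clusters, function(k) {
    in_k <- table(factor(table$sample_id[table[[cluster]] == k],
                         levels = names(totals)))
    f <- as.numeric(in_k) / as.numeric(totals)
    cond <- md$condition[match(names(totals), md$sample_id)]
    a <- f[cond == lev[1]]; b <- f[cond == lev[2]]
    tt <- t.test(logit(a), logit(b), var.equal = FALSE)
    tibble::tibble(cluster = k,
                   mean_freq_1 = mean(a), mean_freq_2 = mean(b),
                   log2_ratio = log2((mean(a) + eps) / (mean(b) + eps)),
                   statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  names(out)[names(out) == "mean_freq_1"] <- paste0("mean_freq_", lev[1])
  names(out)[names(out) == "mean_freq_2"] <- paste0("mean_freq_", lev[2])
  out
}

#' Per-channel contrast limits from a reference image
#'
#' Percentile limits computed once on a reference specimen and applied
#' unchanged to every specimen's galleries, so thumbnails are comparable
#' across a batch.
#'
#' @param reference_image A [multiplex_image].
#' @param percentiles Lower/upper percentiles in `[0, 100]`.
#' @return Tibble `channel`, `lower`, `upper`, `constant` (flagged when the
#'   channel has no dynamic range).
#' @export
set_contrast <- function(reference_image, percentiles = c(0.1, 99.9)) {
  chs <- reference_image$channels
  rows <- lapply(chs, function(ch) {
    v <- as.numeric(.channel(reference_image, ch))
    q <- .quantile7(v, percentiles / 100)
    tibble::tibble(channel = ch, lower = q[1], upper = q[2],
                   constant = q[1] == q[2])
  })
  dplyr::bind_rows(rows)
}

#' Thumbnail galleries of randomly drawn cluster cells
#'
#' Draws `n_per_cluster` seeded random cells per cluster and cuts a square
#' window (20 x 20 um; 30 x 30 px at 0.65 um/px) centred on each reference
#' nucleus, zero-padded at image borders. The three most highly expressed
#' markers of the cluster (largest entries of its normalised profile column)
#' are composited as green/red/blue under the given contrast limits, with
#' segmentation boundaries overlaid and a single white centre pixel marking
#' the reference cell.
#'
#' @param image A [multiplex_image] for the sample.
#' @param mask Integer label mask (used only to locate boundary overlay when
#'   `boundary` is `NULL`).
#' @param table Feature table of this sample carrying a `cluster` column.
#' @param n_per_cluster Cells per cluster (clusters smaller than this
#'   contribute all their cells, noted in the result).
#' @param contrast Contrast-limit tibble from [set_contrast()]; computed
#'   from `image` when `NULL`.
#' @param profile Optional `"cluster_profile"` (computed from `table` when
#'   `NULL`).
#' @param boundary Optional logical boundary matrix.
#' @param seed Sampling seed.
#' @return A `"thumbnail_gallery"` tibble: `cluster`, `cell_id`, `x`, `y`,
#'   `markers` (list of 3 names), `patch` (list of window x window x 3 RGB
#'   arrays in `[0, 1]`).
#' @export
curate_thumbnails <- function(image, mask, table, n_per_cluster = 10,
                              contrast = NULL, profile = NULL,
                              boundary = NULL, seed = 1) {
  if (!"cluster" %in% names(table)) abort("no cluster column; cluster first")
  w <- 2L * as.integer(round(10 / image$pixel_size))
  contrast <- contrast %||% set_contrast(image)
  profile <- profile %||% cluster_profile(table)
  if (is.null(boundary)) boundary <- .mask_boundary(mask)
  H <- nrow(mask); W <- ncol(mask)
  clusters <- sort(setdiff(unique(table$cluster), -1L))
  picks <- .with_seed(seed, {
    lapply(clusters, function(k) {
      idx <- which(table$cluster == k)
      if (length(idx) <= n_per_cluster) idx
      else sample(idx, n_per_cluster)
    })
  })
  scale01 <- function(m, ch) {
    lim <- contrast[contrast$channel == ch, ]
    if (lim$constant) return(m * 0)
    .clamp((m - lim$lower) / (lim$upper - lim$lower), 0, 1)
  }
  rows <- list()
  half <- w %/% 2L
  for (ki in seq_along(clusters)) {
    k <- clusters[ki]
    col <- profile$normalized[, as.character(k)]
    top3 <- names(sort(col, decreasing = TRUE))[1:3]
    chans <- lapply(top3, function(ch) scale01(.channel(image, ch), ch))
    for (i in picks[[ki]]) {
      rc <- round(table$y[i]) + 1L
      cc <- round(table$x[i]) + 1L
      rr <- (rc - half + 1L):(rc + half)
      ccx <- (cc - half + 1L):(cc + half)
      ok_r <- rr >= 1 & rr <= H; ok_c <- ccx >= 1 & ccx <= W
      patch <- array(0, c(w, w, 3))
      for (b in 1:3) {
        pm <- matrix(0, w, w)
        pm[ok_r, ok_c] <- chans[[b]][rr[ok_r], ccx[ok_c]]
        bm <- matrix(FALSE, w, w)
        bm[ok_r, ok_c] <- boundary[rr[ok_r], ccx[ok_c]]
        pm[bm] <- pmax(pm[bm], 0.6)          # translucent outline overlay
        patch[, , b] <- pm
      }
      patch[half, half, ] <- 1               # white centre pixel
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = k, cell_id = table$cell_id[i],
        x = table$x[i], y = table$y[i],
        markers = list(top3), patch = list(patch),
        undersized = length(picks[[ki]]) < n_per_cluster)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("thumbnail_gallery", class(out))
  attr(out, "window") <- w
  out
}
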