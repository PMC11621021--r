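# metaQC: an unsupervised audit of the redaction. Human-guided (and
# automated) artifact flagging makes mistakes in both directions; clustering
# a balanced pool of redacted and retained cells exposes them. A cluster
# dominated by retained cells vouches for its redacted members (they are
# reinstated); a cluster dominated by redacted cells indicts its retained
# members (they are dropped). Clusters near parity take no action.

#' Build a balanced redacted/retained pool
#'
#' Samples `min(k_cap, N_redacted, N_retained)` cells uniformly without
#' replacement from each class, seeded.
#'
#' @param table Gated spatial feature table.
#' @param k_cap Maximum pool size per class.
#' @param seed Sampling seed.
#' @return The pooled rows with an `.origin` column (`"redacted"` /
#'   `"retained"`), or `NULL` (with a warning) if either class is empty.
#' @export
build_pool <- function(table, k_cap = 1e5, seed = 1) {
  .assert_table(table)
  kept <- .retained_idx(table)
  n_ret <- sum(kept); n_red <- sum(!kept)
  if (n_ret == 0 || n_red == 0) {
    warn("metaQC skipped: need both redacted and retained cells")
    return(NULL)
  }
  k <- min(k_cap, n_red, n_ret)
  idx <- .with_seed(seed, {
    c(sample(which(!kept), k), sample(which(kept), k))
  })
  pool <- table[sort(idx), ]
  pool$.origin <- ifelse(.retained_idx(pool), "retained", "redacted")
  pool
}

#' Cluster a metaQC pool
#'
#' Embeds the pool (UMAP on log10 marker intensities by default) and
#' clusters the embedding with HDBSCAN, as in the phenotyping module.
#'
#' @param pool Pool tibble from [build_pool()].
#' @param channels Channels to use; defaults to non-DNA channels.
#' @param log10_transform Log10-transform channels first (set `FALSE` when
#'   the table is already on the log scale).
#' @param min_cluster_size,n_neighbors,seed Clustering parameters.
#' @return The pool with a `.cluster` column (`-1` = unclustered).
#' @export
cluster_pool <- function(pool, channels = NULL, log10_transform = TRUE,
                         min_cluster_size = 25, n_neighbors = 15, seed = 1) {
  channels <- channels %||% intensity_channels(pool, markers_only = TRUE)
  work <- pool
  if (log10_transform) work <- log_transform(work, channels)
  cl <- cluster_cells(work, channels = channels,
                      min_cluster_size = min_cluster_size,
                      n_neighbors = n_neighbors, silhouette = FALSE,
                      seed = seed)
  if (cl$fit$n_clusters == 0) {
    warn("metaQC aborted: no cell clustered")
    return(NULL)
  }
  pool$.cluster <- cl$cells$cluster
  pool
}

#' Reclassify cells from pool clusters
#'
#' For each cluster, `f` is the fraction of members that are retained. When
#' `f >= threshold` the cluster is predominantly clean: its redacted members
#' are reinstated. When `f <= 1 - threshold` it is predominantly noisy: its
#' retained members are dropped (`dropped_metaqc`). In between (the dead
#' zone) and for unclustered cells, nothing happens.
#'
#' @param table Gated table the pool was built from.
#' @param pool Clustered pool ([cluster_pool()]).
#' @param threshold Majority threshold `t` in `(0.5, 1]` (default 0.75).
#' @return The reclassified table with log entries appended; the sets of
#'   reinstated / newly dropped cell ids are attached as attributes
#'   `"reinstated"` and `"newly_dropped"`.
#' @export
reclassify <- function(table, pool, threshold = 0.75) {
  stopifnot(threshold > 0.5, threshold <= 1)
  .assert_table(table)
  key <- paste(table$sample_id, table$cell_id)
  reinstated <- character(0)
  dropped <- character(0)
  f_of <- numeric(0)
  for (k in sort(setdiff(unique(pool$.cluster), -1L))) {
    members <- pool[pool$.cluster == k, ]
    f <- mean(members$.origin == "retained")
    mk <- paste(members$sample_id, members$cell_id)
    if (f >= threshold) {
      picked <- mk[members$.origin == "redacted"]
      reinstated <- c(reinstated, picked)
      f_of <- c(f_of, rep(f, length(picked)))
    } else if (f <= 1 - threshold) {
      picked <- mk[members$.origin == "retained"]
      dropped <- c(dropped, picked)
      f_of <- c(f_of, rep(f, length(picked)))
    }
  }
  before <- table$status
  table$status[key %in% reinstated] <- "reinstated"
  table$status[key %in% dropped] <- "dropped_metaqc"
  table <- .log_status_change(table, before, "metaqc",
                              list(threshold = threshold,
                                   n_reinstated = length(reinstated),
                                   n_dropped = length(dropped)))
  attr(table, "reinstated") <- table$cell_id[key %in% reinstated]
  attr(table, "newly_dropped") <- table$cell_id[key %in% dropped]
  table
}

#' Run the full metaQC audit
#'
#' [build_pool()], [cluster_pool()] and [reclassify()] in sequence. The
#' audit runs once (no iteration to a fixed point) unless `iterate = TRUE`,
#' in which case it repeats until no cell changes status (or `max_iter`).
#'
#' @inheritParams build_pool
#' @inheritParams cluster_pool
#' @inheritParams reclassify
#' @param iterate Repeat to a fixed point.
#' @param max_iter Iteration cap when `iterate = TRUE`.
#' @return The audited table (unchanged if a class was empty).
#' @export
metaqc_audit <- function(table, channels = NULL, k_cap = 1e5,
                         threshold = 0.75, min_cluster_size = 25,
                         n_neighbors = 15, log10_transform = TRUE,
                         iterate = FALSE, max_iter = 5, seed = 1) {
  for (i in seq_len(if (iterate) max_iter else 1)) {
    pool <- build_pool(table, k_cap = k_cap, seed = seed + i - 1)
    if (is.null(pool)) return(table)
    pool <- cluster_pool(pool, channels = channels,
                         log10_transform = log10_transform,
                         min_cluster_size = min_cluster_size,
                         n_neighbors = n_neighbors, seed = seed + i - 1)
    if (is.null(pool)) return(table)
    before <- table$status
    table <- reclassify(table, pool, threshold = threshold)
    if (identical(table$status, before)) break
  }
  table
}
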