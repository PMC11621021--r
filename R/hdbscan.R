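# Hierarchical density-based clustering (HDBSCAN). Implemented from the
# standard construction: (1) core distances from k-nearest neighbours,
# (2) mutual-reachability distances, (3) the single-linkage dendrogram of
# the mutual-reachability graph (equivalent to its minimum spanning tree),
# (4) a condensed tree in which splits smaller than min_cluster_size "fall
# out" as noise, and (5) excess-of-mass cluster selection by stability
# (the root is never selected, so a structureless dataset yields no
# clusters). Suited to the embedding sizes this package clusters (up to a
# few thousand cells); distances are computed densely.

#' HDBSCAN clustering
#'
#' @param x Numeric matrix or data frame of observations (rows) to cluster;
#'   a tibble's numeric columns are used.
#' @param min_cluster_size Smallest group of points treated as a cluster.
#' @param min_samples Neighbourhood size for core distances (density
#'   smoothing); defaults to `min_cluster_size`.
#' @return An object of class `"hdbscan_fit"`: `labels` (integer, clusters
#'   contiguous from 0 in decreasing size order, `-1` = unclustered noise),
#'   `n_clusters`, and `cluster_stability`.
#' @export
hdbscan_cluster <- function(x, min_cluster_size = 25,
                            min_samples = min_cluster_size) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  n <- nrow(x)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  min_samples <- max(2L, min(as.integer(min_samples), n))
  out <- structure(list(labels = rep(-1L, n), n_clusters = 0L,
                        cluster_stability = numeric(0),
                        min_cluster_size = min_cluster_size,
                        min_samples = min_samples),
                   class = "hdbscan_fit")
  if (n < min_cluster_size || n < 3) return(out)

  d <- as.matrix(dist(x))
  if (max(d) == 0) {                 # degenerate: one point repeated n times
    out$labels <- rep(0L, n)
    out$n_clusters <- 1L
    return(out)
  }
  # core distance: distance to the min_samples-th nearest point, self included
  core <- apply(d, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mr <- pmax(d, outer(core, core, pmax))
  hc <- hclust(as.dist(mr), method = "single")

  res <- .condense_tree(hc$merge, hc$height, n, min_cluster_size)
  if (res$n_condensed == 0) return(out)
  sel <- .select_clusters(res)
  if (length(sel) == 0) return(out)

  # label each point by the nearest selected ancestor of the cluster it
  # fell out of; no selected ancestor => noise
  lab <- rep(-1L, n)
  for (p in seq_len(n)) {
    c <- res$fall_cluster[p]
    while (c > 0) {
      if (c %in% sel) { lab[p] <- c; break }
      c <- res$parent[c]
    }
  }
  keep <- sort(unique(lab[lab > 0]))
  sizes <- vapply(keep, function(k) sum(lab == k), integer(1))
  keep <- keep[order(-sizes)]
  relab <- rep(-1L, n)
  for (i in seq_along(keep)) relab[lab == keep[i]] <- i - 1L
  out$labels <- relab
  out$n_clusters <- length(keep)
  out$cluster_stability <- res$stability[keep]
  out
}

# Build the condensed tree by walking the dendrogram from the root.
# Returns parent links, birth lambdas and stabilities of condensed clusters
# (cluster 1 is the root), and for each point the condensed cluster it fell
# out of (as noise) and at which lambda.
.condense_tree <- function(merge, height, n, mcs) {
  n_nodes <- n - 1L
  size <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    l <- merge[i, 1]; r <- merge[i, 2]
    size[i] <- (if (l < 0) 1L else size[l]) + (if (r < 0) 1L else size[r])
  }
  node_size <- function(v) ifelse(v < 0, 1L, size[pmax(v, 1)])
  leaves_under <- function(v) {
    # iterative leaf collection for a dendrogram node reference
    if (v < 0) return(-v)
    acc <- integer(0); stack <- v
    while (length(stack) > 0) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in merge[nd, ]) {
        if (ch < 0) acc <- c(acc, -ch) else stack <- c(stack, ch)
      }
    }
    acc
  }

  parent <- 0L; birth <- 0; stability <- 0; has_children <- FALSE
  n_cl <- 1L   # cluster 1 = root
  fall_cluster <- integer(n); fall_lambda <- numeric(n)

  stack_node <- n_nodes; stack_cl <- 1L
  while (length(stack_node) > 0) {
    i <- length(stack_node)
    nd <- stack_node[i]; cl <- stack_cl[i]
    stack_node <- stack_node[-i]; stack_cl <- stack_cl[-i]
    lam <- 1 / max(height[nd], .Machine$double.eps)
    l <- merge[nd, 1]; r <- merge[nd, 2]
    sl <- node_size(l); sr <- node_size(r)
    bigl <- sl >= mcs; bigr <- sr >= mcs

    if (bigl && bigr) {
      stability[cl] <- stability[cl] + (sl + sr) * (lam - birth[cl])
      has_children[cl] <- TRUE
      for (ch in list(l, r)) {
        n_cl <- n_cl + 1L
        parent[n_cl] <- cl; birth[n_cl] <- lam
        stability[n_cl] <- 0; has_children[n_cl] <- FALSE
        stack_node <- c(stack_node, ch); stack_cl <- c(stack_cl, n_cl)
      }
    } else if (bigl || bigr) {
      small <- if (bigl) r else l
      big <- if (bigl) l else r
      s_small <- node_size(small)
      stability[cl] <- stability[cl] + s_small * (lam - birth[cl])
      pts <- leaves_under(small)
      fall_cluster[pts] <- cl; fall_lambda[pts] <- lam
      if (big < 0) {
        fall_cluster[-big] <- cl; fall_lambda[-big] <- lam
        stability[cl] <- stability[cl] + (lam - birth[cl])
      } else {
        stack_node <- c(stack_node, big); stack_cl <- c(stack_cl, cl)
      }
    } else {
      # cluster death: both remnants are below min_cluster_size
      stability[cl] <- stability[cl] + (sl + sr) * (lam - birth[cl])
      pts <- c(leaves_under(l), leaves_under(r))
      fall_cluster[pts] <- cl; fall_lambda[pts] <- lam
    }
  }
  list(parent = parent, birth = birth, stability = stability,
       has_children = has_children, fall_cluster = fall_cluster,
       fall_lambda = fall_lambda, n_condensed = n_cl - 1L)
}

# Excess-of-mass selection: a cluster is chosen when its own stability
# exceeds the summed selected value of its children; the root is excluded.
.select_clusters <- function(res) {
  n_cl <- length(res$parent)
  if (n_cl < 2) return(integer(0))
  children <- split(2:n_cl, res$parent[2:n_cl])
  value <- res$stability
  chosen <- rep(FALSE, n_cl)
  for (c in n_cl:2) {
    ch <- children[[as.character(c)]]
    if (is.null(ch)) {
      chosen[c] <- TRUE
    } else {
      childsum <- sum(value[ch])
      if (res$stability[c] >= childsum) {
        chosen[c] <- TRUE
      } else {
        value[c] <- childsum
      }
    }
  }
  # top-down: stop descending at the first chosen cluster on each path
  sel <- integer(0)
  stack <- children[["1"]] %||% integer(0)
  while (length(stack) > 0) {
    c <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (chosen[c]) sel <- c(sel, c)
    else stack <- c(stack, children[[as.character(c)]] %||% integer(0))
  }
  sel
}

#' @export
print.hdbscan_fit <- function(x, ...) {
  cat(sprintf("<hdbscan_fit> %d clusters over %d points (%.1f%% unclustered)\n",
              x$n_clusters, length(x$labels),
              100 * mean(x$labels == -1L)))
  invisible(x)
}

#' @export
glance.hdbscan_fit <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 n_cells = length(x$labels),
                 frac_unclustered = mean(x$labels == -1L),
                 min_cluster_size = x$min_cluster_size)
}
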