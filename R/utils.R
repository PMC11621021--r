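# Shared helpers: status vocabulary, feature-table column conventions,
# seeded RNG wrappers and small assertions used across modules.

#' QC status vocabulary
#'
#' Every cell in a spatial feature table carries exactly one status at any
#' time. `"retained"` means the cell has survived all stages run so far;
#' `"reinstated"` means it was dropped by an earlier stage and added back by
#' the metaQC audit. All other values name the stage that removed the cell.
#'
#' @return Character vector of the eight recognised status values.
#' @export
qc_statuses <- function() {
  c("retained", "dropped_roi", "dropped_dna_intensity", "dropped_area",
    "dropped_unstable", "dropped_outlier", "reinstated", "dropped_metaqc")
}

# Columns of a spatial feature table that are not marker intensities.
.reserved_cols <- c("sample_id", "cell_id", "x", "y", "area", "status",
                    "cycle_ratio", "cluster", "silhouette",
                    "embed_1", "embed_2")

#' Intensity channel columns of a spatial feature table
#'
#' @param table A spatial feature table (tibble).
#' @param dna_channels Optional character vector of DNA (nuclear stain)
#'   channel names to exclude when `markers_only = TRUE`.
#' @param markers_only If `TRUE`, DNA channels are excluded.
#' @return Character vector of channel column names, in table order.
#' @export
intensity_channels <- function(table, dna_channels = NULL, markers_only = FALSE) {
  ch <- setdiff(names(table), .reserved_cols)
  ch <- ch[!startsWith(ch, ".")]
  if (markers_only) {
    dna <- dna_channels %||% grep("^DNA", ch, value = TRUE)
    ch <- setdiff(ch, dna)
  }
  ch
}

# cells still in play for a gate (gates never touch already-dropped cells)
.retained_idx <- function(table) {
  table$status %in% c("retained", "reinstated")
}

.assert_table <- function(table) {
  miss <- setdiff(c("sample_id", "cell_id", "area", "status"), names(table))
  if (length(miss) > 0) {
    abort(paste0("not a spatial feature table; missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(table)
}

# run `code` under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# linear-interpolation quantile (type 7), the package-wide definition
.quantile7 <- function(x, p) {
  unname(quantile(x, probs = p, type = 7, names = FALSE, na.rm = FALSE))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# block-mean downsample of a matrix by an integer factor per axis;
# edge blocks (when factor does not divide the dimension) are averaged
# over the pixels actually present (edge-inclusive pooling).
.block_mean <- function(m, factor) {
  if (factor == 1) return(m)
  rg <- (seq_len(nrow(m)) - 1L) %/% factor
  cg <- (seq_len(ncol(m)) - 1L) %/% factor
  s <- rowsum(m, rg, reorder = TRUE)
  s <- t(rowsum(t(s), cg, reorder = TRUE))
  n <- tabulate(rg + 1L) %o% tabulate(cg + 1L)
  s / n
}

# upscale a (logical or numeric) matrix by block replication, cropped to
# the requested full-resolution dimensions.
.block_upscale <- function(m, factor, dim_out) {
  r <- rep(seq_len(nrow(m)), each = factor)[seq_len(dim_out[1])]
  c <- rep(seq_len(ncol(m)), each = factor)[seq_len(dim_out[2])]
  m[r, c, drop = FALSE]
}

# disk-shaped structuring element with odd diameter (matrix of 0/1)
.disk_kernel <- function(diameter) {
  d <- as.integer(diameter)
  if (d %% 2L == 0L) d <- d + 1L
  if (d < 3L) d <- 3L
  r <- (d - 1) / 2
  off <- seq(-r, r)
  k <- outer(off, off, function(i, j) as.numeric(i^2 + j^2 <= r^2 + 1e-9))
  k
}
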