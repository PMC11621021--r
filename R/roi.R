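# File-driven polygonal regions of interest. ROIs replace an interactive
# lasso: they persist as JSON (vertices in full-resolution, 0-based pixel
# coordinates) so a QC run is replayable without a GUI. Negative mode drops
# cells inside the polygons; positive mode keeps only cells inside.

#' Construct an ROI set
#'
#' @param sample_id Sample the ROIs belong to.
#' @param mode `"negative"` (drop inside) or `"positive"` (keep only inside).
#' @param polygons List of vertex matrices/data frames, each with columns
#'   `x`, `y` (full-resolution pixels, 0-based) and at least 3 vertices.
#' @param channel_note Optional free-text note (e.g. the channel the artifact
#'   was seen in); metadata only.
#' @return An object of class `"roi_set"`.
#' @export
roi_set <- function(sample_id, mode = c("negative", "positive"),
                    polygons = list(), channel_note = NULL) {
  mode <- match.arg(mode)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(as.data.frame(p)[, c("x", "y")])
    if (nrow(p) < 3) abort("polygon must have at least 3 vertices")
    storage.mode(p) <- "double"
    p
  })
  structure(list(sample_id = sample_id, mode = mode, polygons = polygons,
                 channel_note = channel_note), class = "roi_set")
}

#' Read / write ROI sets as JSON
#'
#' Schema: `{"sample": ..., "mode": ..., "polygons": [[[x,y], ...], ...]}`.
#'
#' @param path JSON file path.
#' @return [read_rois()]: a list of `roi_set` objects (one per sample entry).
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$sample)) raw <- list(raw)
  lapply(raw, function(e) {
    polys <- lapply(e$polygons, function(p) {
      m <- do.call(rbind, lapply(p, unlist))
      colnames(m) <- c("x", "y")
      m
    })
    roi_set(e$sample, e$mode, polys, e$channel_note)
  })
}

#' @rdname read_rois
#' @param rois A `roi_set` or list of them.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "roi_set")) rois <- list(rois)
  out <- lapply(rois, function(r) {
    list(sample = r$sample_id, mode = r$mode,
         polygons = lapply(r$polygons, function(p) {
           lapply(seq_len(nrow(p)), function(i) c(p[i, "x"], p[i, "y"]))
         }),
         channel_note = r$channel_note)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Point-in-polygon test (even-odd rule, boundary-inclusive)
#'
#' Vectorised ray-crossing with the even-odd fill rule for non-convex
#' polygons; points lying exactly on a polygon edge or vertex count as
#' inside. This is the containment semantics used for all ROI gating.
#'
#' @param x,y Point coordinates (equal-length vectors).
#' @param poly Matrix with columns `x`, `y` (vertices, not closed).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, "x"]; py <- poly[, "y"]
  n <- length(px)
  jx <- px[c(n, seq_len(n - 1))]; jy <- py[c(n, seq_len(n - 1))]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- jx[e]; y2 <- jy[e]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # collinear and within the segment's bounding box => on the edge
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (abs(cross) < 1e-9 &
      x >= pmin(x1, x2) - 1e-9 & x <= pmax(x1, x2) + 1e-9 &
      y >= pmin(y1, y2) - 1e-9 & y <= pmax(y1, y2) + 1e-9)
  }
  inside | on_edge
}

#' Flag cells inside the ROIs of a sample
#'
#' @param table Spatial feature table.
#' @param rois An `roi_set`; only rows of the matching `sample_id` are
#'   tested (other samples get `FALSE`).
#' @return Logical vector, one flag per row of `table`: `TRUE` iff the cell
#'   centroid is inside (or on the boundary of) any polygon.
#' @export
cells_in_polygons <- function(table, rois) {
  .assert_table(table)
  flag <- rep(FALSE, nrow(table))
  sel <- table$sample_id == rois$sample_id
  for (p in rois$polygons) {
    flag[sel] <- flag[sel] | point_in_polygon(table$x[sel], table$y[sel], p)
  }
  flag
}

#' Apply an ROI set in its mode
#'
#' Negative mode drops flagged cells; positive mode drops unflagged cells of
#' that sample. Either way the dropped status is `"dropped_roi"` and only
#' currently retained cells are touched, so application is idempotent.
#'
#' @param table Spatial feature table.
#' @param rois An `roi_set`.
#' @param allow_empty Permit a positive-mode set with no polygons (which
#'   drops every cell of the sample); default `FALSE` errors instead.
#' @return The gated table with log entries appended ([qc_log()]).
#' @export
apply_roi_mode <- function(table, rois, allow_empty = FALSE) {
  .assert_table(table)
  if (rois$mode == "positive" && length(rois$polygons) == 0 && !allow_empty) {
    abort("positive ROI mode with an empty ROI set would drop every cell")
  }
  flag <- cells_in_polygons(table, rois)
  sel <- table$sample_id == rois$sample_id
  doomed <- if (rois$mode == "negative") flag & sel else !flag & sel
  before <- table$status
  table$status[doomed & .retained_idx(table)] <- "dropped_roi"
  .log_status_change(table, before, "roi",
                     list(mode = rois$mode, sample = rois$sample_id,
                          n_polygons = length(rois$polygons)))
}
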