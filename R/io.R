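# Specimen I/O. Each specimen is described by four files: a multi-channel
# image (multi-page TIFF), an integer-label segmentation mask (TIFF), a
# binary cell-boundary image (TIFF, used only for gallery overlays) and a
# spatial feature table (CSV with one row per segmented cell). Channel
# metadata (names, acquisition cycle, pixel size, DNA channels) travels in a
# YAML manifest so that runs are fully file-driven.

#' Construct a multiplex image
#'
#' @param pixels Numeric array `[row, col, channel]` of non-negative
#'   intensities (arbitrary fluorescence units).
#' @param channels Character vector of channel names, one per slice.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param cycle_of Integer vector (named by channel or positional) giving the
#'   imaging cycle in which each channel was acquired.
#' @param dna_channels Character vector of per-cycle nuclear-stain channel
#'   names, in cycle order; its first and last entries define the DNA
#'   channels used by the cross-cycle stability gate.
#' @return A `multiplex_image` object.
#' @export
multiplex_image <- function(pixels, channels, pixel_size, cycle_of, dna_channels) {
  if (length(dim(pixels)) == 2) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == length(channels))
  if (length(dna_channels) < 1) abort("dna_channels must be nonempty")
  if (!all(dna_channels %in% channels)) abort("dna_channels must name image channels")
  cycle_of <- as.integer(cycle_of)
  if (length(cycle_of) != length(channels)) abort("cycle_of must match channels")
  dimnames(pixels) <- list(NULL, NULL, channels)
  structure(
    list(pixels = pixels, channels = channels,
         pixel_size = as.numeric(pixel_size),
         cycle_of = setNames(cycle_of, channels),
         dna_channels = dna_channels),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multiplex_image> %d x %d px, %d channels, %.2f um/px\n",
              d[1], d[2], d[3], x$pixel_size))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  DNA:", paste(x$dna_channels, collapse = ", "), "\n")
  invisible(x)
}

# one channel as a matrix
.channel <- function(image, name) {
  i <- match(name, image$channels)
  if (is.na(i)) abort(paste0("channel not in image: ", name))
  image$pixels[, , i]
}

# readTIFF(as.is = TRUE) returns the stored integer sample values directly
.read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages, use.names = FALSE), c(dim(pages[[1]]), length(pages)))
}

.write_tiff_stack <- function(x, path, bits = 16L) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1L))
  maxv <- 2^bits - 1
  pages <- lapply(seq_len(dim(x)[3]), function(i) {
    m <- x[, , i]
    m[m < 0] <- 0
    m[m > maxv] <- maxv
    round(m) / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Load one specimen from its four input files
#'
#' Reconciles channel names between the image and the feature table
#' (case-sensitively, after applying the manifest's `marker_map`), and
#' validates that the mask label set equals the table's cell-id set.
#'
#' @param image_path,mask_path,table_path Paths to the multi-channel image,
#'   integer-label mask and CSV feature table.
#' @param manifest_entry Named list describing the specimen: `sample_id`,
#'   `channels`, `pixel_size`, `cycle_of`, `dna_channels`, optional
#'   `boundary` (path to the boundary image), optional `marker_map`
#'   (named character vector mapping table columns to channel names) and
#'   optional `id_col`/`x_col`/`y_col`/`area_col` (defaults `CellID`,
#'   `X_centroid`, `Y_centroid`, `Area`).
#' @return A list with elements `image` ([multiplex_image]), `mask` (integer
#'   matrix), `boundary` (logical matrix or `NULL`) and `table` (tibble),
#'   of class `"specimen"`.
#' @export
load_specimen <- function(image_path, mask_path, table_path, manifest_entry) {
  me <- manifest_entry
  for (p in c(image_path, mask_path, table_path)) {
    if (!file.exists(p)) abort(paste0("input file does not exist: ", p))
  }
  stack <- .read_tiff_stack(image_path)
  if (length(me$channels) != dim(stack)[3]) {
    abort(sprintf("image has %d pages but the manifest names %d channels",
                  dim(stack)[3], length(me$channels)))
  }
  image <- multiplex_image(stack, me$channels, me$pixel_size,
                           me$cycle_of, me$dna_channels)
  mask <- .read_tiff_stack(mask_path)[, , 1]
  storage.mode(mask) <- "integer"
  if (!all(dim(mask) == dim(stack)[1:2])) {
    abort("mask dimensions do not match image dimensions")
  }
  boundary <- NULL
  if (!is.null(me$boundary) && file.exists(me$boundary)) {
    boundary <- .read_tiff_stack(me$boundary)[, , 1] > 0
  }

  raw <- readr::read_csv(table_path, show_col_types = FALSE, progress = FALSE)
  id_col <- me$id_col %||% "CellID"
  x_col <- me$x_col %||% "X_centroid"
  y_col <- me$y_col %||% "Y_centroid"
  area_col <- me$area_col %||% "Area"
  for (cc in c(id_col, x_col, y_col, area_col)) {
    if (!cc %in% names(raw)) abort(paste0("table is missing column: ", cc))
  }
  if (!is.null(me$marker_map)) {
    mm <- me$marker_map
    hit <- names(raw) %in% names(mm)
    names(raw)[hit] <- unname(mm[names(raw)[hit]])
  }
  missing_ch <- setdiff(me$channels, names(raw))
  if (length(missing_ch) > 0) {
    abort(paste0("feature table is missing intensity column(s) for channel(s): ",
                 paste(missing_ch, collapse = ", ")))
  }
  table <- tibble::tibble(
    sample_id = as.character(me$sample_id),
    cell_id = as.integer(raw[[id_col]]),
    x = as.numeric(raw[[x_col]]),
    y = as.numeric(raw[[y_col]]),
    area = as.numeric(raw[[area_col]])
  )
  table <- dplyr::bind_cols(table, raw[me$channels])
  table$status <- "retained"

  mask_ids <- sort(unique(mask[mask > 0]))
  orphan_table <- setdiff(table$cell_id, mask_ids)
  orphan_mask <- setdiff(mask_ids, table$cell_id)
  if (length(orphan_table) > 0 || length(orphan_mask) > 0) {
    abort(paste0(
      "mask/table cell-id mismatch; ids only in table: [",
      paste(head(orphan_table, 20), collapse = ", "),
      "]; ids only in mask: [",
      paste(head(orphan_mask, 20), collapse = ", "), "]"))
  }
  structure(list(image = image, mask = mask, boundary = boundary,
                 table = table, sample_id = as.character(me$sample_id)),
            class = "specimen")
}

#' Aggregate per-specimen feature tables into one table
#'
#' @param specimens A list of `"specimen"` objects (from [load_specimen()] or
#'   [generate_phantom()]) or of feature tables that already carry
#'   `sample_id`.
#' @param panels `"strict"` (default) requires identical marker panels and
#'   errors otherwise; `"intersect"` keeps the shared channels.
#' @return One spatial feature table with canonical column order
#'   (`sample_id`, `cell_id`, `x`, `y`, `area`, channels, `status`).
#' @export
aggregate_samples <- function(specimens, panels = c("strict", "intersect")) {
  panels <- match.arg(panels)
  tables <- lapply(specimens, function(s) {
    if (inherits(s, "specimen")) s$table else s
  })
  lapply(tables, .assert_table)
  chans <- lapply(tables, intensity_channels)
  shared <- Reduce(intersect, chans)
  if (panels == "strict") {
    same <- all(vapply(chans, function(ch) identical(sort(ch), sort(chans[[1]])),
                       logical(1)))
    if (!same) {
      abort(paste0("specimens have different marker panels ",
                   "(use panels = \"intersect\" to keep the shared channels); ",
                   "shared channels: ", paste(shared, collapse = ", ")))
    }
    keep <- chans[[1]]
  } else {
    if (length(shared) == 0) abort("specimens share no marker channels")
    keep <- shared
  }
  out <- dplyr::bind_rows(lapply(tables, function(t) {
    t[, c("sample_id", "cell_id", "x", "y", "area", keep, "status")]
  }))
  if (anyDuplicated(paste(out$sample_id, out$cell_id)) > 0) {
    abort("(sample_id, cell_id) pairs are not unique after aggregation")
  }
  out
}

#' Final partition of cells over QC categories
#'
#' @param table A gated spatial feature table.
#' @return Tibble with one row per status category: count and fraction of the
#'   raw cell total. Fractions sum to 1 by construction (the status column is
#'   a partition).
#' @export
qc_partition <- function(table) {
  .assert_table(table)
  n_raw <- nrow(table)
  tab <- table(factor(table$status, levels = qc_statuses()))
  tibble::tibble(
    status = names(tab),
    n = as.integer(tab),
    fraction = as.numeric(tab) / n_raw
  )
}

#' Build the QC report
#'
#' @param table Final gated table.
#' @param log Redaction log ([qc_log()]).
#' @param files Optional named list of input-file references to record.
#' @return A nested list (serialisable to YAML): per-sample and overall
#'   counts/fractions per category, per-stage drop counts, and the parameters
#'   each stage used.
#' @export
qc_report <- function(table, log = qc_log(table), files = NULL) {
  .assert_table(table)
  part <- qc_partition(table)
  stopifnot(abs(sum(part$fraction) - 1) < 1e-12)
  by_sample <- lapply(split(table, table$sample_id), function(t) {
    p <- qc_partition(t)
    list(n_cells = nrow(t),
         counts = as.list(setNames(p$n, p$status)),
         fractions = as.list(setNames(p$fraction, p$status)))
  })
  stages <- unique(log$stage)
  stage_info <- lapply(stages, function(s) {
    e <- log[log$stage == s, ]
    list(dropped = sum(e$action == "drop"),
         reinstated = sum(e$action == "reinstate"),
         parameters = jsonlite::fromJSON(e$params[[1]]))
  })
  names(stage_info) <- stages
  list(
    n_cells_raw = nrow(table),
    overall = list(counts = as.list(setNames(part$n, part$status)),
                   fractions = as.list(setNames(part$fraction, part$status))),
    samples = by_sample,
    stages = stage_info,
    files = files
  )
}

#' Write the redacted table, QC report and redaction log
#'
#' The redacted table keeps only cells whose final status is `"retained"` or
#' `"reinstated"`. Before writing, the function asserts that replaying the
#' log over the raw table reproduces the final status column.
#'
#' @param table Final gated table (with its log attached, or pass `log`).
#' @param log Redaction log; defaults to the one attached to `table`.
#' @param out_dir Output directory (created if needed).
#' @param files Optional named list of input-file references for the report.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_outputs <- function(table, log = qc_log(table), out_dir, files = NULL) {
  .assert_table(table)
  replayed <- replay_log(table, log)
  if (!identical(replayed$status, table$status)) {
    abort("internal error: redaction log does not reproduce the status column")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  redacted <- table[table$status %in% c("retained", "reinstated"), ]
  table_file <- file.path(out_dir, "redacted_table.csv")
  readr::write_csv(redacted, table_file, progress = FALSE)
  report_file <- file.path(out_dir, "qc_report.yml")
  yaml::write_yaml(qc_report(table, log, files), report_file, precision = 12)
  log_file <- file.path(out_dir, "redaction_log.json")
  jsonlite::write_json(log, log_file, dataframe = "rows", digits = NA)
  invisible(list(table = table_file, report = report_file, log = log_file))
}

#' Write one specimen to the standard four-file layout
#'
#' Used by [make_exemplar()]; also handy for exporting phantoms for use by
#' other tools. Images are written as 16-bit multi-page TIFF, the mask as a
#' 16-bit label TIFF, the boundary image as 8-bit binary TIFF and the table
#' as CSV in the conventional quantification schema (`CellID`, `X_centroid`,
#' `Y_centroid`, `Area`, one column per channel).
#'
#' @param specimen A `"specimen"`/`"phantom"`-like list with `image`, `mask`,
#'   `boundary`, `table`.
#' @param dir Output directory.
#' @param sample_id Sample identifier used in file names.
#' @return The manifest entry (named list) describing the written files.
#' @export
write_specimen <- function(specimen, dir, sample_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- specimen$image
  paths <- list(
    image = file.path(dir, paste0(sample_id, "_image.tif")),
    mask = file.path(dir, paste0(sample_id, "_mask.tif")),
    boundary = file.path(dir, paste0(sample_id, "_boundary.tif")),
    table = file.path(dir, paste0(sample_id, "_cells.csv"))
  )
  .write_tiff_stack(img$pixels, paths$image)
  .write_tiff_stack(specimen$mask, paths$mask)
  .write_tiff_stack(specimen$boundary * 255, paths$boundary, bits = 8L)
  t <- specimen$table
  out <- tibble::tibble(CellID = t$cell_id, X_centroid = t$x,
                        Y_centroid = t$y, Area = t$area)
  out <- dplyr::bind_cols(out, t[intensity_channels(t)])
  readr::write_csv(out, paths$table, progress = FALSE)
  c(list(sample_id = sample_id, channels = img$channels,
         pixel_size = img$pixel_size, cycle_of = as.list(img$cycle_of),
         dna_channels = img$dna_channels), paths)
}
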