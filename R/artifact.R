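# Automated artifact detection with classical morphology. The detector runs
# channel by channel on a downsampled 8-bit rendering: a disk-kernel
# erosion / local-mean / dilation transform suppresses single-cell texture
# while preserving artifact-scale structure (folds, aggregates, fibers,
# aberrations); local maxima of the transformed image found with an
# expanded kernel, gated against a robust background level, seed a
# tolerance-based flood fill whose union is the binary artifact mask. Cells
# whose centroid falls inside the (block-upscaled) mask are dropped.

#' Artifact-detector configuration
#'
#' @param downsample_factor Integer per-axis downsampling before detection.
#' @param kernel_diameter Disk kernel diameter(s) in *downsampled* pixels,
#'   spanning roughly three to five cells at the working scale (each rounded
#'   up to the next odd value, minimum 3). A vector runs the transform at
#'   several scales and unions the resulting masks: a small kernel preserves
#'   compact bright artifacts (antibody aggregates), a large one erases
#'   near-confluent nuclear texture so that broad floor-level artifacts
#'   (folds, aberrations) stand out.
#' @param seed_kernel_scale Multiplier (> 1) on `kernel_diameter` for the
#'   local-maxima search neighbourhood.
#' @param tolerance Flood-fill tolerance. In `"relative"` mode (default) a
#'   pixel joins a region when within `tolerance * seed_value` of the seed
#'   value (`tolerance` in `(0, 1]`), so bright compact artifacts with steep
#'   shoulders and faint extended ones are filled on comparable footing; in
#'   `"absolute"` mode the tolerance is in 8-bit units `[0, 255]`.
#' @param tolerance_mode `"relative"` or `"absolute"`.
#' @param min_region_area Minimum connected-region area (downsampled px) to
#'   keep; defaults to the area of one kernel disk, suppressing single-pixel
#'   fills.
#' @param seed_mad_k Seeds must exceed `median + seed_mad_k * MAD` of the
#'   transformed image (robust-outlier gate against background texture).
#' @param flood_mad_k Floor of the flood fill: a fill may not descend below
#'   `median + flood_mad_k * MAD` (set lower than `seed_mad_k` so a fill can
#'   spread beyond its seed plateau but never into background texture);
#'   `NULL` disables the floor and fills on tolerance alone.
#' @param bright_seed_min 8-bit value splitting seed responsibility between
#'   scales in a multi-scale run: the smaller kernels (compact,
#'   near-saturating artifacts such as antibody aggregates) only accept
#'   seeds at or above it, while the largest kernel (extended faint
#'   floor-level artifacts such as folds) only accepts seeds below it --
#'   residual biological structure that stays bright after a cell-scale
#'   erosion is compact by construction and is left to the small-kernel
#'   pass rather than flooded at fold scale.
#' @param mask_dilate Fraction of the kernel diameter by which the final
#'   mask is dilated (positive) or eroded (negative). The transform ends in
#'   a grayscale dilation that inflates every surviving feature by about
#'   half a kernel, so the default erodes the mask by half a kernel to
#'   recover the feature's true footprint; 0 disables.
#' @param rescale 8-bit rescaling of the downsampled channel: `"log"`
#'   (default; min--max of log10 intensities, matching the multiplicative
#'   dynamic range of fluorescence so that both a doubled tissue floor and a
#'   near-saturated aggregate remain distinguishable), `"minmax"` (linear),
#'   or `"percentile"` (linear with robust limits).
#' @param rescale_percentiles Percentiles used when `rescale = "percentile"`.
#' @return An `"artifact_config"` list.
#' @export
artifact_config <- function(downsample_factor = 4, kernel_diameter = c(3, 7),
                            seed_kernel_scale = 2.0, tolerance = 0.4,
                            tolerance_mode = c("relative", "absolute"),
                            min_region_area = 10, seed_mad_k = 5,
                            flood_mad_k = 5, bright_seed_min = 100,
                            mask_dilate = 0,
                            rescale = c("log", "minmax", "percentile"),
                            rescale_percentiles = c(1, 99)) {
  rescale <- match.arg(rescale)
  tolerance_mode <- match.arg(tolerance_mode)
  stopifnot(downsample_factor >= 1, tolerance >= 0, seed_kernel_scale > 1)
  if (tolerance_mode == "relative" && tolerance > 1) {
    abort("relative tolerance must lie in (0, 1]")
  }
  kd <- as.integer(kernel_diameter)
  kd <- ifelse(kd %% 2L == 0L, kd + 1L, kd)
  kd <- sort(unique(pmax(kd, 3L)))
  if (is.null(min_region_area)) min_region_area <- sum(.disk_kernel(kd[1]))
  structure(list(downsample_factor = as.integer(downsample_factor),
                 kernel_diameter = kd,
                 seed_kernel_scale = seed_kernel_scale,
                 tolerance = tolerance, tolerance_mode = tolerance_mode,
                 min_region_area = min_region_area,
                 seed_mad_k = seed_mad_k, flood_mad_k = flood_mad_k,
                 bright_seed_min = bright_seed_min, mask_dilate = mask_dilate,
                 rescale = rescale,
                 rescale_percentiles = rescale_percentiles),
            class = "artifact_config")
}

#' Downsample a channel and rescale to 8-bit
#'
#' Block-mean downsampling (edge-inclusive pooling when the factor does not
#' divide the dimensions) followed by min--max rescaling of the downsampled
#' channel onto `[0, 255]` (rounded). A constant channel has no detectable
#' artifacts and returns all zeros.
#'
#' @param image A [multiplex_image].
#' @param channel Channel name.
#' @param config An [artifact_config()].
#' @return Numeric matrix with integer values in `[0, 255]`, carrying the
#'   downsample factor as attribute `"factor"`.
#' @export
prepare_channel <- function(image, channel, config = artifact_config()) {
  m <- .block_mean(.channel(image, channel), config$downsample_factor)
  if (config$rescale == "log") m <- log10(m + 1)
  if (config$rescale == "percentile") {
    lim <- .quantile7(as.numeric(m), config$rescale_percentiles / 100)
  } else {
    lim <- range(m)
  }
  out <- if (lim[2] - lim[1] <= .Machine$double.eps) {
    matrix(0, nrow(m), ncol(m))
  } else {
    round(.clamp((m - lim[1]) / (lim[2] - lim[1]), 0, 1) * 255)
  }
  attr(out, "factor") <- config$downsample_factor
  out
}

#' Morphological transform of an 8-bit channel
#'
#' Disk-kernel erosion, then local mean smoothing, then dilation. Erosion
#' removes structures smaller than the kernel (individual bright cells),
#' smoothing levels residual texture, and dilation restores the spatial
#' extent of surviving artifact-scale features.
#'
#' @param img8 8-bit matrix from [prepare_channel()].
#' @param config An [artifact_config()].
#' @param kernel Disk diameter to use (default: the config's first, i.e.
#'   smallest, kernel).
#' @return Transformed matrix, values in `[0, 255]`.
#' @export
transform_channel <- function(img8, config = artifact_config(),
                              kernel = config$kernel_diameter[1]) {
  kd <- kernel
  if (kd > min(dim(img8))) abort("kernel larger than the (downsampled) image")
  k <- EBImage::makeBrush(kd, shape = "disc")
  # EBImage grayscale morphology operates on [0, 1] image data
  x <- EBImage::erode(img8 / 255, k)
  x <- EBImage::filter2(x, k / sum(k), boundary = "replicate")
  x <- EBImage::dilate(x, k)
  # back to whole 8-bit levels: keeps plateaus exact, so equal-valued local
  # maxima collapse to one seed per connected plateau
  out <- round(.clamp(x * 255, 0, 255))
  attr(out, "factor") <- attr(img8, "factor")
  out
}

#' Find artifact seed points
#'
#' Local maxima of the transformed image within a disk neighbourhood of
#' `kernel_diameter * seed_kernel_scale` whose value exceeds the robust
#' background gate `median + seed_mad_k * MAD`. Plateaus of equal value
#' yield one seed per connected plateau.
#'
#' @param timg Transformed matrix from [transform_channel()].
#' @param config An [artifact_config()].
#' @param kernel Disk diameter the transform used.
#' @return Tibble `row`, `col`, `value` (possibly zero rows).
#' @export
find_seeds <- function(timg, config = artifact_config(),
                       kernel = config$kernel_diameter[1]) {
  kd <- kernel * config$seed_kernel_scale
  kd <- as.integer(round(kd))
  if (kd %% 2L == 0L) kd <- kd + 1L
  kexp <- EBImage::makeBrush(max(kd, 3L), shape = "disc")
  localmax <- EBImage::dilate(timg / 255, kexp) * 255
  # MAD floored at one grey level so a near-flat background still gates
  gate <- median(timg) + config$seed_mad_k * max(mad(timg), 1)
  multi_scale <- length(config$kernel_diameter) > 1
  cap <- Inf
  if (multi_scale && kernel < max(config$kernel_diameter)) {
    gate <- max(gate, config$bright_seed_min)
  } else if (multi_scale) {
    cap <- config$bright_seed_min
  }
  cand <- timg >= localmax - 1e-9 & timg > gate & timg < cap
  if (!any(cand)) {
    return(tibble::tibble(row = integer(0), col = integer(0),
                          value = numeric(0)))
  }
  comp <- .label_components(cand)
  seeds <- lapply(seq_len(comp$n), function(i) {
    idx <- comp$pixels[[i]]
    best <- idx[which.max(timg[idx])]
    c(row = (best - 1L) %% nrow(timg) + 1L,
      col = (best - 1L) %/% nrow(timg) + 1L)
  })
  s <- do.call(rbind, seeds)
  tibble::tibble(row = as.integer(s[, "row"]), col = as.integer(s[, "col"]),
                 value = timg[s])
}

# 8-connected component labelling of a logical matrix; returns pixel index
# lists per component.
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  v <- as.logical(mask)
  visited <- logical(length(v))
  comps <- list()
  todo <- which(v)
  for (start in todo) {
    if (visited[start]) next
    visited[start] <- TRUE
    acc <- integer(0)
    frontier <- start
    while (length(frontier) > 0) {
      acc <- c(acc, frontier)
      nb <- .neighbors8(frontier, H, W)
      nb <- nb[v[nb] & !visited[nb]]
      nb <- unique(nb)
      visited[nb] <- TRUE
      frontier <- nb
    }
    comps[[length(comps) + 1]] <- acc
  }
  list(n = length(comps), pixels = comps)
}

# 8-neighbourhood of linear indices in an H x W matrix
.neighbors8 <- function(idx, H, W) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- r + dr >= 1L & r + dr <= H & c + dc >= 1L & c + dc <= W
    out <- c(out, idx[ok] + dr + dc * H)
  }
  out
}

#' Flood-fill artifact mask from seed points
#'
#' For each seed, the 8-connected region of pixels whose value lies within
#' `tolerance` of the seed value and above the robust background gate
#' (`median + seed_mad_k * MAD` of the transformed image -- a fill may not
#' descend into the background texture, which stands in for the interactive
#' per-region tolerance adjustment of a human operator); the union over
#' seeds, with connected components smaller than `min_region_area`
#' discarded, is the artifact mask at the downsampled scale.
#'
#' @param timg Transformed matrix from [transform_channel()].
#' @param seeds Seed tibble from [find_seeds()].
#' @param config An [artifact_config()].
#' @param channel Channel name recorded on the mask.
#' @return An `"artifact_mask"`: `channel`, logical `mask`,
#'   `downsample_factor`, and a `regions` tibble (id, area, seed point).
#' @export
flood_fill_mask <- function(timg, seeds, config = artifact_config(),
                            channel = NA_character_,
                            kernel = config$kernel_diameter[1]) {
  H <- nrow(timg); W <- ncol(timg)
  acc <- logical(H * W)
  v <- as.numeric(timg)
  floor_gate <- if (is.null(config$flood_mad_k)) -Inf
                else median(v) + config$flood_mad_k * max(mad(v), 1)
  for (i in seq_len(nrow(seeds))) {
    sidx <- (seeds$col[i] - 1L) * H + seeds$row[i]
    if (acc[sidx]) next                      # already inside a region
    tol <- if (config$tolerance_mode == "relative") {
      config$tolerance * v[sidx]
    } else config$tolerance
    ok <- abs(v - v[sidx]) <= tol & v > floor_gate
    visited <- logical(H * W)
    visited[sidx] <- TRUE
    frontier <- sidx
    while (length(frontier) > 0) {
      nb <- .neighbors8(frontier, H, W)
      nb <- unique(nb[ok[nb] & !visited[nb]])
      visited[nb] <- TRUE
      frontier <- nb
    }
    acc <- acc | visited
  }
  mask <- matrix(acc, H, W)
  comp <- .label_components(mask)
  regions <- list()
  for (i in seq_len(comp$n)) {
    px <- comp$pixels[[i]]
    if (length(px) < config$min_region_area) {
      mask[px] <- FALSE
    } else {
      peak <- px[which.max(timg[px])]
      regions[[length(regions) + 1]] <- tibble::tibble(
        id = length(regions) + 1L, area = length(px),
        seed_row = (peak - 1L) %% H + 1L, seed_col = (peak - 1L) %/% H + 1L)
    }
  }
  if (config$mask_dilate != 0 && any(mask)) {
    dd <- as.integer(round(abs(config$mask_dilate) * kernel))
    if (dd %% 2L == 0L) dd <- dd + 1L
    if (dd >= 3L) {
      br <- EBImage::makeBrush(dd, "disc")
      mask <- if (config$mask_dilate > 0) {
        EBImage::dilate(mask * 1, br) > 0
      } else {
        EBImage::erode(mask * 1, br) > 0
      }
    }
  }
  structure(list(channel = channel, mask = mask,
                 downsample_factor = config$downsample_factor,
                 regions = if (length(regions)) dplyr::bind_rows(regions)
                           else tibble::tibble(id = integer(0), area = integer(0),
                                               seed_row = integer(0),
                                               seed_col = integer(0))),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %s: %d region(s), %.2f%% of pixels (1/%d scale)\n",
              x$channel %||% "?", nrow(x$regions), 100 * mean(x$mask),
              x$downsample_factor))
  invisible(x)
}

#' Run the automated artifact detector
#'
#' Applies prepare/transform/seed/flood-fill per channel (and per kernel
#' scale, unioned) and returns one mask per channel (named list). Use
#' [combine_masks()] for the union across channels.
#'
#' @param image A [multiplex_image].
#' @param channels Channels to scan (default: all).
#' @param config An [artifact_config()].
#' @return Named list of `"artifact_mask"` objects.
#' @export
detect_artifacts <- function(image, channels = NULL,
                             config = artifact_config()) {
  channels <- channels %||% image$channels
  masks <- lapply(channels, function(ch) {
    img8 <- prepare_channel(image, ch, config)
    per_kernel <- list()
    claimed <- NULL   # pixels already claimed by smaller-kernel passes
    for (kd in config$kernel_diameter) {
      timg <- transform_channel(img8, config, kernel = kd)
      seeds <- find_seeds(timg, config, kernel = kd)
      if (!is.null(claimed) && nrow(seeds) > 0) {
        # a compact bright artifact leaves a faint halo at coarser scales;
        # larger kernels may not re-seed inside regions already claimed
        veto <- EBImage::dilate(claimed * 1, EBImage::makeBrush(kd, "disc")) > 0
        seeds <- seeds[!veto[cbind(seeds$row, seeds$col)], , drop = FALSE]
      }
      m <- flood_fill_mask(timg, seeds, config, channel = ch, kernel = kd)
      claimed <- if (is.null(claimed)) m$mask else claimed | m$mask
      per_kernel[[length(per_kernel) + 1]] <- m
    }
    m <- combine_masks(per_kernel)
    m$channel <- ch
    m
  })
  setNames(masks, channels)
}

#' Union of artifact masks
#'
#' @param masks List of `"artifact_mask"` objects at a common scale.
#' @return A single `"artifact_mask"` whose mask is the pixelwise union.
#' @export
combine_masks <- function(masks) {
  stopifnot(length(masks) > 0)
  m <- masks[[1]]$mask
  for (i in seq_along(masks)[-1]) {
    stopifnot(masks[[i]]$downsample_factor == masks[[1]]$downsample_factor)
    m <- m | masks[[i]]$mask
  }
  structure(list(channel = "union", mask = m,
                 downsample_factor = masks[[1]]$downsample_factor,
                 regions = dplyr::bind_rows(lapply(masks, function(x) x$regions))),
            class = "artifact_mask")
}

#' Drop cells inside an artifact mask
#'
#' The mask is upscaled to full resolution by block replication; a cell is
#' dropped when its centroid pixel lies inside (status `dropped_roi`, the
#' same category as manual ROI redaction). With
#' `membership = "any_pixel"` a segmentation mask must be supplied and a
#' cell is dropped when any of its pixels intersects the mask.
#'
#' @param table Spatial feature table.
#' @param mask An `"artifact_mask"` (single channel or union).
#' @param image_dim Full-resolution image dimensions `c(rows, cols)`.
#' @param membership `"centroid"` (default) or `"any_pixel"`.
#' @param segmentation Integer label mask (required for `"any_pixel"`).
#' @param sample_id Restrict to one sample (default: all rows).
#' @return Gated table with log entries appended.
#' @export
drop_cells_in_mask <- function(table, mask, image_dim,
                               membership = c("centroid", "any_pixel"),
                               segmentation = NULL, sample_id = NULL) {
  .assert_table(table)
  membership <- match.arg(membership)
  full <- .block_upscale(mask$mask, mask$downsample_factor, image_dim)
  sel <- if (is.null(sample_id)) rep(TRUE, nrow(table))
         else table$sample_id == sample_id
  doomed <- rep(FALSE, nrow(table))
  if (membership == "centroid") {
    ridx <- .clamp(round(table$y) + 1L, 1L, image_dim[1])
    cidx <- .clamp(round(table$x) + 1L, 1L, image_dim[2])
    doomed <- full[cbind(ridx, cidx)]
  } else {
    if (is.null(segmentation)) abort("any_pixel membership needs the segmentation mask")
    hit <- sort(unique(segmentation[full & segmentation > 0]))
    doomed <- table$cell_id %in% hit
  }
  before <- table$status
  table$status[sel & doomed & .retained_idx(table)] <- "dropped_roi"
  .log_status_change(table, before, "artifact",
                     list(channel = mask$channel,
                          downsample_factor = mask$downsample_factor,
                          membership = membership))
}
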