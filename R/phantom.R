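# Synthetic tissue phantom. Generates the four per-specimen inputs (image
# stack, label mask, boundary image, feature table) with known cell types
# and injected artifacts from the taxonomy seen in real cyclic-imaging data:
# tissue folds (bright in all channels), antibody aggregates (very bright
# blobs in one channel), autofluorescent fibers, smooth illumination
# aberrations, cross-cycle cell loss, segmentation errors and dim truncated
# nuclei. Ground truth is emitted for every class so each QC stage can be
# scored. Intensities are log-normal around type-specific means, which
# reproduces the right-skewed channel histograms of real data and leaves the
# artifact tail separable by a Gaussian mixture on the log scale.

#' Default cell-type panel for phantoms
#'
#' Six types over a six-marker panel (pan-immune, epithelial, T-helper,
#' cytotoxic-T, T-regulatory and smooth-muscle markers). Values are log10
#' mean intensities in arbitrary fluorescence units; unlisted markers sit at
#' the 2.0 (100 AFU) baseline.
#'
#' @return Tibble with columns `name`, `abundance` and one column per marker.
#' @export
phantom_cell_types <- function() {
  markers <- c("CD45", "panCK", "CD4", "CD8a", "FOXP3", "aSMA")
  base <- 2.0
  m <- matrix(base, nrow = 6, ncol = length(markers),
              dimnames = list(NULL, markers))
  m[1, "panCK"] <- 3.2                                   # tumor/epithelial
  m[2, "aSMA"] <- 3.0                                    # stromal
  m[3, c("CD45", "CD4")] <- 3.0                          # helper T
  m[4, c("CD45", "CD8a")] <- 3.0                         # cytotoxic T
  m[5, "CD45"] <- 3.0; m[5, "CD4"] <- 2.8; m[5, "FOXP3"] <- 3.0  # Treg
  m[6, "CD45"] <- 3.2                                    # other immune
  dplyr::bind_cols(
    tibble::tibble(
      name = c("tumor", "stromal", "T_helper", "T_cytotoxic", "Treg", "immune_other"),
      abundance = c(0.30, 0.20, 0.15, 0.12, 0.08, 0.15)),
    tibble::as_tibble(m))
}

#' Default artifact plan
#'
#' One block per artifact class; pass a named subset (or modified blocks) to
#' [phantom_spec()]. Counts and geometry are scaled for a 600x600 px field.
#' Magnitudes: folds double every channel (multiplicative gain 2), aggregates
#' sit near saturation (10^4.2 AFU, far above both background and biological
#' signal), fibers are bright in a few channels, aberrations add a smooth
#' gradient an order of magnitude above background, and cell loss leaves the
#' last-cycle DNA at 5% of its first-cycle value.
#'
#' @return Named list of per-class parameter blocks.
#' @export
phantom_artifacts <- function() {
  list(
    fold        = list(n = 1, size = 180, gain = 2),
    aggregate   = list(n = 6, radius = c(10, 16), log_intensity = 4.2),
    fiber       = list(n = 1, width = 3, n_steps = 400, log_intensity = 3.7,
                       n_channels = 3),
    aberration  = list(n = 1, sigma = 120, peak = 2000),
    cell_loss   = list(fraction = 0.20, factor = 0.05),
    overseg     = list(fraction = 0.05),
    underseg    = list(fraction = 0.05),
    dim_nuclei  = list(fraction = 0.05, factor = 0.2)
  )
}

#' Specify a synthetic specimen
#'
#' @param image_size Height/width in pixels (scalar or length-2).
#' @param pixel_size Micrometres per pixel (0.65 matches 20x acquisition with
#'   2x2 binning).
#' @param n_cycles Number of imaging cycles; one DNA channel per cycle.
#' @param cell_types Tibble as from [phantom_cell_types()].
#' @param cell_density Cells per pixel^2 (0.006 = 60 cells per 100x100 px).
#' @param min_spacing Minimum nucleus centre spacing in px (Poisson-disk).
#' @param nucleus_radius Mean and sd of nucleus radius in px.
#' @param dna_log_mean,dna_sd log10 mean/sd of first-cycle nuclear intensity.
#' @param marker_sd Per-cell log10 sd around the type mean.
#' @param cycle_jitter_sd log10 sd of cycle-to-cycle nuclear intensity jitter.
#' @param background,background_sd In-tissue background level and pixel
#'   noise (AFU). Formalin-fixed tissue autofluoresces well above the
#'   camera floor, so "background" inside tissue sits near 10% of nuclear
#'   signal; folds double it along with everything else, which is why they
#'   are visible in every channel.
#' @param glass_level Background outside tissue (AFU); used where tissue has
#'   detached in a cell-loss region (post-loss cycles revert to bare glass).
#' @param artifacts Named list of artifact blocks ([phantom_artifacts()]),
#'   a character vector naming default blocks to include, or `"none"`.
#' @param seed Integer seed; the whole phantom is a pure function of the spec.
#' @return A `"phantom_spec"` list.
#' @export
phantom_spec <- function(image_size = 600, pixel_size = 0.65, n_cycles = 3,
                         cell_types = phantom_cell_types(),
                         cell_density = 0.006, min_spacing = 8,
                         nucleus_radius = c(mean = 4, sd = 0.35),
                         dna_log_mean = 3.0, dna_sd = 0.12, marker_sd = 0.12,
                         cycle_jitter_sd = 0.02,
                         background = 100, background_sd = 10,
                         glass_level = 10,
                         artifacts = phantom_artifacts(), seed = 1) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  if (is.character(artifacts)) {
    artifacts <- if (identical(artifacts, "none")) list()
                 else phantom_artifacts()[artifacts]
  }
  stopifnot(abs(sum(cell_types$abundance) - 1) < 1e-8)
  markers <- setdiff(names(cell_types), c("name", "abundance"))
  cycles_for_markers <- rep(2:max(2, n_cycles), length.out = length(markers))
  structure(
    list(image_size = as.integer(image_size), pixel_size = pixel_size,
         n_cycles = as.integer(n_cycles), cell_types = cell_types,
         markers = markers, marker_cycle = setNames(cycles_for_markers, markers),
         cell_density = cell_density, min_spacing = min_spacing,
         nucleus_radius = nucleus_radius, dna_log_mean = dna_log_mean,
         dna_sd = dna_sd, marker_sd = marker_sd,
         cycle_jitter_sd = cycle_jitter_sd,
         background = background, background_sd = background_sd,
         glass_level = glass_level,
         artifacts = artifacts, seed = as.integer(seed)),
    class = "phantom_spec")
}

# -- geometry helpers --------------------------------------------------------

# Seeded dart-throwing Poisson-disk sampler on [margin, w-margin] etc.
.poisson_disk <- function(n_target, height, width, min_dist, margin) {
  cell <- min_dist / sqrt(2)
  gh <- ceiling(height / cell); gw <- ceiling(width / cell)
  grid <- matrix(0L, gh, gw)
  px <- numeric(n_target); py <- numeric(n_target)
  n <- 0L; attempts <- 0L; max_attempts <- 60L * n_target
  while (n < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- runif(1, margin, width - margin)
    y <- runif(1, margin, height - margin)
    gi <- floor(y / cell) + 1L; gj <- floor(x / cell) + 1L
    ri <- max(1L, gi - 2L):min(gh, gi + 2L)
    rj <- max(1L, gj - 2L):min(gw, gj + 2L)
    nb <- grid[ri, rj]
    nb <- nb[nb > 0L]
    if (length(nb) == 0L ||
        all((px[nb] - x)^2 + (py[nb] - y)^2 >= min_dist^2)) {
      n <- n + 1L
      px[n] <- x; py[n] <- y
      grid[gi, gj] <- n
    }
  }
  if (n < n_target) {
    abort(sprintf(
      "cell density too high for the Poisson-disk spacing (placed %d of %d)",
      n, n_target))
  }
  cbind(x = px[seq_len(n)], y = py[seq_len(n)])
}

# pixel offsets of a filled disk of radius r (row/col offsets)
.disk_offsets <- function(r) {
  ri <- ceiling(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 0.5, ]
  off
}

# even-odd rasterization of a polygon (vertices in 0-based x/y pixel coords)
# onto an image of dims; returns a logical matrix.
.rasterize_polygon <- function(poly, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  rr <- max(1, floor(min(poly[, 2])) + 1):min(dims[1], ceiling(max(poly[, 2])) + 1)
  cc <- max(1, floor(min(poly[, 1])) + 1):min(dims[2], ceiling(max(poly[, 1])) + 1)
  gx <- rep(cc - 1, each = length(rr))
  gy <- rep(rr - 1, times = length(cc))
  inside <- point_in_polygon(gx, gy, poly)
  m[cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))] <- inside
  m
}

# random blobby polygon around a centre (angular vertices, jittered radii)
.random_polygon <- function(cx, cy, size, n_vertices = 8) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- size / 2 * runif(n_vertices, 0.6, 1.1)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# -- generator ---------------------------------------------------------------

#' Generate a synthetic specimen with ground truth
#'
#' Nuclei are placed by seeded Poisson-disk sampling, per-cell intensities
#' drawn log-normally around type means, DNA channels rendered per cycle,
#' artifacts composited per the spec's plan, and the feature table computed
#' from the rendered image and the final mask, so table and image are
#' mutually consistent. The same seed yields bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A `"phantom"` list: `image` ([multiplex_image]), `mask` (integer
#'   matrix), `boundary` (logical matrix), `table` (spatial feature table,
#'   all cells `"retained"`), `truth` (list: `true_type` tibble,
#'   `artifact_map` per-class logical matrices, `affected_cells` per-class id
#'   sets, `lost_cells`, `misseg_cells`), and the `spec` itself.
#' @export
generate_phantom <- function(spec) {
  .with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  markers <- spec$markers
  dna_ch <- paste0("DNA", seq_len(spec$n_cycles))
  channels <- c(dna_ch, markers)
  cycle_of <- c(seq_len(spec$n_cycles), unname(spec$marker_cycle[markers]))
  n_ch <- length(channels)

  n_cells <- round(spec$cell_density * H * W)
  margin <- ceiling(spec$nucleus_radius[["mean"]] + 3 * spec$nucleus_radius[["sd"]]) + 1
  pts <- .poisson_disk(n_cells, H, W, spec$min_spacing, margin)
  n_cells <- nrow(pts)
  radius <- pmax(2, rnorm(n_cells, spec$nucleus_radius[["mean"]],
                          spec$nucleus_radius[["sd"]]))
  type_idx <- sample.int(nrow(spec$cell_types), n_cells, replace = TRUE,
                         prob = spec$cell_types$abundance)

  # --- label mask (first-placed cell wins contested pixels) ---
  mask <- matrix(0L, H, W)
  cr <- round(pts[, "y"]) + 1L   # centre row (1-based)
  cc <- round(pts[, "x"]) + 1L
  for (i in seq_len(n_cells)) {
    off <- .disk_offsets(radius[i])
    idx <- (cc[i] + off$dc - 1L) * H + (cr[i] + off$dr)
    idx <- idx[mask[idx] == 0L]
    mask[idx] <- i
  }

  # --- per-cell true intensities ---
  type_mat <- as.matrix(spec$cell_types[, markers])
  marker_val <- 10^(type_mat[type_idx, , drop = FALSE] +
                    matrix(rnorm(n_cells * length(markers), 0, spec$marker_sd),
                           n_cells))
  colnames(marker_val) <- markers
  dna_base <- 10^rnorm(n_cells, spec$dna_log_mean, spec$dna_sd)

  plan <- spec$artifacts
  dim_ids <- integer(0)
  if (!is.null(plan$dim_nuclei) && plan$dim_nuclei$fraction > 0) {
    dim_ids <- sort(sample.int(n_cells, round(plan$dim_nuclei$fraction * n_cells)))
    dna_base[dim_ids] <- dna_base[dim_ids] * plan$dim_nuclei$factor
  }
  # cycle-to-cycle multiplicative jitter of the nuclear stain
  dna_val <- outer(dna_base, rep(1, spec$n_cycles)) *
    10^matrix(rnorm(n_cells * spec$n_cycles, 0, spec$cycle_jitter_sd), n_cells)
  dna_val[, 1] <- dna_base   # first cycle is the reference

  # --- render channels ---
  lab_pix <- which(mask > 0L)
  pix_by_cell <- split(lab_pix, mask[lab_pix])
  pix_ids <- as.integer(names(pix_by_cell))
  pix_all <- unlist(pix_by_cell, use.names = FALSE)
  pix_len <- lengths(pix_by_cell)
  render <- function(values_per_cell) {
    img <- pmax(rnorm(H * W, spec$background, spec$background_sd), 0)
    img[pix_all] <- rep(values_per_cell[pix_ids], pix_len)
    matrix(img, H, W)
  }
  pixels <- array(0, c(H, W, n_ch), dimnames = list(NULL, NULL, channels))
  for (k in seq_len(spec$n_cycles)) pixels[, , dna_ch[k]] <- render(dna_val[, k])
  for (m in markers) pixels[, , m] <- render(marker_val[, m])

  # --- composite artifacts ---
  empty_map <- matrix(FALSE, H, W)
  maps <- list(fold = empty_map, aggregate = empty_map, fiber = empty_map,
               aberration = empty_map, cell_loss = empty_map)

  if (!is.null(plan$aberration)) {
    for (i in seq_len(plan$aberration$n)) {
      ch <- sample(markers, 1)
      ax <- runif(1, 0.2 * W, 0.8 * W); ay <- runif(1, 0.2 * H, 0.8 * H)
      d2 <- outer((seq_len(H) - 1 - ay)^2, (seq_len(W) - 1 - ax)^2, `+`)
      add <- plan$aberration$peak * exp(-d2 / (2 * plan$aberration$sigma^2))
      pixels[, , ch] <- pixels[, , ch] + add
      maps$aberration <- maps$aberration | (add >= 0.1 * plan$aberration$peak)
    }
  }
  if (!is.null(plan$fiber)) {
    for (i in seq_len(plan$fiber$n)) {
      chs <- sample(markers, plan$fiber$n_channels)
      x <- runif(1, 0.1 * W, 0.9 * W); y <- runif(1, 0.1 * H, 0.9 * H)
      ang <- runif(1, 0, 2 * pi)
      path <- matrix(NA_real_, plan$fiber$n_steps, 2)
      for (s in seq_len(plan$fiber$n_steps)) {
        ang <- ang + rnorm(1, 0, 0.15)
        x <- .clamp(x + cos(ang), 2, W - 1); y <- .clamp(y + sin(ang), 2, H - 1)
        path[s, ] <- c(x, y)
      }
      fmap <- empty_map
      off <- .disk_offsets(plan$fiber$width / 2)
      pr <- round(path[, 2]) + 1L; pc <- round(path[, 1]) + 1L
      for (s in seq_len(nrow(path))) {
        rr <- .clamp(pr[s] + off$dr, 1L, H); ccx <- .clamp(pc[s] + off$dc, 1L, W)
        fmap[cbind(rr, ccx)] <- TRUE
      }
      val <- 10^plan$fiber$log_intensity
      for (ch in chs) {
        sl <- pixels[, , ch]; sl[fmap] <- pmax(sl[fmap], val); pixels[, , ch] <- sl
      }
      maps$fiber <- maps$fiber | fmap
    }
  }
  if (!is.null(plan$aggregate)) {
    for (i in seq_len(plan$aggregate$n)) {
      ch <- sample(markers, 1)
      r <- runif(1, plan$aggregate$radius[1], plan$aggregate$radius[2])
      ax <- round(runif(1, r + 1, W - r - 1)); ay <- round(runif(1, r + 1, H - r - 1))
      off <- .disk_offsets(r)
      idx <- cbind(ay + 1L + off$dr, ax + 1L + off$dc)
      val <- 10^(plan$aggregate$log_intensity + rnorm(1, 0, 0.05))
      sl <- pixels[, , ch]; sl[idx] <- pmax(sl[idx], val); pixels[, , ch] <- sl
      amap <- empty_map; amap[idx] <- TRUE
      maps$aggregate <- maps$aggregate | amap
    }
  }
  if (!is.null(plan$fold)) {
    for (i in seq_len(plan$fold$n)) {
      cx <- runif(1, 0.25 * W, 0.75 * W); cy <- runif(1, 0.25 * H, 0.75 * H)
      fmap <- .rasterize_polygon(.random_polygon(cx, cy, plan$fold$size), c(H, W))
      for (k in seq_len(n_ch)) {
        sl <- pixels[, , k]; sl[fmap] <- sl[fmap] * plan$fold$gain
        pixels[, , k] <- sl
      }
      maps$fold <- maps$fold | fmap
    }
  }
  if (!is.null(plan$cell_loss) && plan$cell_loss$fraction > 0) {
    r <- sqrt(plan$cell_loss$fraction * H * W / pi)
    lx <- runif(1, r, W - r); ly <- runif(1, r, H - r)
    d2 <- outer((seq_len(H) - 1 - ly)^2, (seq_len(W) - 1 - lx)^2, `+`)
    lmap <- d2 <= r^2
    maps$cell_loss <- lmap
    # detached tissue leaves bare glass behind in post-loss cycles
    glasspix <- function() pmax(rnorm(sum(lmap), spec$glass_level,
                                      spec$glass_level / 5), 0)
    for (k in seq_len(n_ch)) {
      if (cycle_of[k] >= 2) {
        sl <- pixels[, , k]
        if (channels[k] %in% dna_ch) sl[lmap] <- sl[lmap] * plan$cell_loss$factor
        else sl[lmap] <- glasspix()
        pixels[, , k] <- sl
      }
    }
  }

  # --- segmentation errors (mask-only edits; the image is untouched) ---
  split_ids <- integer(0); merged_ids <- integer(0); absorbed <- integer(0)
  next_id <- n_cells
  if (!is.null(plan$underseg) && plan$underseg$fraction > 0) {
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    n_merge <- round(plan$underseg$fraction * n_cells / 2)
    used <- rep(FALSE, n_cells)
    cand <- order(apply(d, 1, min))
    for (i in cand) {
      if (n_merge <= 0) break
      j <- which.min(d[i, ])
      if (!used[i] && !used[j] && d[i, j] <= spec$min_spacing + 3) {
        used[i] <- used[j] <- TRUE
        mask[mask == j] <- i
        # bridge the two nuclei so the merged instance is one blob
        nseg <- ceiling(d[i, j])
        bx <- round(seq(pts[i, "x"], pts[j, "x"], length.out = nseg)) + 1L
        by <- round(seq(pts[i, "y"], pts[j, "y"], length.out = nseg)) + 1L
        for (s in seq_len(nseg)) {
          rr <- .clamp(by[s] + (-1:1), 1L, H); ccx <- .clamp(bx[s] + (-1:1), 1L, W)
          blk <- as.matrix(expand.grid(rr, ccx))
          blk <- blk[mask[blk] == 0L, , drop = FALSE]
          mask[blk] <- i
        }
        merged_ids <- c(merged_ids, i)
        absorbed <- c(absorbed, j)
        n_merge <- n_merge - 1
      }
    }
  }
  if (!is.null(plan$overseg) && plan$overseg$fraction > 0) {
    pool <- setdiff(seq_len(n_cells), c(merged_ids, absorbed))
    n_split <- min(round(plan$overseg$fraction * n_cells), length(pool))
    for (i in sample(pool, n_split)) {
      idx <- which(mask == i)
      cols <- (idx - 1L) %/% H + 1L
      right <- idx[cols > round(pts[i, "x"]) + 1]
      if (length(right) > 2 && length(right) < length(idx) - 2) {
        next_id <- next_id + 1L
        mask[right] <- next_id
        split_ids <- c(split_ids, i, next_id)
      }
    }
  }

  # --- feature table from final image + final mask ---
  pixels <- round(pixels)   # integer AFU, so file round-trips are exact
  lab_pix <- which(mask > 0L)
  labs <- mask[lab_pix]
  area <- tabulate(labs, nbins = max(labs))
  ids <- which(area > 0)
  rowp <- (lab_pix - 1L) %% H + 1L
  colp <- (lab_pix - 1L) %/% H + 1L
  xbar <- rowsum(colp - 1, labs)[, 1] / area[ids]
  ybar <- rowsum(rowp - 1, labs)[, 1] / area[ids]
  inten <- matrix(0, length(ids), n_ch, dimnames = list(NULL, channels))
  for (k in seq_len(n_ch)) {
    v <- pixels[, , k]
    inten[, k] <- rowsum(v[lab_pix], labs)[, 1] / area[ids]
  }
  table <- tibble::tibble(
    sample_id = "phantom", cell_id = as.integer(ids),
    x = unname(xbar), y = unname(ybar), area = as.numeric(area[ids]))
  table <- dplyr::bind_cols(table, tibble::as_tibble(inten))
  table$status <- "retained"

  # --- ground truth (split fragments inherit the parent's type) ---
  type_of <- spec$cell_types$name[type_idx]
  type_lookup <- type_of
  if (length(split_ids) > 0) {
    parent <- split_ids[seq(1, length(split_ids), by = 2)]
    child <- split_ids[seq(2, length(split_ids), by = 2)]
    type_lookup[child] <- type_of[parent]
  }
  tt <- tibble::tibble(cell_id = as.integer(ids), type = type_lookup[ids])
  centroid_in <- function(map) {
    ridx <- .clamp(round(table$y) + 1L, 1L, H)
    cidx <- .clamp(round(table$x) + 1L, 1L, W)
    table$cell_id[map[cbind(ridx, cidx)]]
  }
  affected <- lapply(maps, centroid_in)
  affected$dim_nuclei <- intersect(dim_ids, ids)
  affected$overseg <- split_ids
  affected$underseg <- merged_ids

  boundary <- .mask_boundary(mask)
  image <- multiplex_image(pixels, channels, spec$pixel_size, cycle_of, dna_ch)
  structure(
    list(image = image, mask = mask, boundary = boundary, table = table,
         truth = list(true_type = tt, artifact_map = maps,
                      affected_cells = affected,
                      lost_cells = affected$cell_loss,
                      misseg_cells = list(split = split_ids,
                                          merged = merged_ids)),
         spec = spec, sample_id = "phantom"),
    class = c("phantom", "specimen"))
}

# pixels whose label differs from a 4-neighbor are boundary pixels
.mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  b <- matrix(FALSE, H, W)
  d <- mask[-1, ] != mask[-H, ]
  b[-1, ] <- b[-1, ] | d; b[-H, ] <- b[-H, ] | d
  d <- mask[, -1] != mask[, -W]
  b[, -1] <- b[, -1] | d; b[, -W] <- b[, -W] | d
  b & mask > 0
}

# -- scoring against ground truth -------------------------------------------

#' Pixel IoU of a detected artifact mask against ground truth
#'
#' @param mask An `artifact_mask` (at downsampled scale) or a full-resolution
#'   logical matrix.
#' @param truth_map Full-resolution logical ground-truth map for one class.
#' @return Intersection-over-union in `[0, 1]`.
#' @export
score_mask_iou <- function(mask, truth_map) {
  m <- if (inherits(mask, "artifact_mask")) {
    .block_upscale(mask$mask, mask$downsample_factor, dim(truth_map))
  } else mask
  stopifnot(all(dim(m) == dim(truth_map)))
  inter <- sum(m & truth_map)
  uni <- sum(m | truth_map)
  if (uni == 0) return(1)
  inter / uni
}

#' Cell-level precision/recall of a redaction against ground truth
#'
#' @param table A gated feature table.
#' @param affected_ids Cell ids truly affected by the artifact class.
#' @param statuses Status values counted as "redacted" (default: all
#'   dropped states).
#' @return Tibble with `recall`, `precision` and `false_drop` (fraction of
#'   truly clean cells redacted).
#' @export
score_redaction <- function(table, affected_ids,
                            statuses = setdiff(qc_statuses(),
                                               c("retained", "reinstated"))) {
  .assert_table(table)
  dropped <- table$cell_id[table$status %in% statuses]
  clean <- setdiff(table$cell_id, affected_ids)
  tp <- length(intersect(dropped, affected_ids))
  tibble::tibble(
    recall = if (length(affected_ids)) tp / length(affected_ids) else NA_real_,
    precision = if (length(dropped)) tp / length(dropped) else NA_real_,
    false_drop = if (length(clean)) length(intersect(dropped, clean)) / length(clean)
                 else NA_real_)
}

#' Write a small multi-specimen exemplar dataset
#'
#' Emits `n_specimens` phantoms in the exact four-file layout consumed by
#' [load_specimen()], plus a `manifest.yml` naming every file and the channel
#' metadata. Regeneration with the same seed is file-identical.
#'
#' @param out_dir Output directory.
#' @param n_specimens Number of specimens.
#' @param size Image side in pixels per specimen.
#' @param seed Base seed; specimen `i` uses `seed + i`.
#' @param artifacts Artifact plan passed through to [phantom_spec()].
#' @return Invisibly, the manifest as a list.
#' @export
make_exemplar <- function(out_dir, n_specimens = 4, size = 300, seed = 1,
                          artifacts = phantom_artifacts()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", n_specimens)
  for (i in seq_len(n_specimens)) {
    id <- sprintf("specimen_%02d", i)
    ph <- generate_phantom(phantom_spec(image_size = size, seed = seed + i,
                                        artifacts = artifacts))
    ph$table$sample_id <- id
    entries[[i]] <- write_specimen(ph, out_dir, id)
  }
  manifest <- list(seed = seed, specimens = entries)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}
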