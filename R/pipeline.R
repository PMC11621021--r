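# Pipeline orchestration: the gate sequence of a full QC run, in the order
# ROI / automated artifact masks -> nuclear intensity -> segmentation area
# -> cross-cycle stability -> log transform -> percentile pruning ->
# metaQC audit. Each stage only touches cells still retained when it runs,
# and every drop/reinstate lands in the redaction log, so the final status
# partition is exactly replayable.

#' Default QC-run configuration
#'
#' Nested parameter list consumed by [run_qc()]; the same structure can be
#' stored as a YAML file next to the data (see [read_qc_config()]).
#'
#' @param rois Named list (by sample id) of ROI JSON paths, or `NULL`.
#' @param artifact `TRUE` to run the automated detector with defaults, a
#'   list of [artifact_config()] arguments, or `FALSE` to skip.
#' @param dna_intensity,area,cycle,prune,metaqc Per-stage parameter lists
#'   (`FALSE` disables a stage).
#' @param seed Seed for the stages that sample.
#' @return A `"qc_config"` list.
#' @export
qc_config <- function(rois = NULL,
                      artifact = TRUE,
                      dna_intensity = list(n_components = 3,
                                           quantiles = c(0.005, 0.995)),
                      area = list(n_components = 3,
                                  quantiles = c(0.005, 0.995)),
                      cycle = list(n_components = 2,
                                   quantiles = c(0.005, 0.995)),
                      prune = list(p_lo = 0.1, p_hi = 99.9,
                                   per_sample = FALSE),
                      metaqc = list(threshold = 0.75, k_cap = 1e5,
                                    min_cluster_size = 25),
                      seed = 1) {
  structure(list(rois = rois, artifact = artifact,
                 dna_intensity = dna_intensity, area = area, cycle = cycle,
                 prune = prune, metaqc = metaqc, seed = seed),
            class = "qc_config")
}

#' Read / write a QC configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_qc_config()]: a `"qc_config"` list.
#' @export
read_qc_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- qc_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg
}

#' @rdname read_qc_config
#' @param config A `"qc_config"`.
#' @export
write_qc_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# fit-and-gate one interval stage per sample on the retained cells
.gate_per_sample <- function(table, column, stage_fun, fit_fun) {
  for (s in unique(table$sample_id)) {
    sel <- table$sample_id == s & .retained_idx(table)
    th <- tryCatch(fit_fun(table[[column]][sel]), error = function(e) {
      warn(paste0("threshold fit failed for sample ", s, " on ", column,
                  " (", conditionMessage(e), "); stage skipped there"))
      NULL
    })
    if (is.null(th)) next
    sub <- table$sample_id == s
    sub_tb <- table[sub, ]
    attr(sub_tb, "qc_log") <- NULL   # entries already held on `table`
    gated <- stage_fun(sub_tb, th)
    table$status[sub] <- gated$status
    attr(table, "qc_log") <- dplyr::bind_rows(qc_log(table), qc_log(gated))
  }
  table
}

#' Run the QC pipeline over loaded specimens
#'
#' @param specimens List of `"specimen"` objects ([load_specimen()] or
#'   [generate_phantom()]), or a single one.
#' @param config A [qc_config()].
#' @param modules Stages to run (default: all, in pipeline order). A
#'   later-stage subset resumes a run on `table` (pass the table of a
#'   previous run via `table`).
#' @param table Optional starting table (resume support); defaults to
#'   aggregating the specimens.
#' @return A `"qc_run"` list: the final `table` (log attached), the
#'   `log`, the `report`, and the per-specimen artifact masks (if the
#'   detector ran).
#' @export
run_qc <- function(specimens, config = qc_config(),
                   modules = c("roi", "artifact", "dna_intensity", "area",
                               "cycle", "log_transform", "prune", "metaqc"),
                   table = NULL) {
  if (inherits(specimens, "specimen")) specimens <- list(specimens)
  modules <- match.arg(modules, several.ok = TRUE)
  table <- table %||% aggregate_samples(specimens)
  sample_of <- vapply(specimens, function(s) s$table$sample_id[1], character(1))
  masks <- list()

  if ("roi" %in% modules && !is.null(config$rois)) {
    for (s in names(config$rois)) {
      for (rs in read_rois(config$rois[[s]])) {
        table <- apply_roi_mode(table, rs)
      }
    }
  }
  if ("artifact" %in% modules && !isFALSE(config$artifact)) {
    acfg <- if (isTRUE(config$artifact)) artifact_config()
            else do.call(artifact_config, config$artifact)
    for (i in seq_along(specimens)) {
      sp <- specimens[[i]]
      u <- combine_masks(detect_artifacts(sp$image, config = acfg))
      masks[[sample_of[i]]] <- u
      table <- drop_cells_in_mask(table, u, dim(sp$mask),
                                  sample_id = sample_of[i])
    }
  }
  dna1 <- specimens[[1]]$image$dna_channels[1]
  if ("dna_intensity" %in% modules && !isFALSE(config$dna_intensity)) {
    table <- .gate_per_sample(
      table, dna1,
      function(t, th) gate_dna_intensity(t, th, dna_channel = dna1),
      function(v) fit_gmm_thresholds(
        v, n_components = config$dna_intensity$n_components,
        quantiles = config$dna_intensity$quantiles, transform = "log10"))
  }
  if ("area" %in% modules && !isFALSE(config$area)) {
    table <- .gate_per_sample(
      table, "area", gate_area,
      function(v) fit_gmm_thresholds(
        v, n_components = config$area$n_components,
        quantiles = config$area$quantiles, transform = "log10"))
  }
  if ("cycle" %in% modules && !isFALSE(config$cycle)) {
    table <- compute_cycle_ratio(table, specimens[[1]]$image$dna_channels)
    table <- .gate_per_sample(
      table, "cycle_ratio", gate_stable_cells,
      function(v) fit_gmm_thresholds(
        v[is.finite(v)], n_components = config$cycle$n_components,
        quantiles = config$cycle$quantiles))
  }
  if ("log_transform" %in% modules) {
    table <- log_transform(table)
  }
  if ("prune" %in% modules && !isFALSE(config$prune)) {
    table <- prune_percentile_outliers(
      table, p_lo = config$prune$p_lo, p_hi = config$prune$p_hi,
      per_sample = isTRUE(config$prune$per_sample))
  }
  if ("metaqc" %in% modules && !isFALSE(config$metaqc)) {
    table <- metaqc_audit(
      table, threshold = config$metaqc$threshold,
      k_cap = config$metaqc$k_cap,
      min_cluster_size = config$metaqc$min_cluster_size,
      log10_transform = !("log_transform" %in% modules),
      seed = config$seed)
  }
  structure(list(table = table, log = qc_log(table),
                 report = qc_report(table), masks = masks,
                 config = config),
            class = "qc_run")
}

#' @export
print.qc_run <- function(x, ...) {
  p <- qc_partition(x$table)
  kept <- sum(p$fraction[p$status %in% c("retained", "reinstated")])
  cat(sprintf("<qc_run> %d cells, %.1f%% retained after QC\n",
              nrow(x$table), 100 * kept))
  print(p[p$n > 0, ])
  invisible(x)
}

#' @export
glance.qc_run <- function(x, ...) {
  p <- qc_partition(x$table)
  out <- tibble::as_tibble(as.list(setNames(p$fraction, p$status)))
  out$n_cells <- nrow(x$table)
  out
}
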