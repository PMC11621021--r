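# Per-cell gates: Gaussian-mixture thresholds on nuclear intensity and
# segmentation area, cross-cycle DNA-ratio gating of unstable (lost) cells,
# log10 transformation of protein signals, and per-channel percentile
# outlier pruning. All gates are interval gates -- widening [lower, upper]
# never drops more cells -- and each stage only touches cells that are still
# retained when it runs.

#' Fit gate thresholds with a univariate Gaussian mixture
#'
#' Fits a `K`-component unequal-variance Gaussian mixture to the supplied
#' values (optionally log10-transformed first). The "valid" population is
#' taken to be the component with the largest mixing weight; the returned
#' thresholds are that component's normal quantiles (0.5% and 99.5% by
#' default). Three components accommodate the dim-debris / valid /
#' oversaturated trimodality typical of nuclear-stain histograms; pass
#' `n_components = 2` when the data are known to be bimodal.
#'
#' @param values Numeric vector (at least 50 finite values).
#' @param n_components Number of mixture components `K` (default 3).
#' @param quantiles Lower/upper quantiles of the valid component.
#' @param transform `"identity"` fits the values as given; `"log10"` fits
#'   their log10 (thresholds are then on the log10 scale).
#' @return A `"qc_gate"` object: `lower`, `upper`, `scale`, `source =
#'   "gmm"`, and `model` (means, sds, weights of the full mixture, for the
#'   QC log).
#' @export
fit_gmm_thresholds <- function(values, n_components = 3,
                               quantiles = c(0.005, 0.995),
                               transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  v <- values[is.finite(values)]
  if (transform == "log10") {
    if (any(v <= 0)) abort("log10 transform requires positive values")
    v <- log10(v)
  }
  if (length(v) < 50) abort("need at least 50 finite values to fit a mixture")
  if (var(v) <= .Machine$double.eps) abort("degenerate distribution: zero variance")
  if (length(unique(v)) < n_components) {
    abort("fewer distinct values than mixture components")
  }
  # unequal variances preferred; equal-variance fallback for heavily tied
  # data (e.g. small-integer pixel areas) where the "V" EM degenerates
  fit <- Mclust(v, G = n_components, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    fit <- Mclust(v, G = n_components, modelNames = "E", verbose = FALSE)
  }
  if (is.null(fit)) abort("mixture fit failed")
  w <- fit$parameters$pro
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  valid <- which.max(w)
  gate(lower = qnorm(quantiles[1], mu[valid], sig[valid]),
       upper = qnorm(quantiles[2], mu[valid], sig[valid]),
       scale = if (transform == "log10") "log10" else "linear",
       source = "gmm",
       model = list(weights = as.numeric(w), means = as.numeric(mu),
                    sds = as.numeric(sig), valid_component = valid,
                    quantiles = quantiles))
}

#' Construct gate thresholds manually
#'
#' @param lower,upper Bounds on the gated scale (`lower <= upper`).
#' @param scale `"linear"` or `"log10"` -- the scale the bounds live on.
#' @param source `"gmm"` or `"manual"`.
#' @param model Optional fitted-mixture record.
#' @return A `"qc_gate"` object.
#' @export
gate <- function(lower, upper, scale = c("linear", "log10"),
                 source = c("manual", "gmm"), model = NULL) {
  scale <- match.arg(scale)
  source <- match.arg(source)
  if (lower > upper) abort("gate lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper, scale = scale,
                 source = source, model = model), class = "qc_gate")
}

#' @export
print.qc_gate <- function(x, ...) {
  cat(sprintf("<qc_gate> [%.4g, %.4g] on %s scale (%s)\n",
              x$lower, x$upper, x$scale, x$source))
  invisible(x)
}

# value vector on the gate's scale
.on_gate_scale <- function(v, gate) {
  if (gate$scale == "log10") log10(pmax(v, .Machine$double.xmin)) else v
}

.interval_gate <- function(table, column, gate, stage) {
  .assert_table(table)
  if (!column %in% names(table)) abort(paste0("no such column: ", column))
  v <- .on_gate_scale(table[[column]], gate)
  out <- !is.na(v) & v >= gate$lower & v <= gate$upper
  before <- table$status
  table$status[.retained_idx(table) & !out] <- unname(.stage_status[stage])
  .log_status_change(table, before, stage,
                     list(column = column, lower = gate$lower,
                          upper = gate$upper, scale = gate$scale,
                          source = gate$source))
}

#' Gate cells on first-cycle nuclear intensity
#'
#' Cells whose mean first-cycle DNA intensity falls outside
#' `[lower, upper]` are dropped (`dropped_dna_intensity`). Dim nuclei are
#' typically truncated by sectioning or out of focus; very bright nuclei are
#' oversaturated or sit in tissue folds.
#'
#' @param table Spatial feature table.
#' @param thresholds A `"qc_gate"` ([fit_gmm_thresholds()] or [gate()]).
#' @param dna_channel Column holding first-cycle DNA intensity.
#' @return Gated table with log entries appended.
#' @export
gate_dna_intensity <- function(table, thresholds, dna_channel = "DNA1") {
  .interval_gate(table, dna_channel, thresholds, "dna_intensity")
}

#' Gate cells on segmentation area
#'
#' Undersegmented (merged) instances exceed the upper bound; oversegmented
#' fragments fall below the lower bound. Dropped status is `dropped_area`.
#'
#' @inheritParams gate_dna_intensity
#' @return Gated table with log entries appended.
#' @export
gate_area <- function(table, thresholds) {
  .interval_gate(table, "area", thresholds, "area")
}

#' Cross-cycle DNA ratio per cell
#'
#' Adds the column `cycle_ratio` = log10(DNA_first / DNA_last) computed from
#' the first and last entries of `dna_channels`. Stable cells sit near 0;
#' cells lost between cycles form a discrete peak at positive ratios. Cells
#' with non-positive last-cycle DNA get `+Inf` (always unstable).
#'
#' @param table Spatial feature table.
#' @param dna_channels Character vector of per-cycle DNA channel names (only
#'   the first and last entries are used).
#' @return The table with a `cycle_ratio` column added.
#' @export
compute_cycle_ratio <- function(table, dna_channels) {
  .assert_table(table)
  first <- dna_channels[1]
  last <- dna_channels[length(dna_channels)]
  for (cc in c(first, last)) {
    if (!cc %in% names(table)) abort(paste0("missing DNA channel column: ", cc))
  }
  d1 <- table[[first]]
  dn <- table[[last]]
  r <- ifelse(dn <= 0, Inf, log10(d1 / dn))
  table$cycle_ratio <- r
  table
}

#' Fit stability bounds for the cycle ratio
#'
#' Default bounds come from a Gaussian mixture on the finite ratios: the
#' largest-weight component is the stable population around zero and the
#' bounds are its (0.5%, 99.5%) quantiles. Override with [gate()] if needed.
#'
#' @param table Table with a `cycle_ratio` column ([compute_cycle_ratio()]).
#' @param n_components Mixture components (default 2: stable vs lost).
#' @param quantiles Quantiles of the stable component.
#' @return A `"qc_gate"` on the ratio scale.
#' @export
fit_ratio_bounds <- function(table, n_components = 2,
                             quantiles = c(0.005, 0.995)) {
  if (!"cycle_ratio" %in% names(table)) {
    abort("run compute_cycle_ratio() first")
  }
  fit_gmm_thresholds(table$cycle_ratio[is.finite(table$cycle_ratio)],
                     n_components = n_components, quantiles = quantiles)
}

#' Gate unstable cells on the cycle ratio
#'
#' Cells whose `cycle_ratio` falls outside the bounds are dropped
#' (`dropped_unstable`); `+Inf` ratios always fail.
#'
#' @param table Table with a `cycle_ratio` column.
#' @param bounds A `"qc_gate"` ([fit_ratio_bounds()] or [gate()]).
#' @return Gated table with log entries appended.
#' @export
gate_stable_cells <- function(table, bounds) {
  .interval_gate(table, "cycle_ratio", bounds, "cycle_correlation")
}

#' log10-transform protein signals
#'
#' Replaces each intensity column `v` by `log10(v + eps)` where `eps`
#' defaults to the smallest positive value of that channel, keeping
#' zero-valued cells finite. DNA channels are left on the linear scale by
#' default (the cycle-ratio gate consumes them raw).
#'
#' @param table Spatial feature table (intensities must be non-negative).
#' @param channels Columns to transform; defaults to all non-DNA channels.
#' @param eps Pseudo-count; `NULL` (default) uses the per-channel smallest
#'   positive value.
#' @return The transformed table; the applied scale is recorded in the
#'   `"intensity_scale"` attribute.
#' @export
log_transform <- function(table, channels = NULL, eps = NULL) {
  .assert_table(table)
  channels <- channels %||% intensity_channels(table, markers_only = TRUE)
  for (ch in channels) {
    v <- table[[ch]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative intensities in channel ", ch,
                   "; background-subtracted inputs are not supported"))
    }
    e <- eps %||% {
      pos <- v[v > 0]
      if (length(pos) == 0) 1 else min(pos)
    }
    table[[ch]] <- log10(v + e)
  }
  attr(table, "intensity_scale") <- "log10"
  table
}

#' Prune per-channel percentile outliers
#'
#' For each listed channel (in panel order), cells below the `p_lo` or above
#' the `p_hi` percentile are dropped (`dropped_outlier`). Quantiles use the
#' linear-interpolation definition and are computed over currently retained
#' cells, per sample when `per_sample = TRUE`.
#'
#' @param table Spatial feature table.
#' @param channels Channels to prune; defaults to all non-DNA channels.
#' @param p_lo,p_hi Percentile cutoffs in `[0, 100]`, `p_lo < p_hi`.
#' @param per_sample Compute quantiles within each sample.
#' @return Gated table with log entries appended.
#' @export
prune_percentile_outliers <- function(table, channels = NULL,
                                      p_lo = 0.1, p_hi = 99.9,
                                      per_sample = FALSE) {
  .assert_table(table)
  if (!(p_lo >= 0 && p_hi <= 100 && p_lo < p_hi)) {
    abort("need 0 <= p_lo < p_hi <= 100")
  }
  channels <- channels %||% intensity_channels(table, markers_only = TRUE)
  for (ch in channels) {
    before <- table$status
    alive <- .retained_idx(table)
    doomed <- rep(FALSE, nrow(table))
    groups <- if (per_sample) table$sample_id else rep("all", nrow(table))
    for (g in unique(groups[alive])) {
      sel <- alive & groups == g
      v <- table[[ch]][sel]
      q <- .quantile7(v, c(p_lo, p_hi) / 100)
      doomed[sel] <- v < q[1] | v > q[2]
    }
    table$status[alive & doomed] <- "dropped_outlier"
    table <- .log_status_change(table, before, "prune_outliers",
                                list(channel = ch, p_lo = p_lo, p_hi = p_hi,
                                     per_sample = per_sample))
  }
  table
}

#' @export
tidy.qc_gate <- function(x, ...) {
  tibble::tibble(term = c("lower", "upper"),
                 value = c(x$lower, x$upper),
                 scale = x$scale, source = x$source)
}

#' @export
glance.qc_gate <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper, scale = x$scale,
                 source = x$source,
                 n_components = length(x$model$weights %||% numeric(0)))
}
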