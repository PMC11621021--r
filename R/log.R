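# Redaction log: a per-cell record of which QC stage removed (or reinstated)
# each cell, with the parameters in force at the time. Replaying the log over
# the raw table must reproduce the final status column exactly, which is what
# makes a QC run auditable without the original interactive session.

.stage_status <- c(
  roi              = "dropped_roi",
  artifact         = "dropped_roi",
  dna_intensity    = "dropped_dna_intensity",
  area             = "dropped_area",
  cycle_correlation = "dropped_unstable",
  prune_outliers   = "dropped_outlier",
  metaqc           = "dropped_metaqc"
)

#' Empty redaction log
#'
#' @return A zero-row tibble with columns `sample_id`, `cell_id`, `stage`,
#'   `action`, `timestamp` and `params` (a JSON string of the parameters
#'   used by the stage).
#' @export
new_qc_log <- function() {
  tibble::tibble(
    sample_id = character(), cell_id = integer(), stage = character(),
    action = character(), timestamp = character(), params = character()
  )
}

#' Redaction log attached to a table
#'
#' Gating functions accumulate their log entries on the returned table as an
#' attribute so that piped stages compose; `qc_log()` retrieves them.
#'
#' @param table A spatial feature table that has passed through QC stages.
#' @return A redaction-log tibble (possibly empty).
#' @export
qc_log <- function(table) {
  attr(table, "qc_log") %||% new_qc_log()
}

# Record a drop/reinstate diff between two status vectors and append it to
# the table's log attribute. `params` is a named list, serialised to JSON.
.log_status_change <- function(table, before_status, stage, params = list()) {
  after <- table$status
  changed <- which(after != before_status)
  if (length(changed) > 0) {
    action <- ifelse(after[changed] == "reinstated", "reinstate", "drop")
    entries <- tibble::tibble(
      sample_id = table$sample_id[changed],
      cell_id = as.integer(table$cell_id[changed]),
      stage = stage,
      action = action,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
    )
    attr(table, "qc_log") <- dplyr::bind_rows(qc_log(table), entries)
  }
  table
}

#' Replay a redaction log over a raw table
#'
#' Applies the logged drop/reinstate actions, in order, to a table whose
#' cells all start `"retained"`. The result's status column is identical to
#' the one produced by the original run.
#'
#' @param raw_table The pre-QC spatial feature table.
#' @param log A redaction log, as returned by [qc_log()] or read back from
#'   the JSON written by [write_outputs()].
#' @return The table with the final status column reproduced.
#' @export
replay_log <- function(raw_table, log) {
  .assert_table(raw_table)
  out <- raw_table
  out$status <- "retained"
  if (nrow(log) == 0) return(out)
  key <- paste(out$sample_id, out$cell_id)
  for (i in seq_len(nrow(log))) {
    j <- match(paste(log$sample_id[i], log$cell_id[i]), key)
    if (is.na(j)) {
      abort(paste0("log entry refers to unknown cell ", log$sample_id[i],
                   "/", log$cell_id[i]))
    }
    out$status[j] <- if (log$action[i] == "reinstate") "reinstated"
                     else unname(.stage_status[log$stage[i]])
  }
  out
}
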