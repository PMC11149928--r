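# Plain-text interchange: recordings as 2-column CSV (time_s, voltage) with a
# JSON sidecar carrying the sampling rate and metadata; event/ground-truth
# tables and tidy results as CSV; run manifests as JSON.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write LFP recordings as CSV + JSON sidecar
#'
#' The CSV holds `time_s, voltage`; the sidecar (same path with `.json`
#' extension) holds `fs`, `channel_id`, `trial` and any extra metadata.
#'
#' @param rec An [lfp_recording()].
#' @param path CSV file path.
#' @param meta Extra metadata stored in the sidecar (e.g. generator specs,
#'   seed).
#' @return `write_lfp()` returns `path` invisibly; `read_lfp()` an `lfp_tbl`
#'   with the sidecar metadata in attribute `meta`.
#' @export
write_lfp <- function(rec, path, meta = list()) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  side <- c(list(fs = lfp_fs(rec),
                 channel_id = attr(rec, "channel_id"),
                 trial = attr(rec, "trial")), meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  rec <- lfp_recording(df$voltage, fs = side$fs,
                       channel_id = side$channel_id %||% "ch1",
                       trial = side$trial)
  attr(rec, "meta") <- side
  rec
}

#' Write event, ground-truth or tidy-result tables as CSV
#'
#' @param x A tibble (e.g. `swr_events`, ground truth, or [run_session()]
#'   output).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records every parameter of a run (detection thresholds, bands, toggles,
#' seeds, package version) so an analysis is reproducible from its outputs.
#'
#' @param manifest Named list, e.g. `attr(run_session(...), "manifest")`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
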