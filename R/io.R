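## Delimited-text recording format with a JSON metadata sidecar.
##
## CSV layout: header `t,emgR1..emgR4,emgL1..emgL4,accRx,accRy,accRz,
## accLx,accLy,accLz`, one row per sample.  The sidecar holds the sampling
## rate, class labels and annotation boundaries (0-based inclusive sample
## indices), and optionally the generator seed and parameters.

#' Write a recording to CSV plus a JSON metadata sidecar
#'
#' @param recording an `slr_recording`.
#' @param path CSV output path.
#' @param meta_path sidecar path (default: `path` with a `.json`
#'   extension).
#' @param extra optional named list merged into the sidecar (e.g.
#'   generator seed and parameters).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            meta_path = sub("\\.csv$", ".json", path),
                            extra = NULL) {
  df <- data.frame(t = seq_len(nrow(recording$emg)) - 1L,
                   recording$emg, recording$acc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(fs_hz = recording$fs_hz,
                 annotations = recording$annotations), extra)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path.
#' @param meta_path sidecar path.
#' @return an `slr_recording`.
#' @export
read_recording <- function(path,
                           meta_path = sub("\\.csv$", ".json", path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c(emg_channel_names(), acc_channel_names())
  if (!all(want %in% names(df)))
    stop("recording CSV lacks the expected channel columns")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ann <- if (length(meta$annotations) > 0)
    as.data.frame(meta$annotations)
  else data.frame(class_id = integer(0), t_start = integer(0),
                  t_end = integer(0))
  new_recording(as.matrix(df[, emg_channel_names()]),
                as.matrix(df[, acc_channel_names()]),
                ann, fs_hz = meta$fs_hz)
}

#' Write segmentation output: one CSV per segment plus a boundary manifest
#'
#' @param segmented result of [segment_recording()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_segments <- function(segmented, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(segmented$segments)) {
    s <- segmented$segments[[i]]
    df <- data.frame(t = seq_len(nrow(s$emg)) - 1L, s$emg, s$acc,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("segment_%03d.csv", i)),
                     row.names = FALSE)
  }
  manifest <- file.path(dir, "boundaries.json")
  jsonlite::write_json(list(T_R = segmented$T_R,
                            boundaries = segmented$boundaries),
                       manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(manifest)
}
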