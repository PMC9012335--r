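#' Write a recording to CSV with a YAML metadata sidecar
#'
#' Samples are written as one column per channel (header = channel labels,
#' values in \eqn{\mu}V); the sampling rate and phase/patient metadata go to
#' a YAML sidecar at `<path>.meta.yaml`, since CSV itself carries no rate
#' information.
#'
#' @param recording An `eug_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  df <- as.data.frame(t(recording$samples))
  names(df) <- recording$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    sampling_rate_hz = recording$sampling_rate,
    phase = recording$phase,
    recording_id = recording$recording_id,
    patient_id = recording$patient_id,
    n_channels = nrow(recording$samples),
    n_samples = ncol(recording$samples),
    units = "uV"
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a recording from CSV (+ YAML sidecar)
#'
#' Inverse of [write_recording_csv()]. If the sidecar is missing the
#' recording is still loaded, with `phase = "unknown"`, a default sampling
#' rate of 256 Hz and a warning — the degraded-metadata path.
#'
#' @param path CSV path as written by [write_recording_csv()].
#' @param default_sampling_rate Rate assumed when the sidecar is absent.
#' @return An `eug_recording`.
#' @export
read_recording_csv <- function(path, default_sampling_rate = 256) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("malformed recording CSV (no channels/samples): ", path)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("malformed recording CSV: non-numeric sample column in ", path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    for (field in c("sampling_rate_hz", "recording_id"))
      if (is.null(meta[[field]]))
        stop("malformed sidecar ", sc, ": missing field `", field, "`")
    fs <- meta$sampling_rate_hz
    phase <- if (is.null(meta$phase)) "unknown" else meta$phase
    rid <- meta$recording_id
    pid <- if (is.null(meta$patient_id)) NA_character_ else meta$patient_id
  } else {
    warning("metadata sidecar not found (", sc, "); loading with ",
            "phase = \"unknown\" and sampling rate ", default_sampling_rate,
            " Hz")
    fs <- default_sampling_rate
    phase <- "unknown"
    rid <- tools::file_path_sans_ext(basename(path))
    pid <- NA_character_
  }
  structure(list(
    samples = t(as.matrix(df)),
    sampling_rate = fs,
    channel_labels = names(df),
    phase = phase,
    recording_id = rid,
    patient_id = pid,
    config = NULL
  ), class = "eug_recording")
}

#' Write / read a feature table
#'
#' Plain CSV, one row per segment, with provenance comment lines (prefixed
#' `#`) carrying the master seed and config hash when supplied, so that
#' outputs are auditable and byte-reproducible.
#'
#' @param table Feature data frame ([extract_features()] rows).
#' @param path Output CSV path.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    for (k in names(provenance))
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## Tiny 31-bit polynomial hash over the deparsed object; provenance only
## (avoids a digest dependency). Exact double arithmetic: 31 * (2^31 - 2)
## + 255 < 2^53.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
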