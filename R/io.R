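# Plain-text fixture container and result exports. A recording is stored
# as a directory holding data.tsv (channels x samples, one row per
# channel, first column the label), events.tsv, and meta.json. The format
# is self-contained and human-readable; it is the package's interchange
# format for raw simulated recordings.

#' Write a recording to the fixture container
#'
#' @param recording An `fpvs_recording`.
#' @param dir Directory to create (must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing container.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, overwrite = FALSE) {
  stopifnot(inherits(recording, "fpvs_recording"))
  if (dir.exists(dir)) {
    if (!overwrite) stop("directory exists: ", dir)
  } else dir.create(dir, recursive = TRUE)
  dat <- data.frame(label = recording$channel_labels,
                    recording$data, check.names = FALSE)
  utils::write.table(dat, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(recording$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = recording$subject_id, group = recording$group,
               sampling_rate = recording$sampling_rate,
               n_channels = length(recording$channel_labels),
               n_samples = ncol(recording$data))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording from the fixture container
#'
#' @param dir Directory written by [write_recording()].
#' @return An `fpvs_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  dat <- utils::read.table(file.path(dir, "data.tsv"), sep = "\t",
                           stringsAsFactors = FALSE)
  events <- utils::read.table(file.path(dir, "events.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  structure(list(data = as.matrix(dat[, -1, drop = FALSE]),
                 sampling_rate = meta$sampling_rate,
                 channel_labels = dat[[1]],
                 events = events,
                 subject_id = meta$subject_id,
                 group = meta$group),
            class = "fpvs_recording")
}

#' Export a response table as tidy CSV
#'
#' @param table An `fpvs_response_table`.
#' @param path Output CSV path.
#' @export
export_response_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Export a harmonic plan as JSON
#'
#' @param plan An `fpvs_harmonic_plan`.
#' @param path Output JSON path.
#' @export
export_harmonic_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Export per-bin spectrum statistics as CSV
#'
#' Writes frequency, per-channel amplitude, and (for the requested bins)
#' SNR, baseline-corrected amplitude and z-score.
#'
#' @param spectrum An `fpvs_spectrum`.
#' @param path Output CSV path.
#' @param bins Bin indices for which the noise-window statistics are
#'   computed (default: none, amplitudes only).
#' @param spec An [noise_window_spec()].
#' @export
export_spectrum_csv <- function(spectrum, path, bins = integer(0),
                                spec = noise_window_spec()) {
  amp <- t(spectrum$amplitudes)
  colnames(amp) <- paste0("amp_", spectrum$channel_labels %||%
                            seq_len(nrow(spectrum$amplitudes)))
  out <- data.frame(frequency = spectrum$frequencies, amp,
                    check.names = FALSE)
  if (length(bins)) {
    stats_rows <- lapply(bins, function(b) data.frame(
      bin = b, frequency = spectrum$frequencies[b],
      snr = mean(snr(spectrum, b, spec)),
      baseline_corrected = mean(baseline_corrected(spectrum, b, spec)),
      z = mean(zscore_bin(spectrum, b, spec))))
    attr(out, "bin_stats") <- do.call(rbind, stats_rows)
    utils::write.csv(attr(out, "bin_stats"),
                     sub("\\.csv$", "_bins.csv", path), row.names = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a pipeline configuration to JSON
#'
#' The configuration round-trips: [read_pipeline_config()] rebuilds an
#' equivalent validated object.
#'
#' @param config An `fpvs_pipeline_config`.
#' @param path Output JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "fpvs_pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # named atomic vectors would serialize as plain arrays; keep the names
  x$sim$oddball_amp <- lapply(x$sim$oddball_amp, as.list)
  x$noise_spec <- unclass(x$noise_spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sim_args <- x$sim[names(x$sim) %in% names(formals(sim_config))]
  sim_args$oddball_amp <- lapply(x$sim$oddball_amp, as.list)
  sim <- do.call(sim_config, sim_args)
  ns <- do.call(noise_window_spec,
                x$noise_spec[c("side_bins", "exclude_adjacent", "exclude_extreme")])
  args <- x[names(x) %in% names(formals(pipeline_config))]
  args$sim <- sim
  args$noise_spec <- ns
  args$rois <- lapply(x$rois, as.character)
  args$base_rois <- lapply(x$base_rois, as.character)
  do.call(pipeline_config, args)
}
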