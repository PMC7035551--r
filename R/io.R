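#' Read and write the package's plain-text data formats
#'
#' Waveforms travel as CSV with header \code{t,ecg,ppg} (seconds,
#' arbitrary amplitude units) plus a JSON sidecar (\code{<file>.json})
#' recording the sampling rate; cuff readings as CSV
#' \code{t_start,t_end,sbp,dbp}; PAT series as CSV
#' \code{beat_time,pat}; windows as CSV
#' \code{t_start,t_end,pat_bar,n_beats}.
#'
#' @param wave A \code{patbp_waveform}.
#' @param path CSV file path.
#' @return Writers return \code{path} invisibly; readers return the
#'   corresponding object/data.frame.
#' @export
write_waveform_csv <- function(wave, path) {
  utils::write.csv(data.frame(t = wave$t, ecg = wave$ecg,
                              ppg = wave$ppg),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs = wave$fs, t0 = wave$t0),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(fs = round(1 / stats::median(diff(df$t))), t0 = df$t[1L])
  structure(list(fs = as.numeric(meta$fs), t0 = as.numeric(meta$t0),
                 t = df$t, ecg = df$ecg, ppg = df$ppg),
            class = "patbp_waveform")
}

#' @rdname write_waveform_csv
#' @param df A data.frame in the matching schema.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_table_csv <- function(path) utils::read.csv(path)
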