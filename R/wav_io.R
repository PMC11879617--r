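#' Write a single-channel WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and IEEE float32, the two
#' encodings used by long-term passive acoustic recorders. Samples are taken
#' as *digital* full-scale units (float: +-1.0; PCM16: mapped to +-32767);
#' absolute calibration to pressure lives in the sidecar metadata, not in
#' the WAV itself.
#'
#' @param samples numeric vector of digital samples
#' @param path output file path
#' @param sample_rate_hz sampling rate in Hz
#' @param format `"float32"` (default) or `"pcm16"`
#' @return `path`, invisibly
#' @seealso [read_wav()], [write_deployment_metadata()]
#' @export
write_wav <- function(samples, path, sample_rate_hz, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(length(samples) > 0, sample_rate_hz > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L; data_bytes <- 4L * n
  } else {
    fmt_code <- 1L; bits <- 16L; data_bytes <- 2L * n
  }
  block_align <- bits %/% 8L
  byte_rate <- as.integer(sample_rate_hz) * block_align
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a single-channel WAV file
#'
#' Counterpart of [write_wav()]. Walks the RIFF chunk list, so files with
#' extra metadata chunks are read correctly. Errors on truncated files name
#' the byte offset at which the file ended.
#'
#' @param path WAV file path
#' @return list with `samples` (digital units), `sample_rate_hz`, `format`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt_code <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_; nchan <- NA_integer_
  samples <- NULL
  offset <- 12
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) stop("truncated WAV (chunk header) at byte ", offset, ": ", path)
    offset <- offset + 8
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      nchan <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (is.na(fmt_code)) stop("WAV data chunk before fmt chunk: ", path)
      bytes_per <- bits %/% 8L
      n <- sz %/% bytes_per
      if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", n, size = 4, endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                           endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (format ", fmt_code, ", ", bits, " bit)")
      }
      if (length(samples) < n) {
        stop("truncated WAV data at byte ", offset + length(samples) * bytes_per,
             ": ", path)
      }
    } else {
      readBin(con, "raw", sz)
    }
    offset <- offset + sz
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("WAV file has no data chunk: ", path)
  if (!is.na(nchan) && nchan != 1L) stop("only single-channel WAV supported")
  list(samples = samples, sample_rate_hz = rate,
       format = if (fmt_code == 3L) "float32" else "pcm16")
}

#' Deployment sidecar metadata
#'
#' Recorder deployments carry a JSON sidecar with position, depth, recorder
#' gain and hydrophone sensitivity, the UTC start of the file series, and the
#' full-scale pressure mapping that makes the digital samples absolutely
#' calibrated (dB re 1 uPa).
#'
#' @param site_id character site label (e.g. `"R1"`)
#' @param latitude,longitude decimal degrees
#' @param depth_m recorder depth in metres
#' @param gain_db recorder set gain, dB
#' @param sensitivity_db hydrophone sensitivity magnitude, dB re 1 V/uPa
#' @param sample_rate_hz sampling rate
#' @param utc_start start of the file series, `POSIXct` or ISO string
#' @param full_scale_upa pressure in uPa corresponding to digital full scale
#'   (1.0); this is what converts WAV samples back to pressure
#' @param clipped logical, whether any sample hit full scale during rendering
#' @return a `deployment_metadata` list
#' @export
deployment_metadata <- function(site_id, latitude = 0, longitude = 0,
                                depth_m = 0, gain_db = 0, sensitivity_db = 0,
                                sample_rate_hz = 5333,
                                utc_start = "2013-01-01T00:00:00Z",
                                full_scale_upa = 1, clipped = FALSE) {
  stopifnot(abs(latitude) <= 90, abs(longitude) <= 180, sample_rate_hz > 0)
  structure(list(site_id = site_id, latitude = latitude, longitude = longitude,
                 depth_m = depth_m, gain_db = gain_db,
                 sensitivity_db = sensitivity_db,
                 sample_rate_hz = sample_rate_hz,
                 utc_start = format(utc_start), full_scale_upa = full_scale_upa,
                 clipped = clipped),
            class = "deployment_metadata")
}

#' @rdname deployment_metadata
#' @param meta a `deployment_metadata` object
#' @param path JSON path to write/read
#' @export
write_deployment_metadata <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname deployment_metadata
#' @export
read_deployment_metadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(deployment_metadata, x[setdiff(names(x), character())])
}

#' Read a WAV file together with its calibration sidecar
#'
#' Returns an `audio_segment`: a pressure time series (uPa) when the sidecar
#' metadata is present, or the raw digital samples flagged `calibrated =
#' FALSE` (with a warning) when it is missing. The sidecar is looked up as
#' `<path without .wav>.json`, falling back to a per-directory
#' `deployment.json`.
#'
#' @param path WAV path
#' @param metadata optional `deployment_metadata` overriding sidecar lookup
#' @return an `audio_segment` list: `samples` (uPa if calibrated),
#'   `sample_rate_hz`, `calibrated`, `meta`, `file_id`
#' @export
read_wav_with_metadata <- function(path, metadata = NULL) {
  wav <- read_wav(path)
  if (is.null(metadata)) {
    side <- sub("\\.wav$", ".json", path, ignore.case = TRUE)
    if (!file.exists(side)) side <- file.path(dirname(path), "deployment.json")
    if (file.exists(side)) metadata <- read_deployment_metadata(side)
  }
  if (is.null(metadata)) {
    warning("no sidecar metadata for ", basename(path),
            "; samples are uncalibrated digital units")
    return(audio_segment(wav$samples, wav$sample_rate_hz, calibrated = FALSE,
                         file_id = sub("\\.wav$", "", basename(path),
                                       ignore.case = TRUE)))
  }
  pressure <- wav$samples * metadata$full_scale_upa
  audio_segment(pressure, wav$sample_rate_hz, calibrated = TRUE,
                meta = metadata,
                file_id = sub("\\.wav$", "", basename(path),
                              ignore.case = TRUE))
}

#' Calibrated audio container
#'
#' @param samples numeric samples (uPa when `calibrated`)
#' @param sample_rate_hz Hz
#' @param calibrated logical
#' @param meta optional `deployment_metadata`
#' @param file_id identifier used in downstream tables
#' @export
audio_segment <- function(samples, sample_rate_hz, calibrated = TRUE,
                          meta = NULL, file_id = "audio") {
  stopifnot(sample_rate_hz > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 calibrated = isTRUE(calibrated), meta = meta,
                 file_id = file_id),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %s: %.1f s @ %g Hz (Nyquist %.1f Hz), %s\n",
              x$file_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, x$sample_rate_hz / 2,
              if (x$calibrated) "calibrated (uPa)" else "uncalibrated"))
  invisible(x)
}

#' Duration and Nyquist accessors
#' @param audio an `audio_segment`
#' @export
audio_duration_s <- function(audio) length(audio$samples) / audio$sample_rate_hz

#' @rdname audio_duration_s
#' @export
audio_nyquist_hz <- function(audio) audio$sample_rate_hz / 2
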