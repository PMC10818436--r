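#' Detector trajectory record
#'
#' A uniformly sampled multi-channel record of the position-sensing detector:
#' horizontal and vertical difference signals plus, optionally, the aggregated
#' (total-intensity) signal. Units travel with the object: raw voltages
#' (`"V"`, `"mV"`), normalized dimensionless ratios (`"a.u."`, the difference
#' signal divided by the aggregated signal) or calibrated positions (`"nm"`).
#'
#' @param horizontal,vertical numeric channel vectors of equal length.
#' @param aggregated optional total-intensity channel, same length.
#' @param sampling_frequency sampling rate (Hz).
#' @param units one of `"V"`, `"mV"`, `"a.u."`, `"nm"`.
#' @param start_time time of the first sample (s).
#'
#' @return An object of class `trajectory`.
#' @seealso [read_trajectory()], [normalize_channels()]
#' @export
trajectory <- function(horizontal, vertical, aggregated = NULL,
                       sampling_frequency, units = c("V", "mV", "a.u.", "nm"),
                       start_time = 0) {
  units <- match.arg(units)
  check_positive_scalar(sampling_frequency, "sampling_frequency")
  if (length(horizontal) < 1L)
    stop_trapcal("channels must contain at least one sample", "format_error")
  if (length(vertical) != length(horizontal) ||
      (!is.null(aggregated) && length(aggregated) != length(horizontal)))
    stop_trapcal("all present channel sequences must have equal length", "format_error")
  structure(
    list(horizontal = as.numeric(horizontal),
         vertical = as.numeric(vertical),
         aggregated = if (!is.null(aggregated)) as.numeric(aggregated),
         sampling_frequency = sampling_frequency,
         units = units,
         start_time = start_time),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples at %g Hz (%.4g s), units %s%s\n",
              length(x$horizontal), x$sampling_frequency,
              length(x$horizontal) / x$sampling_frequency, x$units,
              if (is.null(x$aggregated)) ", no aggregated channel" else ""))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$horizontal)

#' @export
as.data.frame.trajectory <- function(x, ...) {
  d <- data.frame(
    time_s = x$start_time + (seq_along(x$horizontal) - 1) / x$sampling_frequency,
    horizontal = x$horizontal,
    vertical = x$vertical)
  if (!is.null(x$aggregated)) d$aggregated <- x$aggregated
  d
}

#' Read and write trajectory files
#'
#' Trajectories are stored as comma-delimited text with a header row
#' (`time_s,horizontal,vertical[,aggregated]`; the time column is optional and
#' ignored, sampling being uniform) plus a structured-text (YAML) metadata
#' sidecar carrying at least `sampling_frequency_hz` and `units`, and
#' optionally `temperature_k`, `bead_radius_m`, `viscosity_pa_s`, `seed`.
#' Values are written in scientific notation at full double precision so a
#' write/read round trip is bit-exact. Both LF and CRLF line endings are
#' accepted.
#'
#' @param path path of the data file.
#' @param sidecar path of the metadata sidecar; defaults to `<path>.yml`.
#' @param metadata for [write_trajectory()], a named list merged into the
#'   sidecar in addition to the mandatory keys.
#'
#' @return [read_trajectory()] returns a [trajectory()] with the remaining
#'   sidecar fields attached as attribute `"metadata"`. [write_trajectory()]
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path, sidecar = paste0(path, ".yml")) {
  if (!file.exists(path))
    stop_trapcal(sprintf("trajectory file '%s' not found", path), "config_error")
  if (!file.exists(sidecar))
    stop_trapcal(sprintf("metadata sidecar '%s' not found", sidecar), "config_error")
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$sampling_frequency_hz))
    stop_trapcal("sidecar is missing 'sampling_frequency_hz'", "config_error")
  if (is.null(meta$units))
    stop_trapcal("sidecar is missing 'units'", "config_error")

  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_trapcal("trajectory file has no data rows", "format_error")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  ncol <- length(header)
  cells <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf != ncol))
    stop_trapcal(sprintf("ragged row: data row %d has %d fields, header has %d",
                         which(nf != ncol)[1L], nf[nf != ncol][1L], ncol),
                 "format_error")
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(cells)))),
              ncol = ncol, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop_trapcal(sprintf("non-numeric cell in data row %d of '%s'", bad, path),
                 "parse_error")
  }
  colnames(m) <- header
  need <- c("horizontal", "vertical")
  if (!all(need %in% header))
    stop_trapcal("header must name 'horizontal' and 'vertical' channels",
                 "format_error")
  tr <- trajectory(
    horizontal = m[, "horizontal"],
    vertical = m[, "vertical"],
    aggregated = if ("aggregated" %in% header) m[, "aggregated"],
    sampling_frequency = meta$sampling_frequency_hz,
    units = meta$units,
    start_time = if ("time_s" %in% header) m[1L, "time_s"] else 0)
  extra <- meta[setdiff(names(meta), c("sampling_frequency_hz", "units"))]
  attr(tr, "metadata") <- extra
  tr
}

#' @rdname read_trajectory
#' @param t a [trajectory()].
#' @export
write_trajectory <- function(t, path, sidecar = paste0(path, ".yml"),
                             metadata = list()) {
  stopifnot(inherits(t, "trajectory"))
  d <- as.data.frame(t)
  fmt <- function(v) sprintf("%.17g", v)
  rows <- do.call(paste, c(lapply(d, fmt), sep = ","))
  writeLines(c(paste(names(d), collapse = ","), rows), path)
  meta <- c(list(sampling_frequency_hz = t$sampling_frequency, units = t$units),
            metadata)
  yaml::write_yaml(meta, sidecar, precision = 12)
  invisible(path)
}

#' Normalize difference channels by the aggregated signal
#'
#' Divides the horizontal and vertical detector channels elementwise by the
#' aggregated (total-intensity) channel, yielding the dimensionless ratio
#' signal in which hydrodynamic calibration constants are expressed. The
#' aggregated channel is retained unchanged and the units tag becomes
#' `"a.u."`. Applying it to an already-normalized trajectory is an error,
#' never a silent re-division.
#'
#' @param t a [trajectory()] in `"V"` or `"mV"` with an aggregated channel.
#' @return The normalized [trajectory()].
#' @export
normalize_channels <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  if (!t$units %in% c("V", "mV"))
    stop_trapcal(sprintf("normalize_channels requires voltage units, got '%s'",
                         t$units), "precondition_error")
  if (is.null(t$aggregated))
    stop_trapcal("aggregated channel is required for normalization",
                 "precondition_error")
  zero <- which(t$aggregated == 0)
  if (length(zero))
    stop_trapcal(sprintf("aggregated signal is zero at sample %d", zero[1L]),
                 "division_error")
  out <- t
  out$horizontal <- t$horizontal / t$aggregated
  out$vertical <- t$vertical / t$aggregated
  out$units <- "a.u."
  out
}

#' Acquisition channel configuration and range arithmetic
#'
#' Describes one analog input channel of the acquisition board: programmable
#' gain, unipolar or bipolar range mode, full-scale voltage and converter bit
#' depth. [channel_range()] returns the representable voltage interval —
#' `[0, V_max/g]` for a unipolar channel and `[-V_max/(2g), +V_max/(2g)]` for
#' a bipolar one — and [bit_resolution()] the voltage step of one count,
#' `V_max / (g 2^b)`.
#'
#' @param gain integer amplification factor; one of 1, 2, 4, 8.
#' @param range_mode `"unipolar"` or `"bipolar"`.
#' @param v_max full-scale voltage of the board (V).
#' @param bit_depth A/D converter resolution in bits.
#'
#' @return [channel_config()] returns an object of class `channel_config`;
#'   [channel_range()] a length-2 numeric interval (V); [bit_resolution()] a
#'   scalar (V per count).
#'
#' @examples
#' channel_range(channel_config(2, "bipolar"))     # -2.5 .. 2.5 V
#' bit_resolution(channel_config(1, "bipolar"))    # 10 / 2^16 V
#' @export
channel_config <- function(gain, range_mode = c("unipolar", "bipolar"),
                           v_max = 10, bit_depth = 16) {
  range_mode <- match.arg(range_mode)
  if (!is.numeric(gain) || length(gain) != 1L || !gain %in% c(1, 2, 4, 8))
    stop_trapcal("gain must be one of 1, 2, 4, 8", "config_error")
  check_positive_scalar(v_max, "v_max", "config_error")
  if (!is.numeric(bit_depth) || length(bit_depth) != 1L ||
      bit_depth < 1 || bit_depth != round(bit_depth))
    stop_trapcal("bit_depth must be an integer >= 1", "config_error")
  structure(list(gain = gain, range_mode = range_mode,
                 v_max = v_max, bit_depth = bit_depth),
            class = "channel_config")
}

#' @rdname channel_config
#' @param c a [channel_config()].
#' @export
channel_range <- function(c) {
  stopifnot(inherits(c, "channel_config"))
  if (c$range_mode == "unipolar") c(0, c$v_max / c$gain)
  else c(-c$v_max / (2 * c$gain), c$v_max / (2 * c$gain))
}

#' @rdname channel_config
#' @export
bit_resolution <- function(c) {
  stopifnot(inherits(c, "channel_config"))
  c$v_max / (c$gain * 2^c$bit_depth)
}
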