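# Raw on-disk dialect: per channel, little-endian signed 16-bit sample files
# in fixed-length time segments (`ch<NN>/seg<KKK>.i16`) plus one JSON sidecar
# (`meta.json`) holding everything needed for lossless read-back up to
# quantization: waveform geometry, gain, count-to-current scale, segment
# length and channel list. The default count scale maps the full int16 range
# to +-2000 nA (+-10 V at 200 nA/V).

#' Default count-to-current scale of the raw dialect
#'
#' Nanoamps per integer count; the full signed 16-bit range spans +-2000 nA.
#' @return scalar, nA per count.
#' @export
defaultCountScale <- function() 2000 / 32767

.chDir <- function(dir, ch) file.path(dir, sprintf("ch%02d", ch))

#' Write scan streams to the raw binary dialect
#'
#' Serializes one or more [ScanStream-class] objects (one channel each) as
#' little-endian signed 16-bit sample files split into `segmentLength`-second
#' segments, plus a `meta.json` sidecar. Currents are quantized as
#' `round(current / countScale)` and clipped to the int16 range.
#'
#' @param streams a [ScanStream-class] or list of them (distinct channels,
#'   shared waveform/gain).
#' @param dir output recording directory (created if needed).
#' @param countScale nanoamps per count; see [defaultCountScale()].
#' @return `dir`, invisibly.
#' @seealso [readRaw()]
#' @export
writeRaw <- function(streams, dir, countScale = defaultCountScale()) {
  if (is(streams, "ScanStream")) streams <- list(streams)
  stopifnot(length(streams) > 0L, countScale > 0)
  for (s in streams) validObject(s)
  ids <- vapply(streams, channelId, integer(1))
  if (anyDuplicated(ids)) stop("duplicate channel ids in stream list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  ref <- streams[[1L]]
  wf <- waveform(ref)
  scansPerSeg <- max(1L, as.integer(round(ref@segmentLength *
                                            wf@repetitionRate)))
  for (s in streams) {
    d <- .chDir(dir, channelId(s))
    dir.create(d, showWarnings = FALSE)
    counts <- round(scans(s) / countScale)
    counts[counts > 32767] <- 32767
    counts[counts < -32768] <- -32768
    nScans <- nrow(counts)
    segStarts <- seq(1L, nScans, by = scansPerSeg)
    for (k in seq_along(segStarts)) {
      idx <- segStarts[k]:min(segStarts[k] + scansPerSeg - 1L, nScans)
      con <- file(file.path(d, sprintf("seg%03d.i16", k)), "wb")
      writeBin(as.integer(t(counts[idx, , drop = FALSE])), con,
               size = 2L, endian = "little")
      close(con)
    }
  }
  meta <- list(
    dialect = "fscv-raw-1",
    endianness = "little",
    countScale = countScale,
    gain = ref@gain,
    segmentLength = ref@segmentLength,
    waveform = list(vHold = wf@vHold, vPeak = wf@vPeak,
                    scanRate = wf@scanRate,
                    samplesPerScan = wf@samplesPerScan,
                    repetitionRate = wf@repetitionRate),
    channels = sort(ids),
    nScans = vapply(streams[order(ids)], function(s) nrow(scans(s)),
                    integer(1))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.readMeta <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  if (!file.exists(mpath))
    stop("missing sidecar metadata: ", mpath)
  jsonlite::read_json(mpath, simplifyVector = TRUE)
}

#' Read scan streams from the raw binary dialect
#'
#' Reconstructs per-channel [ScanStream-class] objects from a recording
#' directory written by [writeRaw()]: currents are `counts * countScale`
#' nanoamps, scans are partitioned by `samplesPerScan`, and scan times are
#' derived from the scan index and repetition rate.
#'
#' @param dir recording directory containing `meta.json`.
#' @param channels optional integer vector of channel ids to read; all
#'   channels in the sidecar when `NULL`.
#' @return a named list (`"ch00"`, ...) of [ScanStream-class] objects.
#' @export
readRaw <- function(dir, channels = NULL) {
  meta <- .readMeta(dir)
  wf <- buildRamp(meta$waveform$vHold, meta$waveform$vPeak,
                  meta$waveform$scanRate, meta$waveform$samplesPerScan,
                  meta$waveform$repetitionRate)
  if (is.null(channels)) channels <- meta$channels
  n <- wf@samplesPerScan
  out <- list()
  for (ch in channels) {
    d <- .chDir(dir, ch)
    segs <- sort(list.files(d, pattern = "^seg[0-9]+\\.i16$",
                            full.names = TRUE))
    if (!length(segs)) stop("no segment files for channel ", ch)
    samples <- lapply(segs, function(f) {
      sz <- file.size(f)
      if (sz %% (2L * n) != 0L)
        stop(sprintf(
          "corrupt segment %s: %d bytes is not a whole number of %d-sample scans",
          f, sz, n))
      con <- file(f, "rb")
      on.exit(close(con))
      readBin(con, "integer", n = sz / 2L, size = 2L, signed = TRUE,
              endian = "little")
    })
    counts <- unlist(samples, use.names = FALSE)
    mat <- matrix(counts * meta$countScale, ncol = n, byrow = TRUE)
    out[[sprintf("ch%02d", ch)]] <- scanStream(
      mat, channelId = ch, waveform = wf, gain = meta$gain,
      segmentLength = meta$segmentLength)
  }
  out
}
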