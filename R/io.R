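# Recording / epoch I/O: a plain binary array container with a JSON sidecar,
# and a minimal EDF (European Data Format) writer+reader.  The EDF code
# implements the standard 16-bit integer layout directly with
# writeBin/readBin; it supports exactly what this package emits (one
# continuous record per file, physical scaling per channel).

#' Write a recording as a binary array + JSON sidecar
#'
#' The container is a raw little-endian float64 dump of the channels x samples
#' matrix (column-major, i.e. sample-by-sample) next to a `.json` sidecar
#' holding `fs`, `channel_names`, `subject_id`, `label` and the dimensions.
#'
#' @param rec an [eeg_recording()].
#' @param path output path; `.bin` and `.json` extensions are appended.
#' @return invisibly, the two file paths.
#' @export
write_array_recording <- function(rec, path) {
  bin <- paste0(path, ".bin"); sidecar <- paste0(path, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(format = "eegfuse-array-v1",
               dims = dim(rec$data), fs = rec$fs,
               channel_names = rec$channel_names,
               subject_id = rec$subject_id, label = rec$label)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin, json = sidecar))
}

#' Read a recording from the binary array container
#' @param path path stem as given to [write_array_recording()].
#' @return an [eeg_recording()].
#' @export
read_array_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "eegfuse-array-v1"))
    stop("not an eegfuse array container: ", path)
  n <- prod(meta$dims)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  eeg_recording(matrix(x, meta$dims[1], meta$dims[2]), meta$fs,
                channel_names = meta$channel_names,
                subject_id = meta$subject_id, label = meta$label)
}

#' Write a cohort to a directory
#'
#' One array container (or EDF file) per recording plus a `manifest.json`
#' listing subject ids and labels.
#'
#' @param recs list of [eeg_recording()] objects.
#' @param dir output directory (created if needed).
#' @param format `"array"` or `"edf"`.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(recs, dir, format = c("array", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in recs) {
    stem <- file.path(dir, rec$subject_id)
    if (format == "array") write_array_recording(rec, stem)
    else write_edf(rec, paste0(stem, ".edf"))
  }
  manifest <- list(format = format,
                   subjects = vapply(recs, `[[`, "", "subject_id"),
                   labels = vapply(recs, `[[`, 0L, "label"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory containing a `manifest.json`.
#' @return list of [eeg_recording()] objects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_along(manifest$subjects), function(i) {
    stem <- file.path(dir, manifest$subjects[i])
    rec <- if (manifest$format == "array") read_array_recording(stem)
           else read_edf(paste0(stem, ".edf"))
    rec$label <- as.integer(manifest$labels[i])
    rec
  })
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width)   # left-justified, space padded
}

#' Write a recording to EDF
#'
#' Emits a standard EDF file with one data record spanning the whole
#' recording and 16-bit samples scaled to each channel's physical range.
#'
#' @param rec an [eeg_recording()].
#' @param path output `.edf` path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  nch <- nrow(rec$data); ns <- ncol(rec$data)
  phys_min <- apply(rec$data, 1, min); phys_max <- apply(rec$data, 1, max)
  span <- pmax(phys_max - phys_min, 1e-9)
  dig <- round((sweep(sweep(rec$data, 1, phys_min), 1, span, "/")) * 65535 - 32768)
  header <- paste0(
    pad_field("0", 8), pad_field(rec$subject_id, 80),
    pad_field("eegfuse synthetic", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * nch, 8), pad_field("", 44),
    pad_field(1, 8), pad_field(format(ns / rec$fs), 8), pad_field(nch, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, pad_field, "", width = 16), collapse = ""),
    strrep(pad_field("", 80), nch),                 # transducer
    strrep(pad_field("uV", 8), nch),
    paste(vapply(phys_min, function(v) pad_field(signif(v, 7), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) pad_field(signif(v, 7), 8), ""), collapse = ""),
    strrep(pad_field(-32768, 8), nch),
    strrep(pad_field(32767, 8), nch),
    strrep(pad_field("", 80), nch),                 # prefiltering
    strrep(pad_field(ns, 8), nch),
    strrep(pad_field("", 32), nch))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig), con, eos = NULL)
  for (ch in seq_len(nch))
    writeBin(as.integer(pmin(pmax(dig[ch, ], -32768), 32767)), con,
             size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the continuous 16-bit EDF layout (any number of data records,
#' equal samples-per-record across records).
#'
#' @param path `.edf` path.
#' @return an [eeg_recording()] (label is `NA`; it is carried by cohort
#'   manifests, not by EDF).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)                     # physical dimension
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  data <- matrix(0, nch, sum(spr[1]) * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        phys_min[ch] + (raw - dig_min[ch]) * scale
    }
  }
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs, channel_names = labels, subject_id = subject)
}

#' Write an epoch set to a binary container + JSON sidecar
#' @param ep an `epoch_set` (see [segment_epochs()]).
#' @param path path stem; `.bin`/`.json` appended.
#' @return invisibly, the file paths.
#' @export
write_epochs <- function(ep, path) {
  bin <- paste0(path, ".bin"); sidecar <- paste0(path, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(ep$epochs), con, size = 8, endian = "little")
  meta <- list(format = "eegfuse-epochs-v1", dims = dim(ep$epochs),
               fs = ep$fs, labels = ep$labels, subject_ids = ep$subject_ids)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin, json = sidecar))
}

#' Read an epoch set written by [write_epochs()]
#' @param path path stem.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "eegfuse-epochs-v1"))
    stop("not an eegfuse epochs container: ", path)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = prod(meta$dims), size = 8, endian = "little")
  epoch_set(array(x, meta$dims), as.integer(meta$labels),
            meta$subject_ids, meta$fs)
}
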