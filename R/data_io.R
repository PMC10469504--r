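# Readers and writers for continuous EEG recordings.  EDF / EDF+ (16-bit,
# text annotation channel) is fully supported in both directions.  GDF
# support covers the GDF1-style subset this package writes (EDF-like
# field-major binary channel headers, int16 samples, trailing event table
# of mode/count/positions/types); real-world GDF 2.x recordings written by
# other software are out of scope.  Everything downstream consumes only
# epoch_set objects, never these readers.

pad_str <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

num_field <- function(raw, what) {
  s <- trimws(rawToChar(raw))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("malformed EDF header: field '", what,
                     "' is not numeric ('", s, "')", call. = FALSE)
  v
}

#' Write an EDF/EDF+ file
#'
#' Writes a multichannel recording as one EDF data record of 16-bit
#' samples, with an optional EDF+ annotation channel carrying the event
#' table as text annotations.
#'
#' @param path Output file.
#' @param signals Numeric matrix `n_channels x n_samples` (physical units,
#'   microvolts).
#' @param channel_names Character vector, one per channel.
#' @param sampling_rate Hz.
#' @param events Optional data frame with columns `onset_sample` (1-based)
#'   and `code` (character or integer annotation text).
#' @param subject_id Patient identification string.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, channel_names, sampling_rate,
                      events = NULL, subject_id = "X") {
  stopifnot(is.matrix(signals), nrow(signals) == length(channel_names))
  C <- nrow(signals); T <- ncol(signals)
  has_ann <- !is.null(events) && nrow(events) > 0
  ns <- C + if (has_ann) 1L else 0L
  dur <- T / sampling_rate

  pmin_ <- apply(signals, 1, min); pmax_ <- apply(signals, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  ann_raw <- raw(0)
  if (has_ann) {
    chunks <- list(c(charToRaw("+0\x14\x14"), as.raw(0)))
    for (i in seq_len(nrow(events))) {
      onset <- (events$onset_sample[i] - 1) / sampling_rate
      tal <- sprintf("+%g\x14%s\x14", onset, as.character(events$code[i]))
      chunks[[i + 1L]] <- c(charToRaw(tal), as.raw(0))
    }
    ann_raw <- do.call(c, chunks)
    if (length(ann_raw) %% 2L == 1L) ann_raw <- c(ann_raw, as.raw(0))
  }
  ann_spr <- length(ann_raw) %/% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8), pad_str(subject_id, 80), pad_str("recording", 80),
    pad_str(format(Sys.Date(), "%d.%m.%y"), 8), pad_str("00.00.00", 8),
    pad_str(as.character(256 * (1 + ns)), 8),
    pad_str(if (has_ann) "EDF+C" else "", 44),
    pad_str("1", 8), pad_str(format(dur, digits = 8), 8),
    pad_str(as.character(ns), 4)
  )
  writeChar(hdr, con, eos = NULL)
  labels <- c(channel_names, if (has_ann) "EDF Annotations")
  fields <- list(
    vapply(labels, pad_str, "", width = 16),
    rep(pad_str("", 80), ns),
    c(rep(pad_str("uV", 8), C), if (has_ann) pad_str("", 8)),
    vapply(c(format(pmin_, digits = 7), if (has_ann) "-1"), pad_str, "", width = 8),
    vapply(c(format(pmax_, digits = 7), if (has_ann) "1"), pad_str, "", width = 8),
    rep(pad_str(as.character(dmin), 8), ns),
    rep(pad_str(as.character(dmax), 8), ns),
    rep(pad_str("", 80), ns),
    vapply(c(rep(as.character(T), C), if (has_ann) as.character(ann_spr)),
           pad_str, "", width = 8),
    rep(pad_str("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (ch in seq_len(C)) {
    dig <- round((signals[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  if (has_ann) writeBin(ann_raw, con)
  invisible(path)
}

#' Read a continuous recording
#'
#' @param path Path to the file.
#' @param format `"edf"` or `"gdf"`; defaults to the file extension.
#' @return A list with `signals` (matrix `n_channels x n_samples`,
#'   physical units) and `meta`: `channel_names`, `sampling_rate`,
#'   `event_table` (tibble `onset_sample`, `code`), `subject_id`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "gdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("edf", "gdf")) {
      stop("cannot infer format from extension '", format, "'", call. = FALSE)
    }
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") read_edf(path) else read_gdf(path)
}

read_edf <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 256) stop("EDF format error at byte ", sz,
                     ": file shorter than the 256-byte header", call. = FALSE)
  hdr <- readBin(con, "raw", 256)
  subject_id <- trimws(rawToChar(hdr[9:88]))
  hbytes <- num_field(hdr[185:192], "header bytes")
  n_rec <- num_field(hdr[237:244], "n_records")
  rec_dur <- num_field(hdr[245:252], "record duration")
  ns <- as.integer(num_field(hdr[253:256], "n_signals"))
  if (sz < hbytes) {
    stop("EDF format error at byte ", sz, ": header claims ", hbytes,
         " bytes", call. = FALSE)
  }
  rd_field <- function(w) {
    vapply(seq_len(ns), function(i) trimws(rawToChar(readBin(con, "raw", w))),
           "")
  }
  labels <- rd_field(16); rd_field(80); rd_field(8)
  pmin_ <- as.numeric(rd_field(8)); pmax_ <- as.numeric(rd_field(8))
  dmin <- as.numeric(rd_field(8)); dmax <- as.numeric(rd_field(8))
  rd_field(80)
  spr <- as.integer(rd_field(8)); rd_field(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr))) {
    stop("EDF format error: non-numeric signal header fields", call. = FALSE)
  }
  rec_bytes <- sum(spr) * 2
  expect <- hbytes + n_rec * rec_bytes
  if (sz < expect) {
    stop("EDF format error at byte ", sz, ": expected ", expect,
         " bytes (", n_rec, " records of ", rec_bytes, ")", call. = FALSE)
  }
  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), ann_idx)
  sig <- lapply(sig_idx, function(i) numeric(0))
  ann_bytes <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_idx) {
        ann_bytes <- c(ann_bytes, readBin(con, "raw", spr[i] * 2))
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        j <- match(i, sig_idx)
        phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
          pmin_[i]
        sig[[j]] <- c(sig[[j]], phys)
      }
    }
  }
  fs_sig <- spr[sig_idx] / rec_dur
  fs <- fs_sig[1]
  events <- parse_tals(ann_bytes, fs)
  if (length(ann_idx) > 0 && nrow(events) == 0) {
    stop("no events: the annotation channel contains no labelled onsets",
         call. = FALSE)
  }
  signals <- do.call(rbind, sig)
  list(signals = signals,
       meta = list(channel_names = labels[sig_idx], sampling_rate = fs,
                   event_table = events, subject_id = subject_id))
}

parse_tals <- function(bytes, fs) {
  bytes[bytes == as.raw(0)] <- as.raw(10)   # NUL terminators -> newline
  tals <- strsplit(rawToChar(bytes), "\n", fixed = TRUE)[[1]]
  onsets <- numeric(0); codes <- character(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1])))
    anns <- parts[-1]
    anns <- anns[nzchar(anns)]
    if (is.na(onset) || length(anns) == 0) next
    onsets <- c(onsets, rep(onset, length(anns)))
    codes <- c(codes, anns)
  }
  ord <- order(onsets)
  tibble::tibble(onset_sample = as.integer(round(onsets[ord] * fs)) + 1L,
                 code = codes[ord])
}

## ---- GDF1-style minimal writer/reader ----

write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")
write_i64 <- function(con, x) {
  lo <- x %% 2^32; hi <- x %/% 2^32
  lo_int <- if (lo >= 2^31) as.integer(lo - 2^32) else as.integer(lo)
  writeBin(lo_int, con, size = 4, endian = "little")
  writeBin(as.integer(hi), con, size = 4, endian = "little")
}
read_i64 <- function(con) {
  lo <- readBin(con, "integer", 1, size = 4, endian = "little")
  hi <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (lo < 0) lo <- lo + 2^32
  hi * 2^32 + lo
}

#' Write a GDF1-style recording
#'
#' Minimal GDF writer (version tag `GDF 1.25`): binary EDF-like channel
#' headers in field-major order, one int16 data record, and a trailing
#' event table (`mode` byte, 24-bit count, float32 sample rate, uint32
#' positions, uint16 types).  Intended for fixtures and interchange with
#' this package's own reader.
#'
#' @inheritParams write_edf
#' @param events Optional data frame with `onset_sample` (1-based) and
#'   integer `code` columns.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(path, signals, channel_names, sampling_rate,
                      events = NULL, subject_id = "X") {
  stopifnot(is.matrix(signals), nrow(signals) == length(channel_names))
  C <- nrow(signals); T <- ncol(signals)
  pmin_ <- apply(signals, 1, min); pmax_ <- apply(signals, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad_str("GDF 1.25", 8), con, eos = NULL)
  writeChar(pad_str(subject_id, 80), con, eos = NULL)
  writeChar(pad_str("recording", 80), con, eos = NULL)
  writeChar(pad_str("2026010100000000", 16), con, eos = NULL)
  write_i64(con, 256 * (1 + C))          # header length
  writeBin(raw(8 * 3 + 20), con)         # equipment/lab/technician/reserved
  write_i64(con, 1)                      # one data record
  write_u32(con, T); write_u32(con, sampling_rate)  # duration = T / fs s
  write_u32(con, C)
  for (nm in channel_names) writeChar(pad_str(nm, 16), con, eos = NULL)
  for (i in seq_len(C)) writeChar(pad_str("", 80), con, eos = NULL)
  for (i in seq_len(C)) writeChar(pad_str("uV", 8), con, eos = NULL)
  writeBin(pmin_, con, size = 8, endian = "little")
  writeBin(pmax_, con, size = 8, endian = "little")
  for (i in seq_len(C)) write_i64(con, dmin)
  for (i in seq_len(C)) write_i64(con, dmax)
  for (i in seq_len(C)) writeChar(pad_str("", 80), con, eos = NULL)
  for (i in seq_len(C)) write_u32(con, T)          # samples per record
  for (i in seq_len(C)) write_u32(con, 3)          # datatype int16
  for (i in seq_len(C)) writeBin(raw(32), con)
  for (ch in seq_len(C)) {
    dig <- round((signals[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  if (!is.null(events) && nrow(events) > 0) {
    writeBin(as.raw(1), con)                       # event mode 1
    nev <- nrow(events)
    writeBin(as.raw(c(nev %% 256, (nev %/% 256) %% 256, nev %/% 65536)), con)
    writeBin(as.numeric(sampling_rate), con, size = 4, endian = "little")
    for (p in events$onset_sample) write_u32(con, p - 1)
    writeBin(as.integer(events$code), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_gdf <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 256) stop("GDF format error at byte ", sz,
                     ": file shorter than the fixed header", call. = FALSE)
  version <- rawToChar(readBin(con, "raw", 8))
  if (!startsWith(version, "GDF")) {
    stop("GDF format error at byte 0: bad version tag '", version, "'",
         call. = FALSE)
  }
  subject_id <- trimws(rawToChar(readBin(con, "raw", 80)))
  readBin(con, "raw", 80 + 16)
  hbytes <- read_i64(con)
  readBin(con, "raw", 8 * 3 + 20)
  n_rec <- read_i64(con)
  dur_num <- readBin(con, "integer", 1, size = 4, endian = "little")
  dur_den <- readBin(con, "integer", 1, size = 4, endian = "little")
  ns <- readBin(con, "integer", 1, size = 4, endian = "little")
  labels <- vapply(seq_len(ns),
                   function(i) trimws(rawToChar(readBin(con, "raw", 16))), "")
  readBin(con, "raw", ns * 80)
  readBin(con, "raw", ns * 8)
  pmin_ <- readBin(con, "numeric", ns, size = 8, endian = "little")
  pmax_ <- readBin(con, "numeric", ns, size = 8, endian = "little")
  dmin <- vapply(seq_len(ns), function(i) read_i64(con), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) read_i64(con), numeric(1))
  readBin(con, "raw", ns * 80)
  spr <- readBin(con, "integer", ns, size = 4, endian = "little")
  dtype <- readBin(con, "integer", ns, size = 4, endian = "little")
  if (any(dtype != 3)) {
    stop("GDF reader supports int16 (datatype 3) samples only", call. = FALSE)
  }
  readBin(con, "raw", ns * 32)
  fs <- spr[1] * dur_den / dur_num
  data_bytes <- n_rec * sum(spr) * 2
  if (sz < hbytes + data_bytes) {
    stop("GDF format error at byte ", sz, ": expected ", hbytes + data_bytes,
         " bytes of header + samples", call. = FALSE)
  }
  sig <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      sig[[i]] <- c(sig[[i]], (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
                      (dmax[i] - dmin[i]) + pmin_[i])
    }
  }
  events <- tibble::tibble(onset_sample = integer(0), code = character(0))
  if (sz > hbytes + data_bytes) {
    readBin(con, "raw", 1)                         # mode byte
    nevb <- as.integer(readBin(con, "raw", 3))
    nev <- nevb[1] + 256 * nevb[2] + 65536 * nevb[3]
    readBin(con, "numeric", 1, size = 4, endian = "little")
    pos <- readBin(con, "integer", nev, size = 4, endian = "little")
    typ <- readBin(con, "integer", nev, size = 2, endian = "little",
                   signed = FALSE)
    events <- tibble::tibble(onset_sample = pos + 1L,
                             code = as.character(typ))
  }
  list(signals = do.call(rbind, sig),
       meta = list(channel_names = labels, sampling_rate = fs,
                   event_table = events, subject_id = subject_id))
}

#' Select and reorder channels
#'
#' @param signals Matrix `n_channels x n_samples`.
#' @param meta Metadata list from [read_recording()].
#' @param names Requested channel names, in the desired order.
#' @return A list with the reduced `signals` and updated `meta`.
#' @export
select_channels <- function(signals, meta, names) {
  idx <- match(names, meta$channel_names)
  if (anyNA(idx)) {
    stop("channel(s) not found: ", paste(names[is.na(idx)], collapse = ", "),
         "; available: ", paste(meta$channel_names, collapse = ", "),
         call. = FALSE)
  }
  meta$channel_names <- meta$channel_names[idx]
  list(signals = signals[idx, , drop = FALSE], meta = meta)
}

#' The 18 motor-cortex channels of the 64-electrode montage
#'
#' The standard selection near the motor cortex: C1-C6, CP1-CP6, P1-P6.
#' @export
physionet_motor_channels <- c(paste0("C", 1:6), paste0("CP", 1:6),
                              paste0("P", 1:6))

#' Load a label-code mapping table
#'
#' The trial-event code to class-label tables ship as CSV data files so
#' dataset-dialect drift can be absorbed without code changes.
#'
#' @param dataset `"bci2a"` (cue codes 769-772: left hand, right hand,
#'   foot, tongue) or `"physionet"` (annotation texts for left fist, right
#'   fist, both fists, feet).
#' @return A tibble with columns `code`, `label`, `description`.
#' @export
load_label_map <- function(dataset = c("bci2a", "physionet")) {
  dataset <- match.arg(dataset)
  f <- system.file("extdata", paste0("event_codes_", dataset, ".csv"),
                   package = "attnmi", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(f, colClasses = c(code = "character")))
}

#' Cut trials out of a continuous recording
#'
#' Pure slicing: one epoch per event whose code appears in `label_map`,
#' over the half-open window `[onset + offset, onset + offset + length)`
#' (0-based sample indexing).  No filtering or re-referencing is applied.
#'
#' @param signals Matrix `n_channels x n_samples`.
#' @param meta Metadata list from [read_recording()].
#' @param epoch_length Epoch length in samples (1125 for a 4.5-s trial at
#'   250 Hz; 640 for a 4-s trial at 160 Hz).
#' @param offset Samples between the event onset and the epoch start.
#' @param label_map Tibble with columns `code`, `label` (see
#'   [load_label_map()]); events with other codes are ignored.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(signals, meta, epoch_length, offset = 0L,
                           label_map = load_label_map("bci2a")) {
  ev <- meta$event_table
  ev <- ev[as.character(ev$code) %in% as.character(label_map$code), ,
           drop = FALSE]
  if (nrow(ev) == 0) stop("no events with mapped codes", call. = FALSE)
  n_samp <- ncol(signals)
  starts <- ev$onset_sample + offset
  ends <- starts + epoch_length - 1L
  bad <- which(starts < 1L | ends > n_samp)
  if (length(bad) > 0) {
    stop("epoch window for event ", bad[1], " (onset sample ",
         ev$onset_sample[bad[1]], ") exceeds the recording bounds",
         call. = FALSE)
  }
  lab <- label_map$label[match(as.character(ev$code),
                               as.character(label_map$code))]
  x <- array(0, c(nrow(ev), nrow(signals), epoch_length))
  for (i in seq_len(nrow(ev))) {
    x[i, , ] <- signals[, starts[i]:ends[i]]
  }
  epoch_set(x, lab, meta$subject_id, meta$sampling_rate)
}
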