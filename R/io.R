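#' Default marker-description map
#'
#' BrainVision stimulus descriptions `"S 1"`..`"S 4"` map onto the four
#' attention states. The map is an argument of the readers so alternative
#' trigger schemes can be plugged in.
#'
#' @return Named character vector, names are marker descriptions.
#' @export
default_marker_map <- function() {
  c("S 1" = "focused", "S 2" = "visual", "S 3" = "auditory",
    "S 4" = "cognitive")
}

state_to_marker <- function(state, marker_map = default_marker_map()) {
  names(marker_map)[match(state, marker_map)]
}

#' Read an EEG recording from disk
#'
#' Supported formats: the package's internal container (a JSON header plus
#' a raw float64 data file), the BrainVision triplet
#' (`.vhdr`/`.vmrk`/`.eeg`) and EDF/EDF+. Event markers come from the
#' `.vmrk` sidecar (BrainVision), the annotation signal (EDF+) or the
#' header (internal).
#'
#' @param path file path: the `.vhdr` file for BrainVision, the `.edf`
#'   file for EDF, the `.eegr` header for the internal format.
#' @param format one of `"auto"`, `"brainvision"`, `"edf"`, `"internal"`.
#'   `"auto"` dispatches on the file extension.
#' @param marker_map named character vector mapping marker descriptions to
#'   state labels (see [default_marker_map()]).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path,
                           format = c("auto", "brainvision", "edf",
                                      "internal"),
                           marker_map = default_marker_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     eegr = "internal",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  switch(format,
         brainvision = read_brainvision(path, marker_map),
         edf = read_edf(path),
         internal = read_internal(path))
}

## ---- internal container ----------------------------------------------

#' Write a recording in the internal container format
#'
#' Writes `<path>` (a JSON header holding fs, channel names and events)
#' and `<path>.dat` (the sample-multiplexed float64 little-endian data).
#' The round trip through [read_recording()] is bit-exact.
#'
#' @param rec an [eeg_recording()].
#' @param path destination header path; conventionally `*.eegr`.
#' @return `path`, invisibly.
#' @export
write_recording_internal <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  header <- list(
    format = "eegdrive-internal-v1",
    fs = rec$fs,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    channel_names = rec$channel_names,
    unit = "uV",
    events = rec$events)
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # column-major vector == sample-multiplexed (all channels of sample 1,
  # then sample 2, ...)
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(path)
}

read_internal <- function(path) {
  header <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(header$format, "eegdrive-internal-v1")) {
    stop("not an internal-format header: ", path)
  }
  datpath <- paste0(path, ".dat")
  if (!file.exists(datpath)) stop("missing data file: ", datpath)
  header$fs <- as.numeric(header$fs)
  n <- header$n_channels * header$n_samples
  con <- file(datpath, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n + 1L, size = 8,
               endian = "little")
  if (length(x) != n) {
    stop("data length ", length(x), " inconsistent with header (",
         header$n_channels, " x ", header$n_samples, ")")
  }
  data <- matrix(x, nrow = header$n_channels)
  events <- header$events
  if (is.null(events) || (is.data.frame(events) && !nrow(events)) ||
      (!is.data.frame(events) && !length(events))) {
    events <- empty_events()
  }
  eeg_recording(data, header$fs, header$channel_names, events)
}

## ---- BrainVision ------------------------------------------------------

#' Write a recording as a BrainVision triplet
#'
#' Produces `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` with multiplexed
#' IEEE float32 samples. Events become Stimulus markers (descriptions via
#' `marker_map`); invalid trials are written with the marker channel field
#' set to -1, which the reader maps back to `valid = FALSE`.
#'
#' @param rec an [eeg_recording()].
#' @param stem path without extension.
#' @param marker_map named map description -> state (inverted for writing).
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, stem,
                              marker_map = default_marker_map()) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)),
            rec$channel_names))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(rec$events)) {
    ev <- rec$events
    desc <- state_to_marker(ev$state, marker_map)
    if (anyNA(desc)) stop("states without a marker description: ",
                          paste(unique(ev$state[is.na(desc)]),
                                collapse = ", "))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,%d,%d",
                        seq_len(nrow(ev)) + 1L,
                        desc,
                        ev$sample_index + 1L,            # 1-based points
                        as.integer(round(ev$duration_s * rec$fs)),
                        ifelse(ev$valid, 0L, -1L)))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_ini_values <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

read_brainvision <- function(vhdr_path, marker_map = default_marker_map()) {
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  vals <- parse_ini_values(lines)
  need <- c("DataFile", "NumberOfChannels", "SamplingInterval",
            "BinaryFormat", "DataOrientation")
  if (!all(need %in% names(vals))) {
    stop("malformed .vhdr, missing keys: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  }
  if (vals[["DataOrientation"]] != "MULTIPLEXED") {
    stop("unsupported DataOrientation: ", vals[["DataOrientation"]])
  }
  n_ch <- as.integer(vals[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(vals[["SamplingInterval"]])
  fmt <- vals[["BinaryFormat"]]
  bytes <- switch(fmt, IEEE_FLOAT_32 = 4L, INT_16 = 2L,
                  stop("unsupported BinaryFormat: ", fmt))
  what <- switch(fmt, IEEE_FLOAT_32 = "double", INT_16 = "integer")

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_idx <- as.integer(sub("^Ch([0-9]+)=.*$", "\\1", ch_lines))
  ch_fields <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_fields, `[`, character(1), 1L)[order(ch_idx)]
  resolution <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r) || r == 0) 1 else r
  }, numeric(1))[order(ch_idx)]
  if (length(ch_names) != n_ch) {
    stop("header inconsistency: NumberOfChannels=", n_ch, " but ",
         length(ch_names), " channel entries")
  }

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, vals[["DataFile"]])
  if (!file.exists(eeg_path)) stop("missing data file: ", eeg_path)
  sz <- file.info(eeg_path)$size
  n_total <- sz %/% (bytes)
  if (n_total %% n_ch != 0) {
    stop("data length not a multiple of channel count (",
         n_total, " values, ", n_ch, " channels)")
  }
  con <- file(eeg_path, "rb")
  x <- readBin(con, what = what, n = n_total, size = bytes,
               endian = "little", signed = TRUE)
  close(con)
  data <- matrix(as.double(x) * resolution, nrow = n_ch)

  events <- empty_events()
  if ("MarkerFile" %in% names(vals)) {
    vmrk_path <- file.path(dir, vals[["MarkerFile"]])
    if (!file.exists(vmrk_path)) stop("missing marker file: ", vmrk_path)
    events <- read_vmrk(vmrk_path, fs, marker_map)
  }
  eeg_recording(data, fs, ch_names, events)
}

read_vmrk <- function(vmrk_path, fs, marker_map = default_marker_map()) {
  lines <- readLines(vmrk_path, warn = FALSE, encoding = "UTF-8")
  mk <- grep("^Mk[0-9]+=", lines, value = TRUE)
  if (!length(mk)) return(empty_events())
  fields <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  out <- lapply(fields, function(f) {
    if (length(f) < 5L || f[1] != "Stimulus") return(NULL)
    desc <- gsub("[[:space:]]+", " ", trimws(f[2]))
    state <- unname(marker_map[desc])
    if (is.na(state)) return(NULL)
    data.frame(sample_index = as.integer(f[3]) - 1L,
               state = state,
               duration_s = as.numeric(f[4]) / fs,
               valid = as.integer(f[5]) >= 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_events() else out
}

## ---- EDF --------------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF+
#'
#' Classic EDF layout (16-bit samples, one-second data records) with an
#' `EDF Annotations` signal carrying the event markers as time-stamped
#' annotation lists. Each channel is scaled to its own physical range, so
#' the round trip is exact to 16-bit quantisation of that range.
#'
#' @param rec an [eeg_recording()]; its duration must be a whole number
#'   of seconds.
#' @param path destination `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$data) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("EDF writer requires a whole number of seconds of data")
  }
  n_rec <- as.integer(round(n_rec))
  n_sig <- nrow(rec$data)

  # physical scaling per channel; ranges are rounded outward to the 2
  # decimals the header stores, and that stored value drives the scaling
  pmin <- floor(apply(rec$data, 1, min) * 100) / 100
  pmax <- ceiling(apply(rec$data, 1, max) * 100) / 100
  flat <- pmax - pmin < 1e-2
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  # annotations: one TAL stream in record 1; every record begins with its
  # own timestamp TAL
  # each time-stamped annotation list (TAL) terminates with \x14\x00;
  # the terminating nul cannot live in an R string, so records are kept
  # as character pieces and nul-joined at write time
  tal_pieces <- lapply(seq_len(n_rec), function(r) {
    sprintf("+%d\x14\x14", r - 1L)
  })
  if (nrow(rec$events)) {
    ev <- rec$events
    txt <- paste0(ev$state, ifelse(ev$valid, "", " invalid"))
    ev_tal <- sprintf("+%.4f\x15%.4f\x14%s\x14",
                      ev$sample_index / fs, ev$duration_s, txt)
    tal_pieces[[1]] <- c(tal_pieces[[1]], ev_tal)
  }
  tal_raw <- lapply(tal_pieces, function(pieces) {
    unlist(lapply(pieces, function(s) c(charToRaw(s), as.raw(0))))
  })
  max_bytes <- max(vapply(tal_raw, length, integer(1)))
  ann_samples <- as.integer(ceiling(max_bytes / 2))  # int16 slots

  header_bytes <- 256L + 256L * (n_sig + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("EDF+C", 44); wr(n_rec, 8); wr("1", 8)
  wr(n_sig + 1L, 4)
  labels <- c(pad_field(rec$channel_names, 16),
              pad_field("EDF Annotations", 16))
  for (l in labels) wr(l, 16)
  for (i in seq_len(n_sig + 1L)) wr("", 80)                # transducer
  for (i in seq_len(n_sig)) wr("uV", 8); wr("", 8)          # phys dim
  for (i in seq_len(n_sig)) wr(sprintf("%.2f", pmin[i]), 8); wr(-1, 8)
  for (i in seq_len(n_sig)) wr(sprintf("%.2f", pmax[i]), 8); wr(1, 8)
  for (i in seq_len(n_sig + 1L)) wr(dmin, 8)
  for (i in seq_len(n_sig + 1L)) wr(dmax, 8)
  for (i in seq_len(n_sig + 1L)) wr("", 80)                 # prefilter
  for (i in seq_len(n_sig)) wr(fs, 8); wr(ann_samples, 8)
  for (i in seq_len(n_sig + 1L)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(n_sig)) {
      dig <- round((rec$data[s, cols] - pmin[s]) * scale[s] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
    buf <- raw(2L * ann_samples)
    buf[seq_along(tal_raw[[r]])] <- tal_raw[[r]]
    writeBin(buf, con)
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(n_sig), function(i) rd(width),
                                character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  # skip any header padding
  seek(con, header_bytes)

  is_ann <- labels == "EDF Annotations"
  fs <- spr[!is_ann][1] / rec_dur
  if (length(unique(spr[!is_ann])) != 1L) {
    stop("mixed per-signal sampling rates are not supported")
  }
  n_data_sig <- sum(!is_ann)
  data <- matrix(0, nrow = n_data_sig, ncol = n_rec * spr[!is_ann][1])
  scale <- (pmax - pmin) / (dmax - dmin)
  ann_bytes <- list()
  for (r in seq_len(n_rec)) {
    row <- 0L
    for (s in seq_len(n_sig)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2,
                      endian = "little", signed = TRUE)
      if (length(vals) != spr[s]) stop("truncated EDF data at record ", r)
      if (is_ann[s]) {
        ann_bytes[[length(ann_bytes) + 1L]] <-
          writeBin(as.integer(vals), raw(), size = 2, endian = "little")
      } else {
        row <- row + 1L
        cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        data[row, cols] <- (vals - dmin[s]) * scale[s] + pmin[s]
      }
    }
  }
  events <- parse_edf_annotations(unlist(ann_bytes), fs)
  eeg_recording(data, fs, labels[!is_ann], events)
}

parse_edf_annotations <- function(bytes, fs) {
  if (!length(bytes)) return(empty_events())
  # TALs are nul-terminated; map nul to newline and split
  bytes[bytes == as.raw(0)] <- as.raw(10)
  tals <- strsplit(rawToChar(bytes), "\n", fixed = TRUE)[[1]]
  out <- lapply(tals, function(tal) {
    if (!nzchar(tal)) return(NULL)
    head <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    onset_dur <- strsplit(head[1], "\x15", fixed = TRUE)[[1]]
    if (length(head) < 2L || length(onset_dur) < 2L) return(NULL)
    txt <- head[2]
    invalid <- grepl(" invalid$", txt)
    state <- sub(" invalid$", "", txt)
    if (!state %in% attention_states()) return(NULL)
    data.frame(sample_index = as.integer(round(as.numeric(onset_dur[1]) * fs)),
               state = state,
               duration_s = as.numeric(onset_dur[2]),
               valid = !invalid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_events() else out[order(out$sample_index), ,
                                            drop = FALSE]
}
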