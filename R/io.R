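# File formats: minimal EDF+ (16-bit) writer/reader, a plain binary matrix
# with a YAML sidecar, and columnar tables for windows, features and
# normalization statistics.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to EDF+
#'
#' Minimal EDF+ (continuous) writer: 16-bit samples, physical dimension uV
#' with a +/-327.68 uV physical range (0.01 uV resolution), one-second data
#' records, and an annotations channel carrying the event intervals as
#' time-stamped annotation lists (onset/duration in seconds, label = event
#' kind). Values outside the physical range are clipped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  stopifnot(fs == round(fs))
  n_ch <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / fs)
  n_pad <- n_rec * fs - ncol(rec$data)
  data <- cbind(rec$data, matrix(0, n_ch, n_pad))
  phys_min <- -327.68; phys_max <- 327.67
  dig <- pmin(pmax(round(data / 0.01), -32768), 32767)

  # Each time-stamped annotation list ends with 0x14 0x00; onset/duration
  # separators are 0x15/0x14 (nul bytes handled at the raw level).
  ann_len <- 120L  # bytes per record for the annotation channel
  anns <- lapply(seq_len(n_rec) - 1L, function(r) {
    raw_tal <- c(charToRaw(sprintf("+%d", r)), as.raw(c(0x14, 0x14, 0x00)))
    ev <- rec$events[rec$events$onset >= r * fs &
                     rec$events$onset < (r + 1) * fs, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      raw_tal <- c(raw_tal,
                   charToRaw(sprintf("+%.4f", ev$onset[i] / fs)),
                   as.raw(0x15),
                   charToRaw(sprintf("%.4f", (ev$offset[i] - ev$onset[i]) / fs)),
                   as.raw(0x14), charToRaw(ev$kind[i]),
                   as.raw(c(0x14, 0x00)))
    }
    if (length(raw_tal) > ann_len) stop("annotation record overflow")
    c(raw_tal, raw(ann_len - length(raw_tal)))
  })

  ns <- n_ch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(edf_pad("0", 8), con, eos = NULL)
  writeChar(edf_pad(sprintf("X X X %s", rec$subject_id), 80), con, eos = NULL)
  writeChar(edf_pad(sprintf("Startdate X X X X label=%d id=%s",
                            rec$label, rec$recording_id), 80), con, eos = NULL)
  writeChar(edf_pad("01.01.00", 8), con, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, eos = NULL)
  writeChar(edf_pad(as.character(256 * (ns + 1)), 8), con, eos = NULL)
  writeChar(edf_pad("EDF+C", 44), con, eos = NULL)
  writeChar(edf_pad(as.character(n_rec), 8), con, eos = NULL)
  writeChar(edf_pad("1", 8), con, eos = NULL)
  writeChar(edf_pad(as.character(ns), 4), con, eos = NULL)
  field <- function(values, width) {
    for (v in values) writeChar(edf_pad(v, width), con, eos = NULL)
  }
  field(c(rec$channel_names, "EDF Annotations"), 16)
  field(rep("", ns), 80)
  field(c(rep("uV", n_ch), ""), 8)
  field(c(rep(format(phys_min), n_ch), "-1"), 8)
  field(c(rep(format(phys_max), n_ch), "1"), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(c(rep(as.character(fs), n_ch), as.character(ann_len / 2)), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(n_ch)) {
      writeBin(as.integer(dig[ch, idx]), con, size = 2, endian = "little")
    }
    writeBin(anns[[r]], con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Parses the header, reconstructs physical values from the per-signal
#' scaling, and converts annotation lists into the event table (onset and
#' duration rounded to samples). Signals named "EDF Annotations" are not
#' returned as channels.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80)                      # patient
  rec_field <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")   # phys dim
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  chunks <- vector("list", ns)
  for (i in seq_len(ns)) chunks[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        chunks[[i]][[r]] <- readBin(con, "raw", n = 2L * spr[i])
      } else {
        chunks[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                                    signed = TRUE, endian = "little")
      }
    }
  }
  fs <- spr[sig_idx[1]] / dur
  data <- do.call(rbind, lapply(sig_idx, function(i) {
    dig <- unlist(chunks[[i]])
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    pmin_[i] + (dig - dmin_[i]) * scale
  }))

  events <- data.frame(onset = integer(0), offset = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
  ann_i <- which(is_ann)
  if (length(ann_i)) {
    bytes <- unlist(lapply(ann_i, function(i) unlist(chunks[[i]])))
    # split the byte stream into TALs at nul bytes, then decode each
    breaks <- which(bytes == as.raw(0))
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks - 1L, length(bytes))
    for (k in seq_along(starts)) {
      if (ends[k] < starts[k]) next
      tal <- rawToChar(bytes[starts[k]:ends[k]])
      m <- regmatches(tal, regexec("^\\+([0-9.]+)\x15([0-9.]+)\x14([^\x14]+)\x14",
                                   tal))[[1]]
      if (length(m) == 4) {
        onset <- as.integer(round(as.numeric(m[2]) * fs))
        offn <- onset + as.integer(round(as.numeric(m[3]) * fs))
        events <- rbind(events, data.frame(onset = onset, offset = offn,
                                           kind = m[4],
                                           stringsAsFactors = FALSE))
      }
    }
    events <- events[order(events$onset), , drop = FALSE]
  }
  label <- 0L
  subj <- "S1"; rid <- basename(path)
  if (grepl("label=", rec_field)) {
    label <- as.integer(sub(".*label=([01]).*", "\\1", rec_field))
  }
  if (grepl("id=", rec_field)) rid <- sub(".*id=(\\S+).*", "\\1", rec_field)
  eeg_recording(data = data, fs = fs, channel_names = labels[sig_idx],
                events = events, subject_id = subj, recording_id = rid,
                label = label)
}

#' Write a recording as a raw matrix plus YAML sidecar
#'
#' The data file holds the channel x sample matrix as little-endian doubles
#' (column-major, i.e. sample-major on disk); the sidecar (`<path>.yaml`)
#' records dimensions, rate, channel names, events and metadata.
#'
#' @param rec An [eeg_recording()].
#' @param path Data file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_matrix_recording <- function(rec, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               fs = rec$fs, channel_names = rec$channel_names,
               subject_id = rec$subject_id, recording_id = rec$recording_id,
               label = rec$label,
               events = lapply(seq_len(nrow(rec$events)), function(i) {
                 as.list(rec$events[i, ])
               }))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_matrix_recording
#' @export
read_matrix_recording <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
                  size = 8, endian = "little")
  close(con)
  events <- if (length(meta$events)) {
    do.call(rbind, lapply(meta$events, as.data.frame))
  } else NULL
  eeg_recording(data = matrix(vals, meta$n_channels, meta$n_samples),
                fs = meta$fs, channel_names = meta$channel_names,
                events = events, subject_id = meta$subject_id,
                recording_id = meta$recording_id, label = meta$label)
}

#' Read a recording from EDF or matrix+sidecar format
#'
#' Dispatches on the file extension: `.edf` via [read_edf()], anything else
#' via [read_matrix_recording()].
#'
#' @param path File path.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_matrix_recording(path)
}

#' Write / read epoch windows as a columnar table
#'
#' One row per (window, channel, sample) is avoided: the table stores one
#' row per window with metadata columns followed by the 11 x 125 samples
#' flattened channel-major. Round-trips exactly through `read_window_table`.
#'
#' @param windows List of [epoch_window()] objects.
#' @param path CSV path.
#' @return `path` invisibly / list of windows.
#' @export
write_window_table <- function(windows, path) {
  meta <- window_meta(windows)
  meta$onset <- vapply(windows, `[[`, 0L, "onset")
  flat <- do.call(rbind, lapply(windows, function(w) as.numeric(t(w$data))))
  ch <- rownames(windows[[1]]$data) %||% canonical_montage()
  colnames(flat) <- paste0(rep(ch, each = ncol(windows[[1]]$data)), "_",
                           rep(seq_len(ncol(windows[[1]]$data)), length(ch)))
  utils::write.csv(cbind(meta, as.data.frame(flat)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "recording_id", "label", "window_index", "onset")
  sample_cols <- setdiff(names(tab), meta_cols)
  ch <- unique(sub("_[0-9]+$", "", sample_cols))
  n_s <- length(sample_cols) / length(ch)
  lapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(as.numeric(tab[i, sample_cols]), nrow = length(ch),
                ncol = n_s, byrow = TRUE)
    rownames(m) <- ch
    epoch_window(m, tab$subject_id[i], tab$recording_id[i], tab$label[i],
                 tab$window_index[i], tab$onset[i])
  })
}

#' Serialize normalization statistics and class weights to text
#'
#' Exact decimal serialization (`format(..., digits = 17)`) so reloading
#' reproduces the statistics bit-for-bit.
#'
#' @param stats A `norm_stats` object from [fit_norm_stats()].
#' @param class_weights Named numeric of length 2.
#' @param path Output path.
#' @return `path` invisibly / a list with `stats` and `class_weights`.
#' @export
write_norm_config <- function(stats, class_weights, path) {
  lines <- c(sprintf("weight %s %s", names(class_weights),
                     format(class_weights, digits = 17)))
  for (rid in names(stats)) {
    st <- stats[[rid]]
    lines <- c(lines,
               sprintf("mean %s %s", rid,
                       paste(format(st$mean, digits = 17), collapse = " ")),
               sprintf("sd %s %s", rid,
                       paste(format(st$sd, digits = 17), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_norm_config
#' @export
read_norm_config <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, " +")
  weights <- c()
  stats <- list()
  for (p in parts) {
    if (p[1] == "weight") {
      weights[p[2]] <- as.numeric(p[3])
    } else {
      rid <- p[2]
      if (is.null(stats[[rid]])) stats[[rid]] <- list()
      stats[[rid]][[p[1]]] <- as.numeric(p[-(1:2)])
    }
  }
  structure(stats, class = "norm_stats") -> st
  list(stats = st, class_weights = weights)
}
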