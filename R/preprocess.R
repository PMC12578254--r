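# Preprocessing chain: montage restriction, zero-phase filtering, resampling
# to the common 125 Hz rate, 1 s epoching, amplitude QC, per-recording
# normalization and class balancing.

#' Restrict a recording to the canonical 11-channel montage
#'
#' Selects (case-insensitively) the 11 common electrodes C3, Cz, C4, FC3,
#' FCz, FC4, CP3, CPz, CP4, F3, F4 and reorders them canonically. No
#' interpolation is performed; a missing electrode is a hard error.
#'
#' @param rec An [eeg_recording()].
#' @return The recording reduced to 11 channels in canonical order.
#' @export
restrict_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  want <- canonical_montage()
  idx <- match(tolower(want), tolower(rec$channel_names))
  if (anyNA(idx)) {
    stop("missing canonical channel(s): ",
         paste(want[is.na(idx)], collapse = ", "))
  }
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- want
  rec
}

# RBJ second-order IIR notch at f0 with quality factor Q, as b/a coefficients.
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering with mirror padding of `pad` samples at both ends.
filtfilt_mirrored <- function(b, a, x, pad) {
  n <- length(x)
  if (pad >= n) {
    warning("signal shorter than requested padding; using full-signal mirror")
    pad <- n - 1L
  }
  left <- rev(x[2:(pad + 1)])
  right <- rev(x[(n - pad):(n - 1)])
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Notch and band-pass filter a recording (zero-phase)
#'
#' Applies a second-order IIR notch (quality factor 30) at the mains
#' frequency, then an 8-50 Hz fourth-order Butterworth band-pass, both
#' forward-backward (`filtfilt`) for zero phase. Signals are mirrored by 3 s
#' at each end before filtering and cropped back afterwards to suppress edge
#' transients.
#'
#' @param rec An [eeg_recording()] at its native rate (> 100 Hz).
#' @param mains Mains frequency, 50 or 60 Hz.
#' @param band Band-pass edges in Hz (default `c(8, 50)`).
#' @return The filtered recording (same shape and rate).
#' @export
filter_signal <- function(rec, mains = 50, band = c(8, 50)) {
  stopifnot(inherits(rec, "eeg_recording"), mains %in% c(50, 60))
  stopifnot(rec$fs > 100, ncol(rec$data) >= rec$fs)
  pad <- round(3 * rec$fs)
  nc <- notch_coefficients(mains, rec$fs)
  bw <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- filtfilt_mirrored(nc$b, nc$a, out[ch, ], pad)
    out[ch, ] <- filtfilt_mirrored(bw$b, bw$a, x, pad)
  }
  rec$data <- out
  rec
}

#' Resample a recording to 125 Hz
#'
#' Polyphase FIR rate conversion with anti-alias low-pass (zero-phase by
#' linear-phase FIR with delay compensation): identity at 125 Hz, 25/32
#' conversion from 160 Hz and decimation by 4 from 500 Hz. Other input rates
#' are accepted with a warning and converted by the reduced rational factor.
#' Event sample indices are rescaled to the new rate.
#'
#' @param rec An [eeg_recording()].
#' @return The recording at 125 Hz with `round(n * 125 / fs_in)` samples.
#' @export
resample_to_125 <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs_in <- rec$fs
  if (fs_in == 125) return(rec)
  if (!fs_in %in% c(160, 500)) {
    warning("input rate ", fs_in, " Hz outside the harmonized set {125,160,500}")
  }
  g <- gcd_int(round(fs_in), 125L)
  p <- 125L %/% g; q <- as.integer(round(fs_in)) %/% g
  n_in <- ncol(rec$data)
  n_out <- round(n_in * 125 / fs_in)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    y <- signal::resample(rec$data[ch, ], p, q)
    out[ch, ] <- y[seq_len(n_out)]
  }
  rec$data <- out
  if (nrow(rec$events)) {
    rec$events$onset <- as.integer(floor(rec$events$onset * 125 / fs_in))
    rec$events$offset <- as.integer(pmin(round(rec$events$offset * 125 / fs_in),
                                         n_out))
  }
  rec$fs <- 125
  rec
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Segment a 125 Hz recording into 1 s epoch windows
#'
#' Tiles each MI event interval from its onset in non-overlapping steps of
#' 125 samples. Trailing partial windows are dropped, windows that would
#' straddle an event boundary are never produced (tiling restarts at every
#' onset and stops at the offset), and baseline intervals yield no windows.
#'
#' @param rec An [eeg_recording()] at 125 Hz.
#' @return List of [epoch_window()] objects (possibly empty).
#' @export
segment_windows <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), rec$fs == 125)
  wl <- 125L
  mi <- rec$events[rec$events$kind == "MI", , drop = FALSE]
  windows <- list()
  widx <- 0L
  if (nrow(mi)) {
    for (iv in seq_len(nrow(mi))) {
      onset <- mi$onset[iv]; offset <- mi$offset[iv]
      n_win <- (offset - onset) %/% wl
      if (n_win < 1) next
      for (w in seq_len(n_win)) {
        a <- onset + (w - 1L) * wl
        windows[[length(windows) + 1L]] <- epoch_window(
          data = rec$data[, (a + 1L):(a + wl), drop = FALSE],
          subject_id = rec$subject_id, recording_id = rec$recording_id,
          label = rec$label, window_index = widx, onset = a)
        widx <- widx + 1L
      }
    }
  }
  windows
}

#' Amplitude quality control
#'
#' Drops every window in which any sample on any channel strictly exceeds
#' 100 uV in magnitude (non-physiological amplitude). Applied to filtered,
#' un-normalized windows; a sample at exactly 100 uV is kept.
#'
#' @param windows List of [epoch_window()] objects in microvolts.
#' @param threshold Magnitude threshold in uV (default 100).
#' @return List with elements `kept` and `dropped`.
#' @export
amplitude_qc <- function(windows, threshold = 100) {
  bad <- vapply(windows, function(w) max(abs(w$data)) > threshold, logical(1))
  list(kept = windows[!bad], dropped = windows[bad])
}

#' Fit per-recording normalization statistics
#'
#' Computes the per-recording, per-channel mean and standard deviation from
#' the supplied (training-split) windows only. Standard deviations are
#' floored at `1e-12` before any division so constant channels normalize to
#' zero rather than NaN.
#'
#' @param training_windows List of [epoch_window()] objects from the training
#'   split.
#' @return An object of class `norm_stats`: per recording a channels x 2
#'   matrix of means and SDs, plus the window count used.
#' @export
fit_norm_stats <- function(training_windows) {
  stopifnot(length(training_windows) > 0)
  recs <- split(training_windows,
                vapply(training_windows, `[[`, "", "recording_id"))
  stats_list <- lapply(recs, function(ws) {
    mat <- do.call(cbind, lapply(ws, `[[`, "data"))   # ch x (125 * n_windows)
    mu <- rowMeans(mat)
    sd <- apply(mat, 1L, stats::sd)
    flo <- sd < 1e-12
    if (any(flo)) {
      warning("channel SD below floor in recording ",
              ws[[1]]$recording_id, "; flooring")
      sd[flo] <- 1e-12
    }
    list(mean = mu, sd = sd, n_windows = length(ws))
  })
  structure(stats_list, class = "norm_stats")
}

#' Apply normalization statistics to windows
#'
#' Z-scores every window with the statistics of its own recording as fitted
#' by [fit_norm_stats()] on the training split, preventing train-test
#' leakage. A recording absent from the statistics falls back to its own
#' windows' statistics with a warning.
#'
#' @param windows List of [epoch_window()] objects.
#' @param stats A `norm_stats` object.
#' @return The windows, z-scored per recording and channel.
#' @export
apply_norm <- function(windows, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  missing_ids <- setdiff(unique(vapply(windows, `[[`, "", "recording_id")),
                         names(stats))
  fallback <- list()
  if (length(missing_ids)) {
    warning("no training windows for recording(s) ",
            paste(missing_ids, collapse = ", "),
            "; falling back to their own window statistics")
    own <- windows[vapply(windows, function(w) w$recording_id %in% missing_ids,
                          logical(1))]
    fallback <- unclass(fit_norm_stats(own))
  }
  lapply(windows, function(w) {
    st <- stats[[w$recording_id]] %||% fallback[[w$recording_id]]
    w$data <- (w$data - st$mean) / st$sd
    w
  })
}

#' Balance window counts across subjects and classes
#'
#' Two-step balancing: (i) within each class, every subject is downsampled
#' (seeded, uniform, without replacement) to that class's minimum per-subject
#' window count; (ii) if the residual class imbalance (count difference over
#' total) is below 5%,
#' inverse-frequency class weights `w_c = N / (2 N_c)` are attached; at 5% or
#' more the larger class is additionally undersampled (per subject,
#' largest-remainder allocation) to exact equality, after which both weights
#' are 1.
#'
#' @param windows List of [epoch_window()] objects (>= 1 per class).
#' @param seed Integer seed for the undersampling draws.
#' @return List with `windows` (the retained windows, original order) and
#'   `class_weights` (named numeric, `healthy` and `impaired`).
#' @export
balance_and_weight <- function(windows, seed = 1L) {
  meta <- window_meta(windows)
  stopifnot(all(0:1 %in% meta$label))
  keep <- logical(length(windows))

  # (i) per-subject equalization within class
  for (cls in 0:1) {
    in_cls <- which(meta$label == cls)
    per_subj <- split(in_cls, meta$subject_id[in_cls])
    m <- min(lengths(per_subj))
    for (s in names(per_subj)) {
      idx <- per_subj[[s]]
      if (length(idx) > m) {
        idx <- with_seed(derive_seed(seed, paste0("eq", cls, s)),
                         sort(sample(idx, m)))
      }
      keep[idx] <- TRUE
    }
  }

  n0 <- sum(keep & meta$label == 0); n1 <- sum(keep & meta$label == 1)
  imbalance <- abs(n0 - n1) / (n0 + n1)
  if (imbalance >= 0.05) {
    big <- if (n0 > n1) 0L else 1L
    target <- min(n0, n1)
    idx_big <- which(keep & meta$label == big)
    per_subj <- split(idx_big, meta$subject_id[idx_big])
    quota <- largest_remainder(lengths(per_subj) * target / length(idx_big),
                               target)
    keep[idx_big] <- FALSE
    for (k in seq_along(per_subj)) {
      idx <- per_subj[[k]]
      take <- quota[k]
      if (take > 0) {
        sel <- with_seed(derive_seed(seed, paste0("cls", big, names(per_subj)[k])),
                         sort(sample(idx, min(take, length(idx)))))
        keep[sel] <- TRUE
      }
    }
    n0 <- sum(keep & meta$label == 0); n1 <- sum(keep & meta$label == 1)
  }

  n_tot <- n0 + n1
  weights <- c(healthy = n_tot / (2 * n0), impaired = n_tot / (2 * n1))
  list(windows = windows[keep], class_weights = weights)
}

# Integer allocation of `total` among cells with real-valued shares,
# largest-remainder rounding, ties broken by cell order.
largest_remainder <- function(shares, total) {
  fl <- floor(shares)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(-(shares - fl), seq_along(shares))
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Full per-recording preprocessing chain
#'
#' Montage restriction, notch + band-pass filtering at the native rate,
#' resampling to 125 Hz and epoching, in the harmonized order.
#'
#' @param rec An [eeg_recording()].
#' @param mains Mains frequency for the notch (50 or 60 Hz).
#' @return List of [epoch_window()] objects.
#' @export
preprocess_recording <- function(rec, mains = 50) {
  rec <- restrict_montage(rec)
  rec <- filter_signal(rec, mains = mains)
  rec <- resample_to_125(rec)
  segment_windows(rec)
}
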