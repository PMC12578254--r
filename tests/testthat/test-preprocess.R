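test_that("montage restriction selects and orders the canonical channels", {
  # 64-channel input containing the 11 canonical ones
  set.seed(1)
  extra <- paste0("X", 1:53)
  names_all <- sample(c(canonical_montage(), extra))
  rec <- eeg_recording(matrix(rnorm(64 * 250), 64, 250), 125, names_all)
  out <- restrict_montage(rec)
  expect_identical(out$channel_names, canonical_montage())
  expect_identical(out$data[1, ], rec$data[which(names_all == "C3"), ])

  # already canonical but shuffled: reordered, data unchanged
  ord <- sample(11)
  rec2 <- eeg_recording(rec$data[which(names_all %in% canonical_montage())[1:11], ][ord, ],
                        125, canonical_montage()[ord])
  out2 <- restrict_montage(rec2)
  expect_identical(out2$data[4, ], rec2$data[which(canonical_montage()[ord] == "FC3"), ])

  # missing FCz is a hard error naming the channel
  rec3 <- eeg_recording(matrix(0, 10, 250), 125,
                        setdiff(canonical_montage(), "FCz"))
  expect_error(restrict_montage(rec3), "FCz")

  # matching is case-insensitive
  rec4 <- eeg_recording(matrix(0, 11, 250), 125, toupper(canonical_montage()))
  expect_identical(restrict_montage(rec4)$channel_names, canonical_montage())
})

test_that("zero-phase filtering notches mains and passes the 8-50 Hz band", {
  n <- 500 * 10
  zero <- eeg_recording(matrix(0, 1, n), 500, "C3")
  expect_equal(filter_signal(zero)$data, zero$data)

  t60 <- sin(2 * pi * 60 * (0:(n - 1)) / 500)
  f60 <- filter_signal(eeg_recording(matrix(t60, 1, n), 500, "C3"), mains = 60)
  atten <- 20 * log10(sqrt(mean(f60$data[1, 500:4500]^2)) / sqrt(0.5))
  expect_lt(atten, -20)

  t20 <- sin(2 * pi * 20 * (0:(n - 1)) / 500)
  rec20 <- eeg_recording(matrix(t20, 1, n), 500, "C3")
  f20 <- filter_signal(rec20, mains = 50)
  gain <- sqrt(mean(f20$data[1, 500:4500]^2)) / sqrt(0.5)
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)
  cc <- stats::ccf(f20$data[1, 500:4500], rec20$data[1, 500:4500],
                   lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # passband idempotence: double filtering changes RMS by < 10%
  ff <- filter_signal(f20, mains = 50)
  expect_lt(abs(sqrt(mean(ff$data[1, 500:4500]^2)) /
                sqrt(mean(f20$data[1, 500:4500]^2)) - 1), 0.1)

  # short signals fall back to full-signal mirror with a warning
  short <- eeg_recording(matrix(rnorm(250), 1, 250), 125, "C3")
  # both filter stages warn about the shortened mirror
  expect_warning(expect_warning(filter_signal(short), "mirror"), "mirror")
})

test_that("resampling reaches 125 Hz with spectra preserved", {
  rec <- make_test_recording(n_sec = 4, fs = 125)
  expect_identical(resample_to_125(rec), rec)

  # 1 s at 500 Hz -> exactly 125 samples
  r500 <- eeg_recording(matrix(rnorm(500), 1, 500), 500, "C3")
  expect_identical(ncol(resample_to_125(r500)$data), 125L)

  # 10 Hz sinusoid at 160 Hz, 2 s -> 250 samples, peak still at 10 Hz
  x <- sin(2 * pi * 10 * (0:319) / 160)
  r160 <- eeg_recording(matrix(x, 1, 320), 160, "C3",
                        events = data.frame(onset = 0L, offset = 320L,
                                            kind = "MI"))
  out <- resample_to_125(r160)
  expect_identical(ncol(out$data), 250L)
  expect_equal(out$fs, 125)
  spec <- Mod(stats::fft(out$data[1, ]))[2:125]
  expect_equal(which.max(spec) * 125 / 250, 10)
  # events rescaled to the new rate
  expect_identical(out$events$offset, 250L)
})

test_that("segmentation tiles MI intervals and drops partials", {
  mk <- function(events, n_sec = 40) {
    eeg_recording(matrix(rnorm(11 * n_sec * 125), 11, n_sec * 125), 125,
                  canonical_montage(), events = events)
  }
  # one MI interval of exactly 120 s -> 120 windows
  w <- segment_windows(mk(data.frame(onset = 0L, offset = 120L * 125L,
                                     kind = "MI"), n_sec = 120))
  expect_length(w, 120)

  # 250-sample MI interval starting at 187 -> windows at 187 and 312
  w2 <- segment_windows(mk(data.frame(onset = 187L, offset = 437L, kind = "MI")))
  expect_identical(vapply(w2, `[[`, 0L, "onset"), c(187L, 312L))

  # 100-sample interval: no window; baseline intervals produce none
  w3 <- segment_windows(mk(data.frame(onset = c(0L, 200L),
                                      offset = c(100L, 1000L),
                                      kind = c("MI", "baseline"))))
  expect_length(w3, 0)
  expect_length(segment_windows(mk(NULL)), 0)

  # conservation: total window samples <= MI samples, no overlaps
  ev <- data.frame(onset = c(13L, 700L, 2000L), offset = c(600L, 1990L, 2100L),
                   kind = "MI")
  w4 <- segment_windows(mk(ev))
  expect_lte(length(w4) * 125, sum(ev$offset - ev$onset))
  onsets <- sort(vapply(w4, `[[`, 0L, "onset"))
  expect_true(all(diff(onsets) >= 125))
})

test_that("amplitude QC applies the strict 100 uV rule", {
  base <- matrix(0, 11, 125)
  w99 <- epoch_window(base + 99, "s", "r", 0L, 0L, 0L)
  w100 <- epoch_window(`[<-`(base, 5, 60, 100), "s", "r", 0L, 1L, 125L)
  w150 <- epoch_window(`[<-`(base, 5, 60, 150), "s", "r", 0L, 2L, 250L)
  wneg <- epoch_window(`[<-`(base, 2, 3, -101), "s", "r", 0L, 3L, 375L)
  qc <- amplitude_qc(list(w99, w100, w150, wneg))
  expect_length(qc$kept, 2)     # 99 and exactly-100 stay
  expect_length(qc$dropped, 2)  # 150 and -101 go
})

test_that("normalization uses training-split statistics only", {
  rec <- make_test_recording(n_sec = 8, seed = 2,
                             events = data.frame(onset = 0L, offset = 1000L,
                                                 kind = "MI"))
  windows <- segment_windows(rec)
  train <- windows[1:6]; test <- windows[7:8]
  st <- fit_norm_stats(train)
  normed_train <- apply_norm(train, st)
  mat <- do.call(cbind, lapply(normed_train, `[[`, "data"))
  expect_lt(max(abs(rowMeans(mat))), 1e-9)
  expect_lt(max(abs(apply(mat, 1, stats::sd) - 1)), 1e-9)

  # test windows are transformed with the training stats, not their own
  normed_test <- apply_norm(test, st)
  own <- apply_norm(test, fit_norm_stats(test))
  expect_false(isTRUE(all.equal(normed_test[[1]]$data, own[[1]]$data)))
  # leakage guard: including test windows in the fit changes the output
  st_leaky <- fit_norm_stats(windows)
  leaky <- apply_norm(train, st_leaky)
  expect_false(identical(normed_train[[1]]$data, leaky[[1]]$data))

  # constant channel: sd floored, output zeros
  wconst <- epoch_window(matrix(5, 11, 125), "s", "rc", 0L, 0L, 0L)
  expect_warning(stc <- fit_norm_stats(list(wconst)), "floor")
  expect_true(all(apply_norm(list(wconst), stc)[[1]]$data == 0))

  # unknown recording falls back to own stats with a warning
  expect_warning(apply_norm(test, fit_norm_stats(train[1:2])), NA)
  other <- epoch_window(matrix(rnorm(11 * 125), 11, 125), "s2", "other", 1L, 0L, 0L)
  expect_warning(apply_norm(list(other), st), "falling back")
})

test_that("balancing equalizes subjects then weights or trims classes", {
  mkw <- function(subject, label, n) {
    lapply(seq_len(n) - 1L, function(i) {
      epoch_window(matrix(0, 1, 1), subject, paste0(subject, "_r"), label,
                   i, i)
    })
  }
  # per-subject equalization: (200, 150, 150) in one class -> 150 each
  w <- c(mkw("a", 0L, 200), mkw("b", 0L, 150), mkw("c", 0L, 150),
         mkw("p", 1L, 160), mkw("q", 1L, 160), mkw("r", 1L, 160))
  bal <- balance_and_weight(w, seed = 4)
  meta <- do.call(rbind, lapply(bal$windows, function(x) {
    data.frame(s = x$subject_id, y = x$label)
  }))
  expect_true(all(table(meta$s) == 150 | table(meta$s) == 160))
  expect_equal(unname(table(meta$s)["a"]), 150)

  # residual imbalance 450 vs 480 is 30/930 < 5%: weights, no trimming
  expect_equal(sum(meta$y == 0), 450)
  expect_equal(sum(meta$y == 1), 480)
  expect_equal(unname(bal$class_weights["healthy"]), 930 / 900)
  expect_equal(unname(bal$class_weights["impaired"]), 930 / 960)

  # a gross imbalance (x3) is trimmed to equality per subject
  wbig <- c(mkw("a", 0L, 300), mkw("b", 0L, 300), mkw("p", 1L, 100),
            mkw("q", 1L, 100))
  balbig <- balance_and_weight(wbig, seed = 2)
  mbig <- vapply(balbig$windows, `[[`, 0L, "label")
  expect_equal(sum(mbig == 0), sum(mbig == 1))
  expect_equal(unname(balbig$class_weights), c(1, 1))

  # small residual imbalance (< 5%): weights by the inverse-frequency formula
  w2 <- c(mkw("a", 0L, 55), mkw("p", 1L, 50))
  bal2 <- balance_and_weight(w2, seed = 4)
  expect_equal(unname(bal2$class_weights["impaired"]), 105 / 100)
  expect_equal(unname(bal2$class_weights["healthy"]), 105 / 110)
  expect_length(bal2$windows, 105)

  # exactly balanced input: both weights 1
  w3 <- c(mkw("a", 0L, 50), mkw("p", 1L, 50))
  expect_equal(unname(balance_and_weight(w3, seed = 1)$class_weights), c(1, 1))

  # determinism
  expect_identical(balance_and_weight(w, seed = 4)$windows, bal$windows)
})

test_that("artifact injection is removed by QC at about the configured rate", {
  fr <- vapply(1:10, function(s) {
    spec <- synthetic_spec(n_subjects_per_class = 2, run_length = 120,
                           n_runs = 1, fs = 125, artifact_rate = 0.1, seed = s)
    recs <- gen_two_class_recordings(spec)
    w <- unlist(lapply(recs, preprocess_recording), recursive = FALSE)
    qc <- amplitude_qc(w)
    length(qc$dropped) / (length(qc$kept) + length(qc$dropped))
  }, 0)
  expect_lt(abs(mean(fr) - 0.1), 0.03)
})
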