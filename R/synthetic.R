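#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary Gaussian series with the exact autocovariance of
#' fractional Gaussian noise, `gamma(k) = 0.5 * (|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})` (unit variance), using the Davies-Harte circulant embedding.
#' Should the embedding produce (numerically) negative eigenvalues they are
#' clamped to zero, which is deterministic and leaves the target covariance
#' intact to floating-point accuracy for all H in (0,1) at the lengths used
#' here.
#'
#' @param H Hurst parameter, strictly inside (0, 1). `H = 0.5` gives white
#'   Gaussian noise; larger H gives long-range dependence.
#' @param n Number of samples (>= 16).
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @return Numeric vector of length `n` with (population) unit variance.
#' @export
gen_fgn <- function(H, n, seed = 1L) {
  if (!(H > 0 && H < 1)) stop("H must lie strictly inside (0, 1)")
  stopifnot(n >= 16)
  # embed in a power-of-two circulant (>= 2(n-1)) so the FFT size has no
  # large prime factors; the autocovariance extends naturally to any lag
  m <- stats::nextn(2L * (n - 1L), 2)
  k <- 0:(m / 2)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g, g[(m / 2):2])              # first row of the circulant
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0                 # deterministic fallback
  half <- m / 2L
  with_seed(seed, {
    w <- complex(length.out = m)
    w[1] <- sqrt(lambda[1] / m) * stats::rnorm(1)
    w[half + 1] <- sqrt(lambda[half + 1] / m) * stats::rnorm(1)
    j <- seq_len(half - 1)
    u <- stats::rnorm(half - 1)
    v <- stats::rnorm(half - 1)
    w[j + 1] <- sqrt(lambda[j + 1] / (2 * m)) * complex(real = u, imaginary = v)
    w[m - j + 1] <- Conj(w[j + 1])
    x <- Re(stats::fft(w))
    x[seq_len(n)]
  })
}

#' 1/f (pink) background noise
#'
#' Spectral synthesis: white Gaussian spectrum shaped by `f^{-1/2}` in
#' amplitude (power spectral density proportional to 1/f), inverse
#' transformed and standardized to unit variance. Used as the broadband
#' background of the synthetic EEG generator; its detrended-fluctuation
#' exponent is 1 by construction.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, zero mean, unit variance.
#' @export
gen_pink_noise <- function(n, seed = 1L) {
  stopifnot(n >= 16)
  with_seed(seed, {
    nf <- floor(n / 2)
    f <- seq_len(nf)
    amp <- 1 / sqrt(f)
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(length.out = n)
    spec[2:(nf + 1)] <- amp * exp(1i * phase)
    if (n %% 2 == 0) spec[nf + 1] <- Re(spec[nf + 1])
    spec[n:(n - nf + 2)] <- Conj(spec[2:nf])
    x <- Re(stats::fft(spec, inverse = TRUE))
    as.numeric(scale(x))
  })
}

#' Logistic-map trajectory
#'
#' Iterates `x_{t+1} = r x_t (1 - x_t)` and discards a burn-in. The map at
#' `r = 4` is fully chaotic with largest Lyapunov exponent `ln 2` per step,
#' which makes it the reference process for the Lyapunov and
#' correlation-dimension estimators.
#'
#' @param r Map parameter in (0, 4].
#' @param n Number of samples returned (after burn-in).
#' @param x0 Initial condition in (0, 1); if `NULL`, drawn uniformly using
#'   `seed`.
#' @param burn_in Iterations discarded before recording.
#' @param seed Seed used only when `x0` is `NULL`.
#' @return Numeric vector of length `n`.
#' @export
gen_logistic_map <- function(r, n, x0 = NULL, burn_in = 100L, seed = 1L) {
  stopifnot(r > 0, r <= 4, n >= 1)
  if (is.null(x0)) x0 <- with_seed(seed, stats::runif(1, 0.05, 0.95))
  if (!(x0 > 0 && x0 < 1)) stop("x0 must lie strictly inside (0, 1)")
  total <- n + burn_in
  x <- numeric(total)
  x[1] <- x0
  for (t in seq_len(total - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x[(burn_in + 1):total]
}

#' Specification for the two-class synthetic EEG cohort
#'
#' Describes a synthetic cohort of healthy (class 0) and impaired (class 1)
#' subjects. Signals are a sum of band-limited alpha/beta/gamma oscillations
#' with random phases, a 1/f background and a fractional-Gaussian-noise
#' component, so every downstream descriptor has a controllable ground truth.
#' Class 1 receives configurable per-band log-power shifts and a Hurst shift.
#'
#' `fs`, `run_length` and `n_runs` may be length-2 vectors giving per-class
#' values `(class 0, class 1)`, mirroring cohorts whose acquisition setups
#' differ; scalars apply to both classes.
#'
#' @param n_subjects_per_class Subjects per class (default 7).
#' @param n_channels Number of channels; 11 unless `allow_nonstandard`.
#' @param fs Sampling rate(s) in Hz, drawn from 125/160/500.
#' @param run_length Run length(s) in seconds.
#' @param n_runs Runs per subject.
#' @param class_effect Named list with per-band log-power shifts applied to
#'   class 1 (`alpha`, `beta`, `gamma`, natural-log units) and `hurst`, the
#'   additive shift of the fGn Hurst parameter.
#' @param artifact_rate Fraction of 1 s MI window slots receiving a 150 uV
#'   single-channel in-band burst (`0 <= rate < 1`), so the amplitude QC rule
#'   fires even after band-pass filtering.
#' @param mi_block,rest_block Alternating event-block durations in seconds;
#'   `rest_block = 0` marks the whole run as one MI interval.
#' @param base_hurst Hurst parameter of the class-0 fGn component.
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @param allow_nonstandard Permit `n_channels != 11` (testing only).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_class = 7L, n_channels = 11L,
                           fs = 125, run_length = 60, n_runs = 2L,
                           class_effect = list(alpha = -0.4, beta = 0.2,
                                               gamma = 0.6, hurst = 0.15),
                           artifact_rate = 0, mi_block = 4, rest_block = 2,
                           base_hurst = 0.6, seed = 1L,
                           allow_nonstandard = FALSE) {
  stopifnot(all(fs %in% c(125, 160, 500)), all(run_length > 0),
            artifact_rate >= 0, artifact_rate < 1)
  if (n_channels != 11L && !allow_nonstandard) {
    stop("n_channels must be 11 unless allow_nonstandard = TRUE")
  }
  two <- function(v) if (length(v) == 1L) rep(v, 2L) else v[1:2]
  ce <- utils::modifyList(list(alpha = 0, beta = 0, gamma = 0, hurst = 0),
                          as.list(class_effect))
  structure(
    list(n_subjects_per_class = as.integer(n_subjects_per_class),
         n_channels = as.integer(n_channels),
         fs = two(fs), run_length = two(run_length),
         n_runs = two(as.integer(n_runs)),
         class_effect = ce, artifact_rate = artifact_rate,
         mi_block = mi_block, rest_block = rest_block,
         base_hurst = base_hurst, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# One synthetic multichannel run. Amplitudes in microvolts; the rhythm
# amplitudes put typical peak values well inside the +/-100 uV QC bound.
synthesize_run <- function(spec, class_label, fs, n_samples, seed) {
  n_ch <- spec$n_channels
  ce <- spec$class_effect
  shift <- if (class_label == 1L) ce else list(alpha = 0, beta = 0, gamma = 0, hurst = 0)
  H <- spec$base_hurst + shift$hurst
  H <- min(max(H, 0.05), 0.95)
  bands <- list(alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 50))
  base_amp <- c(alpha = 4, beta = 2.5, gamma = 1.5)   # uV per component
  t <- (0:(n_samples - 1)) / fs
  data <- matrix(0, n_ch, n_samples)
  for (ch in seq_len(n_ch)) {
    x <- numeric(n_samples)
    ch_seed <- derive_seed(seed, paste0("ch", ch))
    osc <- with_seed(ch_seed, {
      out <- numeric(n_samples)
      for (b in names(bands)) {
        amp <- base_amp[[b]] * exp(shift[[b]] / 2)
        for (rep_i in 1:3) {                 # 3 sinusoids per band
          f0 <- stats::runif(1, bands[[b]][1], bands[[b]][2])
          ph <- stats::runif(1, 0, 2 * pi)
          out <- out + (amp / sqrt(3)) * sin(2 * pi * f0 * t + ph)
        }
      }
      out
    })
    pink <- 3 * gen_pink_noise(n_samples, seed = derive_seed(ch_seed, "pink"))
    frac <- 2 * gen_fgn(H, n_samples, seed = derive_seed(ch_seed, "fgn"))
    data[ch, ] <- osc + pink + frac
  }
  data
}

# Alternating MI/rest event table for one run (sample units, half-open).
mi_event_table <- function(n_samples, fs, mi_block, rest_block) {
  if (rest_block <= 0) {
    return(data.frame(onset = 0L, offset = n_samples, kind = "MI",
                      stringsAsFactors = FALSE))
  }
  mi_n <- round(mi_block * fs); rest_n <- round(rest_block * fs)
  onsets <- integer(0); offsets <- integer(0); kinds <- character(0)
  pos <- 0L
  while (pos < n_samples) {
    mi_end <- min(pos + mi_n, n_samples)
    if (mi_end > pos) {
      onsets <- c(onsets, pos); offsets <- c(offsets, mi_end)
      kinds <- c(kinds, "MI")
    }
    pos <- mi_end
    rest_end <- min(pos + rest_n, n_samples)
    if (rest_end > pos) {
      onsets <- c(onsets, pos); offsets <- c(offsets, rest_end)
      kinds <- c(kinds, "baseline")
    }
    pos <- rest_end
  }
  data.frame(onset = onsets, offset = offsets, kind = kinds,
             stringsAsFactors = FALSE)
}

#' Generate the two-class synthetic cohort
#'
#' Produces one [eeg_recording()] per subject and run according to a
#' [synthetic_spec()]. Class-1 recordings carry the configured band-power and
#' Hurst shifts; a fraction `artifact_rate` of 1 s slots receives a 150 uV
#' square pulse on one channel so the amplitude QC rule has unambiguous
#' targets. Identical specs (including the seed) give bit-identical cohorts.
#'
#' @param spec A [synthetic_spec()].
#' @return List of `eeg_recording` objects.
#' @export
gen_two_class_recordings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  recs <- list()
  montage <- if (spec$n_channels == 11L) canonical_montage() else
    paste0("CH", seq_len(spec$n_channels))
  for (cls in 0:1) {
    fs <- spec$fs[cls + 1]
    run_len <- spec$run_length[cls + 1]
    n_runs <- spec$n_runs[cls + 1]
    n_samples <- round(run_len * fs)
    for (subj in seq_len(spec$n_subjects_per_class)) {
      subject_id <- sprintf("%s%02d", if (cls == 0) "H" else "P", subj)
      for (run in seq_len(n_runs)) {
        run_seed <- derive_seed(spec$seed,
                                sprintf("c%ds%dr%d", cls, subj, run))
        data <- synthesize_run(spec, cls, fs, n_samples, run_seed)
        events <- mi_event_table(n_samples, fs, spec$mi_block, spec$rest_block)
        if (spec$artifact_rate > 0) {
          # artifacts target the 1 s tiles the segmenter will produce (MI
          # intervals only) as single-channel 150 uV in-band (25 Hz) bursts
          # of 0.2 s, so the amplitude rule still fires after band-passing
          data <- with_seed(derive_seed(run_seed, "artifact"), {
            mi <- events[events$kind == "MI", , drop = FALSE]
            burst_n <- round(0.2 * fs)
            burst <- 150 * sin(2 * pi * 25 * (0:(burst_n - 1)) / fs)
            for (iv in seq_len(nrow(mi))) {
              n_slots <- (mi$offset[iv] - mi$onset[iv]) %/% fs
              if (n_slots < 1) next
              hit <- stats::runif(n_slots) < spec$artifact_rate
              for (slot in which(hit)) {
                ch <- sample.int(nrow(data), 1)
                a0 <- mi$onset[iv] + (slot - 1L) * fs + round(0.4 * fs) + 1L
                idx <- a0:(a0 + burst_n - 1L)
                data[ch, idx] <- data[ch, idx] + burst
              }
            }
            data
          })
        }
        recs[[length(recs) + 1L]] <- eeg_recording(
          data = data, fs = fs, channel_names = montage, events = events,
          subject_id = subject_id,
          recording_id = sprintf("%s_run%02d", subject_id, run),
          label = cls)
      }
    }
  }
  recs
}

#' Synthetic two-class feature vectors
#'
#' Draws feature vectors directly in feature space: class 0 is standard
#' Gaussian in `d` dimensions; class 1 is shifted by `shift` along every
#' coordinate (sign-alternating so the shift is not a pure mean offset of the
#' pooled data). Used to probe the CVAE in isolation from the signal chain.
#' `shift = 0` gives identically distributed classes.
#'
#' @param n Total number of windows (split evenly between classes).
#' @param d Feature dimension (default 88).
#' @param shift Per-dimension mean shift for class 1, in SD units.
#' @param seed Integer seed.
#' @return List with matrix `x` (`n x d`), integer vector `y`, and the shift
#'   vector `mu_shift` actually applied.
#' @export
gen_two_class_features <- function(n, d = 88L, shift = 2, seed = 1L) {
  stopifnot(n >= 2)
  n0 <- floor(n / 2); n1 <- n - n0
  mu_shift <- shift * rep_len(c(1, -1), d)
  with_seed(seed, {
    x0 <- matrix(stats::rnorm(n0 * d), n0, d)
    x1 <- matrix(stats::rnorm(n1 * d), n1, d)
    x1 <- sweep(x1, 2L, mu_shift, `+`)
    x <- rbind(x0, x1)
    y <- c(rep(0L, n0), rep(1L, n1))
    perm <- sample.int(n)
    list(x = x[perm, , drop = FALSE], y = y[perm], mu_shift = mu_shift)
  })
}
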