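# Six-descriptor feature bank: STFT band log-power, rescaled-range Hurst,
# DFA, permutation entropy, Grassberger-Procaccia correlation dimension and
# Rosenstein largest Lyapunov exponent, computed per channel per 1 s window.

#' Feature-bank configuration
#'
#' All estimator parameters, fixed a priori. Defaults: Hann STFT with
#' `N_w = 64`, hop 16, `N_fft = 128`, stabilizer `eps = 1e-8` and bands
#' alpha `[8,13)`, beta `[13,30)`, gamma `[30,50]` Hz; rescaled-range and
#' DFA scales `{8,16,32,64,125}`; permutation entropy `(m,tau) = (3,1)`;
#' state-space embedding `(m,tau) = (6,1)` with Theiler window `W = m*tau =
#' 6`; Lyapunov fit window `t in [3,25]` samples; 20 log-spaced
#' correlation-sum radii between the 5th and 95th distance percentiles with a
#' minimum scaling span of 5 radii.
#'
#' @param fs Sampling rate the windows are expressed at (Hz).
#' @param stft_nw,stft_hop,stft_nfft,stft_eps STFT parameters.
#' @param bands Named list of band edges in Hz.
#' @param scales Scales for the Hurst and DFA fits.
#' @param pe_m,pe_tau Ordinal-pattern embedding.
#' @param embed_m,embed_tau,theiler State-space embedding and Theiler window.
#' @param lle_t1,lle_t2 Divergence-fit window (samples).
#' @param cd_n_radii,cd_prc,cd_min_span Correlation-dimension radius grid.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(fs = 125,
                           stft_nw = 64L, stft_hop = 16L, stft_nfft = 128L,
                           stft_eps = 1e-8,
                           bands = list(alpha = c(8, 13), beta = c(13, 30),
                                        gamma = c(30, 50)),
                           scales = c(8L, 16L, 32L, 64L, 125L),
                           pe_m = 3L, pe_tau = 1L,
                           embed_m = 6L, embed_tau = 1L,
                           theiler = embed_m * embed_tau,
                           lle_t1 = 3L, lle_t2 = 25L,
                           cd_n_radii = 20L, cd_prc = c(0.05, 0.95),
                           cd_min_span = 5L) {
  structure(as.list(environment()), class = "feature_config")
}

#' Names of the per-channel feature scalars, in assembly order
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  c("bp_alpha", "bp_beta", "bp_gamma", "hurst", "dfa", "kolmen", "cd", "lle")
}

#' STFT band log-power
#'
#' Magnitude STFT with a Hann taper of length `N_w` at 75% overlap, frames
#' placed at offsets `0, h, 2h, ...` so a 125-sample window yields exactly
#' `M = floor((125-64)/16) + 1 = 4` complete frames; incomplete frames are
#' not taken. Per band B the feature is
#' `BP_B = (1/M) * sum_m sum_{k in B} log(|X(k,m)|^2 + eps)` with natural
#' logs, bin frequencies `f_k = k * fs / N_fft`, half-open alpha/beta bands
#' and a closed upper gamma edge.
#'
#' @param x Numeric vector (one channel of one window).
#' @param cfg A [feature_config()].
#' @return Named numeric: `bp_alpha`, `bp_beta`, `bp_gamma`.
#' @export
stft_band_power <- function(x, cfg = feature_config()) {
  n <- length(x)
  nw <- cfg$stft_nw; hop <- cfg$stft_hop; nfft <- cfg$stft_nfft
  stopifnot(n >= nw)
  m_frames <- (n - nw) %/% hop + 1L
  taper <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / nw))   # periodic Hann
  fk <- (0:(nfft / 2)) * cfg$fs / nfft
  bins <- lapply(names(cfg$bands), function(b) {
    e <- cfg$bands[[b]]
    if (b == "gamma") which(fk >= e[1] & fk <= e[2]) else
      which(fk >= e[1] & fk < e[2])
  })
  names(bins) <- names(cfg$bands)
  acc <- c(0, 0, 0)
  for (m in seq_len(m_frames)) {
    seg <- x[((m - 1L) * hop + 1L):((m - 1L) * hop + nw)] * taper
    spec <- stats::fft(c(seg, rep(0, nfft - nw)))
    p <- Mod(spec[seq_len(nfft / 2 + 1)])^2
    acc <- acc + vapply(bins, function(k) sum(log(p[k] + cfg$stft_eps)), 0)
  }
  out <- acc / m_frames
  names(out) <- paste0("bp_", names(cfg$bands))
  out
}

# Dominant-rhythm frequency: periodogram maximum (DC excluded).
dominant_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- seq.int(2L, floor(n / 2) + 1L)
  ((which.max(p[half])) ) * fs / n
}

#' Rescaled-range Hurst exponent
#'
#' Classical R/S statistic on segments of each scale at 50% overlap (stride
#' `s/2`, trailing partial segments discarded). Each segment is demeaned; the
#' range of its cumulative deviates divided by its standard deviation
#' (computed with denominator `s - 1`) gives R/S, averaged per scale. The
#' exponent is the OLS slope of `log mean(R/S)` on `log s`. A scale shorter
#' than two cycles of the window's dominant rhythm (periodogram maximum) is
#' omitted; constant segments are skipped. Fewer than two usable scales flag
#' the estimate degenerate with the neutral value 0.5.
#'
#' @param x Numeric vector.
#' @param cfg A [feature_config()].
#' @return Numeric with attribute `degenerate` (logical).
#' @export
hurst_rs <- function(x, cfg = feature_config()) {
  n <- length(x)
  f_dom <- dominant_frequency(x, cfg$fs)
  min_scale <- 2 * cfg$fs / max(f_dom, 1e-12)
  shortest <- min(cfg$scales)
  log_s <- numeric(0); log_rs <- numeric(0)
  for (s in cfg$scales) {
    if (s > n) next
    # only the shortest scale is subject to the two-cycle omission rule
    if (s == shortest && s < min_scale) next
    stride <- max(1L, s %/% 2L)
    starts <- seq.int(1L, n - s + 1L, by = stride)
    rs <- numeric(0)
    for (a in starts) {
      seg <- x[a:(a + s - 1L)]
      seg <- seg - mean(seg)
      S <- sqrt(sum(seg^2) / (s - 1))
      if (S <= 0) next
      Y <- cumsum(seg)
      rs <- c(rs, (max(Y) - min(Y)) / S)
    }
    if (length(rs)) {
      log_s <- c(log_s, log(s)); log_rs <- c(log_rs, log(mean(rs)))
    }
  }
  if (length(log_s) < 2) {
    return(structure(0.5, degenerate = TRUE))
  }
  structure(ols_slope(log_s, log_rs), degenerate = FALSE)
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the demeaned series into the profile `Y`, partitions it into
#' `floor(N/s)` non-overlapping forward segments per scale, removes a
#' least-squares linear trend within each segment, and computes the RMS
#' fluctuation `F(s)` over the covered samples. The exponent is the OLS
#' slope of `log F(s)` on `log s` over scales with `F(s) > 0`. A constant
#' signal has an identically zero profile, hence `F(s) = 0` at every scale,
#' and is flagged degenerate (value 0.5).
#'
#' @param x Numeric vector.
#' @param cfg A [feature_config()].
#' @return Numeric with attribute `degenerate`.
#' @export
dfa <- function(x, cfg = feature_config()) {
  n <- length(x)
  Y <- cumsum(x - mean(x))
  log_s <- numeric(0); log_f <- numeric(0)
  for (s in cfg$scales) {
    ns <- n %/% s
    if (ns < 1) next
    ss <- 0
    t <- seq_len(s)
    st <- sum(t); stt <- sum(t^2)
    det <- s * stt - st^2
    for (seg_i in seq_len(ns)) {
      yk <- Y[((seg_i - 1L) * s + 1L):(seg_i * s)]
      sy <- sum(yk); sty <- sum(t * yk)
      b1 <- (s * sty - st * sy) / det
      b0 <- (sy - b1 * st) / s
      res <- yk - (b0 + b1 * t)
      ss <- ss + sum(res^2)
    }
    f <- sqrt(ss / (ns * s))     # averaged over covered samples only
    if (f > 0) {
      log_s <- c(log_s, log(s)); log_f <- c(log_f, log(f))
    }
  }
  if (length(log_s) < 2) {
    return(structure(0.5, degenerate = TRUE))
  }
  structure(ols_slope(log_s, log_f), degenerate = FALSE)
}

#' Permutation (ordinal) entropy
#'
#' Shannon entropy of ordinal patterns of embedding dimension `m = 3`, delay
#' `tau = 1` (123 triples in a 125-sample window), natural log, without
#' normalization by `log m!`. Ties are broken stably: the earlier index
#' receives the lower rank.
#'
#' @param x Numeric vector of length >= `m`.
#' @param cfg A [feature_config()].
#' @return Numeric (nats); attribute `degenerate` is always `FALSE`.
#' @export
perm_entropy <- function(x, cfg = feature_config()) {
  m <- cfg$pe_m; tau <- cfg$pe_tau
  n <- length(x)
  n_pat <- n - (m - 1L) * tau
  stopifnot(n_pat >= 1)
  codes <- integer(n_pat)
  for (i in seq_len(n_pat)) {
    v <- x[i + (0:(m - 1L)) * tau]
    r <- order(v)                       # stable: earlier index ranks lower
    codes[i] <- sum(r * m^(seq_len(m) - 1L))
  }
  p <- tabulate(match(codes, unique(codes)))
  p <- p / sum(p)
  structure(-sum(p * log(p)), degenerate = FALSE)
}

# Delay embedding: rows are the K = n - (m-1) tau embedded points.
delay_embed <- function(x, m, tau) {
  n <- length(x)
  K <- n - (m - 1L) * tau
  stopifnot(K >= 2)
  idx <- outer(seq_len(K), (0:(m - 1L)) * tau, `+`)
  matrix(x[idx], nrow = K)
}

#' Grassberger-Procaccia correlation dimension
#'
#' Delay embedding `(m,tau) = (6,1)`; the correlation sum counts pairs with
#' temporal separation beyond the Theiler window `W = 6` whose Euclidean
#' distance falls below `r` (strict). Radii are 20 log-spaced values between
#' the 5th and 95th percentiles of the Theiler-excluded pairwise distances;
#' radii with an empty correlation sum are dropped. Local scaling is probed
#' by OLS on every contiguous span of at least 5 radii in `(log r, log C)`;
#' the estimate is the slope of the span with maximal R^2 (ties favour the
#' longest span). Constant signals are flagged degenerate (value 0).
#'
#' @param x Numeric vector (any length compatible with the embedding).
#' @param cfg A [feature_config()].
#' @return Numeric with attribute `degenerate`.
#' @export
correlation_dimension <- function(x, cfg = feature_config()) {
  emb <- delay_embed(x, cfg$embed_m, cfg$embed_tau)
  K <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  sep <- abs(outer(seq_len(K), seq_len(K), `-`))
  valid <- sep > cfg$theiler & upper.tri(d)
  dv <- d[valid]
  if (!length(dv) || max(dv) <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  qs <- stats::quantile(dv, cfg$cd_prc, names = FALSE)
  if (qs[1] <= 0) qs[1] <- min(dv[dv > 0])
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = cfg$cd_n_radii))
  C <- vapply(radii, function(r) mean(dv < r), 0)
  ok <- C > 0
  lr <- log(radii[ok]); lc <- log(C[ok])
  nr <- length(lr)
  if (nr < cfg$cd_min_span) {
    return(structure(0, degenerate = TRUE))
  }
  best <- NULL
  for (a in seq_len(nr - cfg$cd_min_span + 1L)) {
    for (b in seq.int(a + cfg$cd_min_span - 1L, nr)) {
      fit <- ols_fit(lr[a:b], lc[a:b])
      len <- b - a + 1L
      if (is.null(best) || fit$r2 > best$r2 + 1e-12 ||
          (abs(fit$r2 - best$r2) <= 1e-12 && len > best$len)) {
        best <- list(slope = fit$slope, r2 = fit$r2, len = len)
      }
    }
  }
  structure(best$slope, degenerate = FALSE)
}

#' Largest Lyapunov exponent (Rosenstein's method)
#'
#' With the `(6,1)` embedding, each point's nearest neighbour at temporal
#' separation beyond the Theiler window is tracked for `t2` steps; points
#' whose divergence horizon would run past the series are dropped. The mean
#' log-divergence curve `dbar(t)` (distances floored at `1e-12`) is fitted by
#' OLS on `t in [t1, t2]`; the slope is the exponent in units of 1/sample.
#'
#' @param x Numeric vector.
#' @param cfg A [feature_config()]; `lle_t1`/`lle_t2` set the fit window.
#' @return Numeric with attribute `degenerate`.
#' @export
lyapunov_rosenstein <- function(x, cfg = feature_config()) {
  emb <- delay_embed(x, cfg$embed_m, cfg$embed_tau)
  K <- nrow(emb)
  t2 <- cfg$lle_t2
  i_max <- K - t2
  if (i_max < 1) return(structure(0, degenerate = TRUE))
  d <- as.matrix(stats::dist(emb))
  sep <- abs(outer(seq_len(K), seq_len(K), `-`))
  d[sep <= cfg$theiler] <- Inf
  # nearest neighbours among points that can also be tracked for t2 steps
  cand <- d[seq_len(i_max), seq_len(i_max), drop = FALSE]
  nn <- apply(cand, 1L, which.min)
  keep <- is.finite(cand[cbind(seq_len(i_max), nn)])
  if (!any(keep)) return(structure(0, degenerate = TRUE))
  ii <- which(keep); jj <- nn[keep]
  ts <- 0:t2
  dbar <- vapply(ts, function(t) {
    dt <- sqrt(rowSums((emb[ii + t, , drop = FALSE] -
                        emb[jj + t, , drop = FALSE])^2))
    mean(log(pmax(dt, 1e-12)))
  }, 0)
  fit_idx <- which(ts >= cfg$lle_t1 & ts <= cfg$lle_t2)
  structure(ols_slope(ts[fit_idx], dbar[fit_idx]), degenerate = FALSE)
}

#' Assemble the per-window feature vector
#'
#' Computes the configured descriptor subset for every channel of a 1 s
#' window and concatenates channel-major: per channel the order is
#' `(bp_alpha, bp_beta, bp_gamma, hurst, dfa, kolmen, cd, lle)`; the full
#' bank over the 11-channel montage yields 88 values. Degenerate-input
#' substitutions are reported via the `degenerate` attribute (named logical).
#'
#' @param window An [epoch_window()] (z-scored).
#' @param cfg A [feature_config()].
#' @param subset Character subset of descriptor groups to compute, from
#'   `c("stft", "hurst", "dfa", "kolmen", "cd", "lle")`. Default all six.
#' @return Named numeric vector with attribute `degenerate`.
#' @export
assemble_features <- function(window, cfg = feature_config(),
                              subset = c("stft", "hurst", "dfa", "kolmen",
                                         "cd", "lle")) {
  data <- if (inherits(window, "epoch_window")) window$data else window
  stopifnot(is.matrix(data))
  subset <- match.arg(subset, several.ok = TRUE)
  ch_names <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  vals <- c(); flags <- c()
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    v <- c(); f <- c()
    if ("stft" %in% subset) {
      bp <- stft_band_power(x, cfg)
      v <- c(v, bp); f <- c(f, stats::setNames(rep(FALSE, 3), names(bp)))
    }
    for (nm in c("hurst", "dfa", "kolmen", "cd", "lle")) {
      if (!nm %in% subset) next
      est <- switch(nm,
                    hurst = hurst_rs(x, cfg),
                    dfa = dfa(x, cfg),
                    kolmen = perm_entropy(x, cfg),
                    cd = correlation_dimension(x, cfg),
                    lle = lyapunov_rosenstein(x, cfg))
      v <- c(v, stats::setNames(as.numeric(est), nm))
      f <- c(f, stats::setNames(attr(est, "degenerate"), nm))
    }
    names(v) <- paste(ch_names[ch], names(v), sep = ".")
    names(f) <- names(v)
    vals <- c(vals, v); flags <- c(flags, f)
  }
  structure(vals, degenerate = flags)
}

#' Feature table for a set of windows
#'
#' Applies [assemble_features()] to every window and returns one row per
#' window: provenance metadata, the feature columns, and `flags` (a
#' semicolon-separated list of degenerate scalars, empty when none).
#'
#' @param windows List of [epoch_window()] objects.
#' @param cfg A [feature_config()].
#' @param subset Descriptor subset, as in [assemble_features()].
#' @return A `data.frame`.
#' @export
featurize_windows <- function(windows, cfg = feature_config(),
                              subset = c("stft", "hurst", "dfa", "kolmen",
                                         "cd", "lle")) {
  stopifnot(length(windows) > 0)
  rows <- lapply(windows, function(w) assemble_features(w, cfg, subset))
  feat <- do.call(rbind, rows)
  flags <- vapply(rows, function(r) {
    dg <- attr(r, "degenerate")
    paste(names(dg)[dg], collapse = ";")
  }, "")
  cbind(window_meta(windows),
        as.data.frame(feat, optional = TRUE),
        data.frame(flags = flags, stringsAsFactors = FALSE))
}

# Columns of a feature table that hold features (not metadata).
feature_columns <- function(tab) {
  setdiff(names(tab), c("subject_id", "recording_id", "label",
                        "window_index", "flags"))
}
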