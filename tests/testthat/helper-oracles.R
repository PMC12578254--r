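# Independent reference implementations used as oracles. These are written
# as plain brute-force code (explicit loops, lm() fits) on purpose: they
# share no internals with the package estimators they check.

oracle_stft_band_power <- function(x, fs = 125, nw = 64, hop = 16,
                                   nfft = 128, eps = 1e-8) {
  n_frames <- floor((length(x) - nw) / hop) + 1
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / nw))
  out <- c(alpha = 0, beta = 0, gamma = 0)
  for (m in seq_len(n_frames)) {
    seg <- x[((m - 1) * hop + 1):((m - 1) * hop + nw)] * w
    for (k in 0:(nfft / 2)) {
      # direct DFT, one bin at a time
      X <- sum(seg * exp(-2i * pi * k * (0:(nw - 1)) / nfft))
      fk <- k * fs / nfft
      lp <- log(Mod(X)^2 + eps)
      if (fk >= 8 && fk < 13) out["alpha"] <- out["alpha"] + lp
      if (fk >= 13 && fk < 30) out["beta"] <- out["beta"] + lp
      if (fk >= 30 && fk <= 50) out["gamma"] <- out["gamma"] + lp
    }
  }
  out / n_frames
}

oracle_perm_entropy <- function(x, m = 3) {
  pats <- character(0)
  for (i in 1:(length(x) - m + 1)) {
    pats <- c(pats, paste(rank(x[i:(i + m - 1)], ties.method = "first"),
                          collapse = "-"))
  }
  p <- as.numeric(table(pats)) / length(pats)
  -sum(p * log(p))
}

oracle_rs_hurst <- function(x, scales = c(8, 16, 32, 64, 125),
                            drop_shortest = FALSE) {
  if (drop_shortest) scales <- scales[-1]
  lrs <- c(); ls <- c()
  for (s in scales) {
    if (s > length(x)) next
    vals <- c()
    a <- 1
    while (a + s - 1 <= length(x)) {
      seg <- x[a:(a + s - 1)]
      seg <- seg - mean(seg)
      S <- sqrt(sum(seg^2) / (s - 1))
      if (S > 0) {
        cum <- cumsum(seg)
        vals <- c(vals, (max(cum) - min(cum)) / S)
      }
      a <- a + max(1, floor(s / 2))
    }
    if (length(vals)) { lrs <- c(lrs, log(mean(vals))); ls <- c(ls, log(s)) }
  }
  unname(stats::coef(stats::lm(lrs ~ ls))[2])
}

oracle_dfa <- function(x, scales = c(8, 16, 32, 64, 125)) {
  N <- length(x)
  Y <- cumsum(x - mean(x))
  lf <- c(); ls <- c()
  for (s in scales) {
    ns <- floor(N / s)
    if (ns < 1) next
    total <- 0
    for (v in seq_len(ns)) {
      yk <- Y[((v - 1) * s + 1):(v * s)]
      t <- 1:s
      res <- stats::residuals(stats::lm(yk ~ t))
      total <- total + sum(res^2)
    }
    f <- sqrt(total / (ns * s))
    if (f > 0) { lf <- c(lf, log(f)); ls <- c(ls, log(s)) }
  }
  unname(stats::coef(stats::lm(lf ~ ls))[2])
}

# Correlation dimension with the same grid and span-selection contract as
# the package, realized independently (explicit pair loops, lm fits).
oracle_corr_dim <- function(x, m = 6, tau = 1, W = 6, n_radii = 20,
                            prc = c(0.05, 0.95), min_span = 5) {
  K <- length(x) - (m - 1) * tau
  emb <- sapply(0:(m - 1), function(j) x[(1:K) + j * tau])
  dd <- c()
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    if (j - i > W) dd <- c(dd, sqrt(sum((emb[i, ] - emb[j, ])^2)))
  }
  qs <- stats::quantile(dd, prc, names = FALSE)
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  C <- sapply(radii, function(r) sum(dd < r) / length(dd))
  lr <- log(radii[C > 0]); lc <- log(C[C > 0])
  best_r2 <- -1; best_slope <- NA; best_len <- 0
  for (a in 1:(length(lr) - min_span + 1)) {
    for (b in (a + min_span - 1):length(lr)) {
      fit <- stats::lm(lc[a:b] ~ lr[a:b])
      r2 <- summary(fit)$r.squared
      len <- b - a + 1
      if (r2 > best_r2 + 1e-12 ||
          (abs(r2 - best_r2) <= 1e-12 && len > best_len)) {
        best_r2 <- r2; best_slope <- unname(stats::coef(fit)[2]); best_len <- len
      }
    }
  }
  best_slope
}

# Analytic Lyapunov exponent of the logistic map via the derivative-product
# average: lambda = mean log |r (1 - 2 x_t)|.
oracle_lle_logistic <- function(x, r = 4) {
  mean(log(abs(r * (1 - 2 * x))))
}

# Tiny synthetic recording with every canonical channel.
make_test_recording <- function(n_sec = 10, fs = 125, label = 0L, seed = 1,
                                events = NULL) {
  set.seed(seed)
  n <- n_sec * fs
  data <- matrix(rnorm(11 * n, sd = 5), 11, n)
  eeg_recording(data, fs, canonical_montage(), events = events,
                subject_id = "T1", recording_id = paste0("T1_", seed),
                label = label)
}
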