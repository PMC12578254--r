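# Label-conditioned variational autoencoder on feature vectors.
#
# Encoder [d+1 -> 64 -> 32] with two 32-unit heads (mu, log sigma^2);
# decoder [33 -> 32 -> 64 -> d]; linear classifier head on z. The label is
# appended as a single scalar to both the encoder input and the latent code
# (dual concatenation). Forward and backward passes are written out
# explicitly; optimization is Adam.

#' CVAE configuration
#'
#' Architecture and training hyperparameters. Defaults: 88 input features,
#' latent size 32, encoder widths (64, 32), decoder widths (32, 64),
#' divergence weight `beta = 4` with `lambda_div = 2.5e-4` (so the divergence
#' enters the objective at `1e-3`), classifier weight `lambda_clf = 1`, KL
#' divergence (MMD optional), Adam at rate `1e-3` with moment decays
#' 0.9/0.999, batch size 128, 50 epochs, no weight decay, no dropout, no
#' KL annealing.
#'
#' @param d_feat Input feature dimension.
#' @param d_z Latent dimension.
#' @param enc_widths,dec_widths Hidden-layer widths.
#' @param beta Divergence weight multiplier.
#' @param lambda_div,lambda_clf Term weights in the objective.
#' @param divergence `"kl"` or `"mmd"`.
#' @param mmd_bandwidth Kernel bandwidth sigma^2 for MMD; `NULL` = median
#'   heuristic per batch.
#' @param lr,beta1,beta2,adam_eps Adam parameters.
#' @param batch_size,epochs Training schedule.
#' @param seed Seed controlling initialization, shuffling and noise draws.
#' @return Object of class `cvae_config`.
#' @export
cvae_config <- function(d_feat = 88L, d_z = 32L,
                        enc_widths = c(64L, 32L), dec_widths = c(32L, 64L),
                        beta = 4, lambda_div = 2.5e-4, lambda_clf = 1,
                        divergence = c("kl", "mmd"), mmd_bandwidth = NULL,
                        lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        adam_eps = 1e-8,
                        batch_size = 128L, epochs = 50L, seed = 1L) {
  divergence <- match.arg(divergence)
  structure(as.list(environment()), class = "cvae_config")
}

# Fan-in-scaled uniform initialization (framework-default style), seeded.
init_affine <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

#' Initialize a CVAE model
#'
#' @param cfg A [cvae_config()].
#' @return Object of class `cvae_model`: named affine layers plus the config.
#' @export
cvae_init <- function(cfg = cvae_config()) {
  stopifnot(inherits(cfg, "cvae_config"))
  with_seed(derive_seed(cfg$seed, "init"), {
    e1 <- cfg$enc_widths[1]; e2 <- cfg$enc_widths[2]
    d1 <- cfg$dec_widths[1]; d2 <- cfg$dec_widths[2]
    params <- list(
      enc1 = init_affine(cfg$d_feat + 1L, e1),
      enc2 = init_affine(e1, e2),
      mu   = init_affine(e2, cfg$d_z),
      lv   = init_affine(e2, cfg$d_z),
      dec1 = init_affine(cfg$d_z + 1L, d1),
      dec2 = init_affine(d1, d2),
      dec3 = init_affine(d2, cfg$d_feat),
      clf  = init_affine(cfg$d_z, 2L))
    structure(list(params = params, cfg = cfg), class = "cvae_model")
  })
}

#' Count trainable parameters
#'
#' Sum of all weight and bias entries across encoder, heads, decoder and
#' classifier. The default configuration counts 18,938.
#'
#' @param model A `cvae_model`.
#' @return Integer.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params,
             function(l) length(l$W) + length(l$b), 0))
}

affine <- function(X, layer) sweep(X %*% layer$W, 2L, layer$b, `+`)

#' Encode feature vectors to latent statistics
#'
#' Appends the label as one scalar (input width `d_feat + 1`) and runs the
#' encoder; two linear heads emit the posterior mean and log-variance.
#'
#' @param model A `cvae_model`.
#' @param x Numeric matrix (n x d_feat) or vector.
#' @param y Labels in `{0,1}` (recycled scalar allowed); any numeric scalar
#'   is accepted by the underlying network only via [cvae_posterior_mean()].
#' @return List of matrices `mu`, `log_var` (n x d_z).
#' @export
cvae_encode <- function(model, x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  fw <- encoder_forward(model$params, x, rep_len(as.numeric(y), nrow(x)))
  list(mu = fw$MU, log_var = fw$S)
}

encoder_forward <- function(p, X, y) {
  Xp <- cbind(X, y)
  A1 <- affine(Xp, p$enc1); H1 <- relu(A1)
  A2 <- affine(H1, p$enc2); H2 <- relu(A2)
  list(Xp = Xp, A1 = A1, H1 = H1, A2 = A2, H2 = H2,
       MU = affine(H2, p$mu), S = affine(H2, p$lv))
}

decoder_forward <- function(p, Z, y) {
  Zp <- cbind(Z, y)
  B1 <- affine(Zp, p$dec1); G1 <- relu(B1)
  B2 <- affine(G1, p$dec2); G2 <- relu(B2)
  list(Zp = Zp, B1 = B1, G1 = G1, B2 = B2, G2 = G2,
       XH = affine(G2, p$dec3))
}

#' Reparameterization
#'
#' `z = mu + exp(log_var / 2) * eps` with `eps ~ N(0, I)`; the noise is
#' injectable for tests.
#'
#' @param mu,log_var Matrices (n x d_z) or vectors.
#' @param eps Standard-normal draws of the same shape; `NULL` draws fresh
#'   ones from the current RNG stream.
#' @return Matrix of latent samples.
#' @export
reparameterize <- function(mu, log_var, eps = NULL) {
  if (!is.matrix(mu)) { mu <- as_row(mu); log_var <- as_row(log_var) }
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  if (!is.matrix(eps)) eps <- as_row(eps)
  mu + exp(log_var / 2) * eps
}

#' Decode latent vectors under a requested label
#'
#' Concatenates the label to the latent code (width `d_z + 1`) and applies
#' the decoder; the output layer is linear.
#'
#' @param model A `cvae_model`.
#' @param z Matrix (n x d_z) or vector.
#' @param y Labels in `{0,1}`.
#' @return Reconstruction matrix (n x d_feat).
#' @export
cvae_decode <- function(model, z, y) {
  if (!is.matrix(z)) z <- as_row(z)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  decoder_forward(model$params, z, rep_len(as.numeric(y), nrow(z)))$XH
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' `KL = 0.5 * sum_i (mu_i^2 + sigma_i^2 - log sigma_i^2 - 1)` per row,
#' natural logs.
#'
#' @param mu,log_var Matrices (n x d_z) or vectors.
#' @return Numeric vector, one non-negative value per row.
#' @export
kl_divergence <- function(mu, log_var) {
  if (!is.matrix(mu)) { mu <- as_row(mu); log_var <- as_row(log_var) }
  unname(0.5 * rowSums(mu^2 + exp(log_var) - log_var - 1))
}

#' Unbiased MMD^2 between two samples
#'
#' Gaussian kernel `k(u,v) = exp(-||u-v||^2 / (2 sigma^2))`; the unbiased
#' estimator excludes diagonal terms of the within-sample sums and may be
#' negative. When `bandwidth` is `NULL`, `sigma^2` is the median of squared
#' pairwise distances over the pooled sample (median heuristic).
#'
#' @param z Matrix (n x d), sample from the posterior.
#' @param z_prior Matrix (m x d), sample from the prior.
#' @param bandwidth Kernel bandwidth sigma^2, or `NULL`.
#' @return Scalar MMD^2 estimate.
#' @export
mmd_unbiased <- function(z, z_prior, bandwidth = NULL) {
  if (!is.matrix(z)) z <- cbind(z)
  if (!is.matrix(z_prior)) z_prior <- cbind(z_prior)
  n <- nrow(z); m <- nrow(z_prior)
  if (n < 2 || m < 2) stop("mmd_unbiased requires at least 2 points per sample")
  sq <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
    pmax(d2, 0)
  }
  dzz <- sq(z, z); dpp <- sq(z_prior, z_prior); dzp <- sq(z, z_prior)
  if (is.null(bandwidth)) {
    pooled <- rbind(z, z_prior)
    dall <- sq(pooled, pooled)
    bandwidth <- stats::median(dall[upper.tri(dall)])
    if (bandwidth <= 0) bandwidth <- 1
  }
  kzz <- exp(-dzz / (2 * bandwidth)); diag(kzz) <- 0
  kpp <- exp(-dpp / (2 * bandwidth)); diag(kpp) <- 0
  kzp <- exp(-dzp / (2 * bandwidth))
  sum(kzz) / (n * (n - 1)) + sum(kpp) / (m * (m - 1)) - 2 * sum(kzp) / (n * m)
}

# Gradient of the unbiased MMD^2 with respect to the rows of z (bandwidth
# treated as a constant, as is standard for the median heuristic).
mmd_grad_z <- function(z, z_prior, bandwidth) {
  n <- nrow(z); m <- nrow(z_prior)
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, `+`) - 2 * A %*% t(B), 0)
  }
  kzz <- exp(-sqd(z, z) / (2 * bandwidth)); diag(kzz) <- 0
  kzp <- exp(-sqd(z, z_prior) / (2 * bandwidth))
  # within-sample term: d/dz_i 2/(n(n-1)) sum_{i<i'} k = sum_j kzz_ij * -(z_i - z_j)/bw * 2/(n(n-1))
  g_within <- (-(z * rowSums(kzz) - kzz %*% z) / bandwidth) * (2 / (n * (n - 1)))
  g_cross <- ((z * rowSums(kzp) - kzp %*% z_prior) / bandwidth) * (2 / (n * m))
  g_within + g_cross
}

#' Classifier head probabilities
#'
#' Softmax of the linear head on the latent code.
#'
#' @param model A `cvae_model`.
#' @param z Latent matrix (n x d_z) or vector.
#' @return Matrix (n x 2) of class probabilities.
#' @export
cvae_classify <- function(model, z) {
  if (!is.matrix(z)) z <- as_row(z)
  softmax_rows(affine(z, model$params$clf))
}

# Weighted cross-entropy of true labels under softmax probabilities.
weighted_ce <- function(probs, y, weights) {
  p_true <- probs[cbind(seq_along(y), y + 1L)]
  w <- weights[y + 1L]
  mean(w * -log(pmax(p_true, 1e-300)))
}

#' Evaluate the training objective on a batch
#'
#' `total = MSE/feature + lambda_div * beta * D + lambda_clf * CE`, where D
#' is the KL (closed form, batch mean) or the unbiased MMD^2 against fresh
#' prior draws, and CE is the (class-weighted) cross-entropy of the
#' classifier on the sampled latent code.
#'
#' @param model A `cvae_model`.
#' @param x Feature matrix (n x d_feat).
#' @param y Integer labels 0/1.
#' @param class_weights Numeric length-2 weights `(class 0, class 1)`.
#' @param eps Optional noise matrix for the reparameterization.
#' @return Named list `total`, `recon`, `div`, `clf`.
#' @export
cvae_objective <- function(model, x, y, class_weights = c(1, 1), eps = NULL) {
  if (!is.matrix(x)) x <- as_row(x)
  cfg <- model$cfg
  y <- as.integer(rep_len(y, nrow(x)))
  enc <- encoder_forward(model$params, x, as.numeric(y))
  z <- reparameterize(enc$MU, enc$S, eps)
  dec <- decoder_forward(model$params, z, as.numeric(y))
  recon <- mean(rowMeans((x - dec$XH)^2))
  div <- if (cfg$divergence == "kl") {
    mean(kl_divergence(enc$MU, enc$S))
  } else {
    zp <- matrix(stats::rnorm(nrow(z) * cfg$d_z), nrow(z), cfg$d_z)
    mmd_unbiased(z, zp, cfg$mmd_bandwidth)
  }
  probs <- cvae_classify(model, z)
  clf <- weighted_ce(probs, y, class_weights)
  list(total = recon + cfg$lambda_div * cfg$beta * div + cfg$lambda_clf * clf,
       recon = recon, div = div, clf = clf)
}

# One training step: forward, explicit backward, gradient list.
cvae_grads <- function(p, cfg, X, y, class_weights) {
  B <- nrow(X); d <- cfg$d_feat
  yv <- as.numeric(y)
  enc <- encoder_forward(p, X, yv)
  EPS <- matrix(stats::rnorm(B * cfg$d_z), B, cfg$d_z)
  SIG <- exp(enc$S / 2)
  Z <- enc$MU + SIG * EPS
  dec <- decoder_forward(p, Z, yv)
  logits <- affine(Z, p$clf)
  P <- softmax_rows(logits)

  recon <- mean(rowMeans((X - dec$XH)^2))
  w <- class_weights[y + 1L]
  clf <- weighted_ce(P, y, class_weights)

  g <- list()
  # ---- reconstruction path (decoder) ----
  dXH <- 2 * (dec$XH - X) / (d * B)
  g$dec3 <- list(W = t(dec$G2) %*% dXH, b = colSums(dXH))
  dG2 <- dXH %*% t(p$dec3$W) * (dec$B2 > 0)
  g$dec2 <- list(W = t(dec$G1) %*% dG2, b = colSums(dG2))
  dG1 <- dG2 %*% t(p$dec2$W) * (dec$B1 > 0)
  g$dec1 <- list(W = t(dec$Zp) %*% dG1, b = colSums(dG1))
  dZ <- (dG1 %*% t(p$dec1$W))[, seq_len(cfg$d_z), drop = FALSE]

  # ---- classifier path ----
  Y1 <- matrix(0, B, 2); Y1[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- cfg$lambda_clf * (P - Y1) * (w / B)
  g$clf <- list(W = t(Z) %*% dlogits, b = colSums(dlogits))
  dZ <- dZ + dlogits %*% t(p$clf$W)

  # ---- divergence ----
  lam <- cfg$lambda_div * cfg$beta
  if (cfg$divergence == "kl") {
    div <- mean(kl_divergence(enc$MU, enc$S))
    dMU <- lam * enc$MU / B
    dS <- lam * 0.5 * (exp(enc$S) - 1) / B
  } else {
    ZP <- matrix(stats::rnorm(B * cfg$d_z), B, cfg$d_z)
    bw <- cfg$mmd_bandwidth
    if (is.null(bw)) {
      pooled <- rbind(Z, ZP)
      an <- rowSums(pooled^2)
      dall <- pmax(outer(an, an, `+`) - 2 * pooled %*% t(pooled), 0)
      bw <- stats::median(dall[upper.tri(dall)])
      if (bw <= 0) bw <- 1
    }
    div <- mmd_unbiased(Z, ZP, bw)
    dZ <- dZ + lam * mmd_grad_z(Z, ZP, bw)
    dMU <- matrix(0, B, cfg$d_z); dS <- matrix(0, B, cfg$d_z)
  }

  # ---- reparameterization and encoder ----
  dMU <- dMU + dZ
  dS <- dS + dZ * EPS * SIG * 0.5
  g$mu <- list(W = t(enc$H2) %*% dMU, b = colSums(dMU))
  g$lv <- list(W = t(enc$H2) %*% dS, b = colSums(dS))
  dH2 <- (dMU %*% t(p$mu$W) + dS %*% t(p$lv$W)) * (enc$A2 > 0)
  g$enc2 <- list(W = t(enc$H1) %*% dH2, b = colSums(dH2))
  dH1 <- dH2 %*% t(p$enc2$W) * (enc$A1 > 0)
  g$enc1 <- list(W = t(enc$Xp) %*% dH1, b = colSums(dH1))

  list(grads = g, recon = recon, div = div, clf = clf,
       total = recon + lam * div + cfg$lambda_clf * clf)
}

#' Train the CVAE
#'
#' Adam on the composite objective, deterministic given the config seed
#' (initialization, epoch shuffling and all noise draws derive from it).
#' Records per-epoch traces of the loss components, the per-epoch standard
#' deviation of the per-batch classifier loss, and training (and optionally
#' held-out) accuracy.
#'
#' @param x Feature matrix (n x d_feat).
#' @param y Integer labels 0/1.
#' @param cfg A [cvae_config()].
#' @param class_weights Length-2 class weights (default both 1).
#' @param x_val,y_val Optional held-out set evaluated each epoch with
#'   [cvae_predict()].
#' @param label_policy Evaluation label policy, see [cvae_posterior_mean()].
#' @return Object of class `cvae_fit`: the trained `model` and a `trace`
#'   data frame.
#' @export
cvae_train <- function(x, y, cfg = cvae_config(), class_weights = c(1, 1),
                       x_val = NULL, y_val = NULL,
                       label_policy = c("marginal", "true", "zero")) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  label_policy <- match.arg(label_policy)
  cfg$d_feat <- ncol(x)
  model <- cvae_init(cfg)
  p <- model$params
  adam_m <- rapply(p, function(a) a * 0, how = "replace")
  adam_v <- adam_m
  step <- 0L
  trace <- NULL
  y <- as.integer(y)
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(x))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep <- list(recon = 0, div = 0, clf = 0, total = 0)
      clf_batch <- numeric(0)
      for (bi in batches) {
        res <- cvae_grads(p, cfg, x[bi, , drop = FALSE], y[bi], class_weights)
        if (!is.finite(res$total)) {
          stop(sprintf("non-finite loss at epoch %d (recon=%g div=%g clf=%g)",
                       epoch, res$recon, res$div, res$clf))
        }
        step <- step + 1L
        for (ln in names(p)) {
          for (part in c("W", "b")) {
            gg <- res$grads[[ln]][[part]]
            adam_m[[ln]][[part]] <- cfg$beta1 * adam_m[[ln]][[part]] + (1 - cfg$beta1) * gg
            adam_v[[ln]][[part]] <- cfg$beta2 * adam_v[[ln]][[part]] + (1 - cfg$beta2) * gg^2
            mhat <- adam_m[[ln]][[part]] / (1 - cfg$beta1^step)
            vhat <- adam_v[[ln]][[part]] / (1 - cfg$beta2^step)
            p[[ln]][[part]] <- p[[ln]][[part]] - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
          }
        }
        frac <- length(bi) / nrow(x)
        for (nm in names(ep)) ep[[nm]] <- ep[[nm]] + res[[nm]] * frac
        clf_batch <- c(clf_batch, res$clf)
      }
      model$params <- p
      acc_train <- mean(cvae_predict(model, x, y_true = y,
                                     label_policy = label_policy) == y)
      acc_val <- if (!is.null(x_val)) {
        mean(cvae_predict(model, x_val, y_true = y_val,
                          label_policy = label_policy) == y_val)
      } else NA_real_
      trace <- rbind(trace, data.frame(
        epoch = epoch, total = ep$total, recon = ep$recon, div = ep$div,
        clf = ep$clf, clf_sd_batch = stats::sd(clf_batch),
        acc_train = acc_train, acc_val = acc_val))
    }
  })
  model$params <- p
  structure(list(model = model, trace = trace,
                 label_policy = label_policy,
                 class_weights = class_weights), class = "cvae_fit")
}

#' Posterior mean under an evaluation label policy
#'
#' The encoder requires a label input. At evaluation three policies are
#' supported: `"marginal"` (default) averages the posterior means obtained
#' with `y = 0` and `y = 1`, so no true label is consumed; `"true"` feeds the
#' provided labels (the conditional protocol — requires `y_true`); `"zero"`
#' feeds a constant 0.
#'
#' @param model A `cvae_model` or `cvae_fit`.
#' @param x Feature matrix.
#' @param y_true Labels, needed only for `policy = "true"`.
#' @param policy Label policy.
#' @return Posterior-mean matrix (n x d_z).
#' @export
cvae_posterior_mean <- function(model, x, y_true = NULL,
                                policy = c("marginal", "true", "zero")) {
  if (inherits(model, "cvae_fit")) model <- model$model
  policy <- match.arg(policy)
  if (!is.matrix(x)) x <- as_row(x)
  switch(policy,
    marginal = {
      m0 <- encoder_forward(model$params, x, rep(0, nrow(x)))$MU
      m1 <- encoder_forward(model$params, x, rep(1, nrow(x)))$MU
      (m0 + m1) / 2
    },
    true = {
      if (is.null(y_true)) stop("policy 'true' requires y_true")
      encoder_forward(model$params, x, as.numeric(rep_len(y_true, nrow(x))))$MU
    },
    zero = encoder_forward(model$params, x, rep(0, nrow(x)))$MU)
}

#' Predict class labels
#'
#' Classifier applied to the posterior mean (sampling noise is only used
#' during training).
#'
#' @inheritParams cvae_posterior_mean
#' @param label_policy Label policy passed to [cvae_posterior_mean()].
#' @return Integer vector of predicted labels.
#' @export
cvae_predict <- function(model, x, y_true = NULL,
                         label_policy = c("marginal", "true", "zero")) {
  if (inherits(model, "cvae_fit")) model <- model$model
  label_policy <- match.arg(label_policy)
  mu <- cvae_posterior_mean(model, x, y_true, label_policy)
  probs <- cvae_classify(model, mu)
  max.col(probs, ties.method = "first") - 1L
}

#' Label-controlled generation
#'
#' Draws latent codes from the standard-normal prior and decodes them under
#' the requested label.
#'
#' @param model A `cvae_model` or `cvae_fit`.
#' @param y_star Requested label, 0 or 1.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Matrix (n x d_feat) of generated feature vectors.
#' @export
cvae_generate <- function(model, y_star, n, seed = 1L) {
  if (inherits(model, "cvae_fit")) model <- model$model
  stopifnot(y_star %in% c(0, 1))
  z <- with_seed(seed, matrix(stats::rnorm(n * model$cfg$d_z), n, model$cfg$d_z))
  cvae_decode(model, z, rep(y_star, n))
}

#' Save / load a model checkpoint
#'
#' Flat binary checkpoint (RDS) of the named parameter arrays together with
#' an echo of the configuration and a format version.
#'
#' @param model A `cvae_model` or `cvae_fit`.
#' @param path File path.
#' @return `cvae_save` returns `path` invisibly; `cvae_load` the model.
#' @export
cvae_save <- function(model, path) {
  if (inherits(model, "cvae_fit")) model <- model$model
  saveRDS(list(format = "eegcvae-checkpoint-1", params = model$params,
               cfg = unclass(model$cfg)), path)
  invisible(path)
}

#' @rdname cvae_save
#' @export
cvae_load <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "eegcvae-checkpoint-1"))
  cfg <- structure(obj$cfg, class = "cvae_config")
  structure(list(params = obj$params, cfg = cfg), class = "cvae_model")
}
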