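test_that("architecture matches the printed layer sizes and parameter count", {
  model <- cvae_init(cvae_config())
  expect_identical(count_parameters(model), 18938)
  # classifier head alone: 32 * 2 + 2
  expect_identical(length(model$params$clf$W) + length(model$params$clf$b), 66L)
  # encoder first layer consumes 89 inputs; decoder first layer 33
  expect_identical(dim(model$params$enc1$W), c(89L, 64L))
  expect_identical(dim(model$params$dec1$W), c(33L, 32L))

  # closed-form affine count for the reduced-latent variant
  count_formula <- function(d, z) {
    (d + 1) * 64 + 64 + 64 * 32 + 32 + 2 * (32 * z + z) +
      (z + 1) * 32 + 32 + 32 * 64 + 64 + 64 * d + d + z * 2 + 2
  }
  m8 <- cvae_init(cvae_config(d_z = 8L))
  expect_identical(count_parameters(m8), count_formula(88, 8))
  expect_identical(count_parameters(model), count_formula(88, 32))
})

test_that("encoder and decoder consume the concatenated label", {
  model <- cvae_init(cvae_config(seed = 2))
  x <- rnorm(88)
  e0 <- cvae_encode(model, x, 0); e1 <- cvae_encode(model, x, 1)
  expect_false(isTRUE(all.equal(e0$mu, e1$mu)))
  expect_identical(dim(e0$mu), c(1L, 32L))
  expect_error(cvae_encode(model, x, 2), "binary")

  z <- rnorm(32)
  expect_false(isTRUE(all.equal(cvae_decode(model, z, 0),
                                cvae_decode(model, z, 1))))
  expect_identical(dim(cvae_decode(model, z, 0)), c(1L, 88L))

  # zeroed weights: mu = 0 for x = 0, y = 0; decoder returns its bias
  zero <- model
  zero$params <- rapply(zero$params, function(a) a * 0, how = "replace")
  expect_equal(unname(cvae_encode(zero, rep(0, 88), 0)$mu), matrix(0, 1, 32))
  expect_equal(unname(cvae_decode(zero, z, 1)),
               matrix(zero$params$dec3$b, 1, 88))
})

test_that("reparameterization is the location-scale transform", {
  mu <- rnorm(32); lv <- rnorm(32)
  expect_equal(reparameterize(mu, lv, eps = rep(0, 32)), matrix(mu, 1))
  eps <- rnorm(32)
  expect_equal(reparameterize(rep(0, 32), rep(0, 32), eps = eps),
               matrix(eps, 1))
  expect_equal(reparameterize(mu, lv, eps = eps),
               matrix(mu + exp(lv / 2) * eps, 1))
})

test_that("KL closed form matches hand-computed cases and is non-negative", {
  expect_equal(kl_divergence(rep(0, 32), rep(0, 32)), 0)
  expect_equal(kl_divergence(rep(1, 32), rep(0, 32)), 16)
  expect_equal(kl_divergence(0, log(2)), 0.5 * (2 - log(2) - 1))
  expect_equal(kl_divergence(0, log(2)), 0.15343, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:50) {
    kl <- kl_divergence(rnorm(32), rnorm(32))
    expect_gte(kl, 0)
  }
})

test_that("unbiased MMD matches enumeration and concentrates at zero", {
  # hand enumeration: Z = Ztilde = {0, 1}, sigma^2 = 1
  expect_equal(mmd_unbiased(cbind(c(0, 1)), cbind(c(0, 1)), bandwidth = 1),
               exp(-0.5) - 1, tolerance = 1e-12)
  expect_equal(mmd_unbiased(cbind(c(0, 1)), cbind(c(0, 1)), bandwidth = 1),
               -0.39347, tolerance = 1e-5)
  # identical points: all kernel values 1, estimate 0
  expect_equal(mmd_unbiased(cbind(c(3, 3)), cbind(c(3, 3)), bandwidth = 2), 0)
  expect_error(mmd_unbiased(cbind(1), cbind(c(0, 1))), "at least 2")

  # symmetry and the large-bandwidth limit
  set.seed(5)
  z1 <- matrix(rnorm(40), 20, 2); z2 <- matrix(rnorm(40, 1), 20, 2)
  expect_equal(mmd_unbiased(z1, z2), mmd_unbiased(z2, z1))
  expect_lt(abs(mmd_unbiased(z1, z2, bandwidth = 1e12)), 1e-9)

  # both samples from the prior: concentration of the unbiased estimator
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    mmd_unbiased(matrix(rnorm(500 * 32), 500, 32),
                 matrix(rnorm(500 * 32), 500, 32))
  }, 0)
  expect_lt(max(abs(vals)), 0.01)
})

test_that("classifier head emits calibrated softmax probabilities", {
  model <- cvae_init(cvae_config())
  model$params$clf$W[] <- 0; model$params$clf$b[] <- 0
  expect_equal(unname(cvae_classify(model, rnorm(32))), cbind(0.5, 0.5))
  model$params$clf$b <- c(10, -10)
  p <- cvae_classify(model, rep(0, 32))
  expect_equal(p[1, 1], 1 / (1 + exp(-20)), tolerance = 1e-12)
  # weighted CE with unit weights equals unweighted
  probs <- cbind(c(0.7, 0.2), c(0.3, 0.8))
  y <- c(0L, 1L)
  expect_equal(eegcvae:::weighted_ce(probs, y, c(1, 1)),
               mean(-log(c(0.7, 0.8))))
})

test_that("objective combines the printed term weights", {
  cfg <- cvae_config()
  expect_equal(cfg$lambda_div * cfg$beta, 1e-3)
  model <- cvae_init(cfg)
  x <- rnorm(88)
  # recon term: a uniform +1 reconstruction error gives MSE exactly 1
  enc <- cvae_encode(model, x, 0)
  z <- reparameterize(enc$mu, enc$log_var, eps = matrix(0, 1, 32))
  xh <- cvae_decode(model, z, 0)
  recon <- mean((x - (x + 1))^2)
  expect_equal(recon, 1)
  obj <- cvae_objective(model, x, 0L, eps = matrix(0, 1, 32))
  expect_equal(obj$total,
               obj$recon + 1e-3 * obj$div + obj$clf, tolerance = 1e-12)
  expect_equal(obj$div, unname(kl_divergence(enc$mu, enc$log_var)))
})

test_that("analytic gradients match finite differences (KL and MMD paths)", {
  for (div in c("kl", "mmd")) {
    cfg <- cvae_config(d_feat = 10L, d_z = 4L, enc_widths = c(8L, 6L),
                       dec_widths = c(6L, 8L), divergence = div,
                       mmd_bandwidth = 2, seed = 3L)
    model <- cvae_init(cfg)
    X <- with_seed(7, matrix(rnorm(50), 5, 10))
    y <- c(0L, 1L, 0L, 1L, 1L)
    set.seed(99)
    res <- eegcvae:::cvae_grads(model$params, cfg, X, y, c(1, 1))
    objf <- function(p) {
      set.seed(99)
      enc <- eegcvae:::encoder_forward(p, X, as.numeric(y))
      EPS <- matrix(rnorm(5 * cfg$d_z), 5, cfg$d_z)
      Z <- enc$MU + exp(enc$S / 2) * EPS
      dec <- eegcvae:::decoder_forward(p, Z, as.numeric(y))
      P <- eegcvae:::softmax_rows(sweep(Z %*% p$clf$W, 2, p$clf$b, `+`))
      d <- if (div == "kl") mean(kl_divergence(enc$MU, enc$S)) else {
        ZP <- matrix(rnorm(5 * cfg$d_z), 5, cfg$d_z)
        mmd_unbiased(Z, ZP, 2)
      }
      mean(rowMeans((X - dec$XH)^2)) + cfg$lambda_div * cfg$beta * d +
        eegcvae:::weighted_ce(P, y, c(1, 1))
    }
    err <- c()
    for (ln in names(model$params)) for (part in c("W", "b")) {
      p2 <- model$params
      n_el <- length(p2[[ln]][[part]])
      for (k in with_seed(13, sample(n_el, min(3, n_el)))) {
        h <- 1e-5
        p2[[ln]][[part]][k] <- model$params[[ln]][[part]][k] + h
        up <- objf(p2)
        p2[[ln]][[part]][k] <- model$params[[ln]][[part]][k] - h
        dn <- objf(p2)
        p2[[ln]][[part]][k] <- model$params[[ln]][[part]][k]
        err <- c(err, abs((up - dn) / (2 * h) - res$grads[[ln]][[part]][k]))
      }
    }
    expect_lt(max(err), 1e-4)
  }
  # the closed-form KL gradient wrt mu is mu itself
  mu <- rnorm(4); lv <- rnorm(4)
  fd <- vapply(1:4, function(i) {
    e <- rep(0, 4); e[i] <- 1e-6
    (kl_divergence(mu + e, lv) - kl_divergence(mu - e, lv)) / 2e-6
  }, 0)
  expect_equal(fd, mu, tolerance = 1e-4)
})

test_that("training is deterministic and learns separable classes", {
  d <- gen_two_class_features(2000, shift = 2, seed = 5)
  sp <- stratified_split(d$y, rep("s1", 2000), 0.8, seed = 2)
  cfg <- cvae_config(epochs = 12, seed = 11)
  fit1 <- cvae_train(d$x[sp$train, ], d$y[sp$train], cfg,
                     x_val = d$x[sp$test, ], y_val = d$y[sp$test])
  fit2 <- cvae_train(d$x[sp$train, ], d$y[sp$train], cfg,
                     x_val = d$x[sp$test, ], y_val = d$y[sp$test])
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_gte(tail(fit1$trace$acc_val, 1), 0.95)
  # trace bookkeeping: every component logged each epoch
  expect_identical(nrow(fit1$trace), 12L)
  expect_true(all(is.finite(as.matrix(fit1$trace))))

  # ELBO consistency: total loss decreases over the early epochs
  expect_lt(fit1$trace$total[12], fit1$trace$total[1])
  expect_lt(mean(diff(fit1$trace$total[1:6])), 0)
})

test_that("MMD-divergence training runs and regularizes", {
  d <- gen_two_class_features(600, shift = 2, seed = 9)
  cfg <- cvae_config(epochs = 6, divergence = "mmd", seed = 4)
  fit <- cvae_train(d$x, d$y, cfg)
  expect_true(all(is.finite(fit$trace$div)))
  expect_gte(tail(fit$trace$acc_train, 1), 0.9)
})

test_that("label-conditioned generation reproduces class structure", {
  d <- gen_two_class_features(2000, shift = 2, seed = 5)
  fit <- cvae_train(d$x, d$y, cvae_config(epochs = 25, seed = 11))
  g1a <- cvae_generate(fit, 1, 10, seed = 7)
  g1b <- cvae_generate(fit, 1, 10, seed = 7)
  expect_identical(g1a, g1b)
  expect_identical(dim(g1a), c(10L, 88L))

  # parameter recovery at the default weights: generations reproduce the
  # sign of the injected per-dimension shifts in >= 80% of the 88 dims
  g0 <- cvae_generate(fit, 0, 500, seed = 13)
  g1 <- cvae_generate(fit, 1, 500, seed = 14)
  sign_ok <- sign(colMeans(g1) - colMeans(g0)) == sign(d$mu_shift)
  expect_gte(mean(sign_ok), 0.8)

  # full label control of generation requires the divergence term to bind
  # (at the reference 1e-3 weight the unregularized latent already encodes
  # class, so prior draws decode with weak label influence); with a binding
  # weight, re-encoded generations classify as the requested label
  fit_b <- cvae_train(d$x, d$y, cvae_config(epochs = 25, lambda_div = 0.25,
                                            seed = 11))
  for (lab in 0:1) {
    g <- cvae_generate(fit_b, lab, 200, seed = 3)
    expect_gte(mean(cvae_predict(fit_b, g) == lab), 0.8)
  }
})

test_that("checkpoints round-trip through save and load", {
  model <- cvae_init(cvae_config(seed = 6))
  path <- tempfile(fileext = ".rds")
  cvae_save(model, path)
  back <- cvae_load(path)
  expect_identical(back$params, model$params)
  x <- rnorm(88)
  expect_identical(cvae_encode(back, x, 1), cvae_encode(model, x, 1))
})
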