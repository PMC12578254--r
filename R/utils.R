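# Internal helpers shared across modules.

#' Canonical 11-channel montage
#'
#' Ordered electrode names of the common montage used throughout the package.
#' All recordings are reduced to this subset, in this order, before epoching.
#'
#' @return Character vector of length 11.
#' @export
canonical_montage <- function() {
  c("C3", "Cz", "C4", "FC3", "FCz", "FC4", "CP3", "CPz", "CP4", "F3", "F4")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the RNG, evaluates `code`, and restores the caller's RNG state, so
#' seeded computations never perturb the surrounding random stream. All
#' stochastic operations in the package run through this.
#'
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Pipeline stages draw their own seeds from a single run seed so that every
#' stochastic stage is independently reproducible. The derivation hashes the
#' stage name onto the run seed with a fixed 32-bit linear congruential step;
#' the result always fits in a signed 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"balance"`.
#' @return A single non-negative integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # modulus 2^31 - 1 keeps the value a valid R integer
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Ordinary least squares slope of y on x (both numeric, length >= 2).
ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# Slope and R^2 of the simple regression y ~ x.
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 1 else (sxy^2) / (sxx * syy)
  list(slope = slope, r2 = r2)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax of a matrix of logits, numerically stabilised.
softmax_rows <- function(l) {
  m <- apply(l, 1L, max)
  e <- exp(l - m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a bare vector to an unnamed 1-row matrix.
as_row <- function(v) matrix(v, nrow = 1L)
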