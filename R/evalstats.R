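# Stratified splitting, classification metrics, Wilson intervals,
# two-proportion z-tests and the descriptor-redundancy check.

#' Stratified train/test split
#'
#' Window-level split stratified by (class, subject) cell: within each cell,
#' windows are shuffled (seeded) and allocated to the training set by
#' largest-remainder rounding of `frac`, so class and subject proportions are
#' preserved to within one window per cell. The split is not
#' subject-exclusive.
#'
#' @param labels Integer class labels (0/1), one per window.
#' @param subjects Subject identifier per window.
#' @param frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`, plus `frac`
#'   and `seed`.
#' @export
stratified_split <- function(labels, subjects, frac = 0.8, seed = 1L) {
  stopifnot(length(labels) == length(subjects), frac > 0, frac < 1)
  cells <- split(seq_along(labels), paste(labels, subjects, sep = "\r"))
  if (any(lengths(cells) < 2)) {
    bad <- names(cells)[lengths(cells) < 2]
    stop("cell(s) with fewer than 2 windows: ",
         paste(gsub("\r", "/", bad), collapse = ", "))
  }
  # largest-remainder allocation of the training quota across cells
  sizes <- lengths(cells)
  quota <- largest_remainder(sizes * frac, round(sum(sizes) * frac))
  quota <- pmin(quota, sizes - 1L)   # keep at least one test window per cell
  train <- integer(0)
  for (k in seq_along(cells)) {
    idx <- with_seed(derive_seed(seed, paste0("split", names(cells)[k])),
                     sample(cells[[k]]))
    train <- c(train, idx[seq_len(quota[k])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train),
       frac = frac, seed = seed)
}

#' Binary classification metrics
#'
#' Confusion matrix, accuracy, and macro-averaged precision, recall and F1
#' (unweighted mean of the per-class values). A class absent from the truth
#' gets undefined per-class metrics reported as 0 and flagged.
#'
#' @param y_true,y_pred Integer vectors of labels 0/1.
#' @return Object of class `metrics_report`: `confusion` (2x2, rows = truth),
#'   `accuracy`, `precision`, `recall`, `macro_f1`, `per_class` data frame,
#'   `n`, and `flags`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  lv <- c(0, 1)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(truth = lv, pred = lv))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  flags <- character(0)
  per <- lapply(1:2, function(k) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    if (sum(cm[k, ]) == 0) {
      flags <<- c(flags, sprintf("class %d absent from y_true", lv[k]))
      return(c(precision = 0, recall = 0, f1 = 0))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  structure(list(confusion = cm, accuracy = acc,
                 precision = mean(per[, "precision"]),
                 recall = mean(per[, "recall"]),
                 macro_f1 = mean(per[, "f1"]),
                 per_class = as.data.frame(per), n = n, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  macro-F1 %.4f  (n=%d)\n",
              x$accuracy, x$precision, x$recall, x$macro_f1, x$n))
  print(x$confusion)
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' @param p_hat Observed proportion in `[0,1]`.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`, always inside `[0,1]`.
#' @export
wilson_ci <- function(p_hat, n, conf = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  z <- stats::qnorm((1 + conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Two-proportion z-test (unpaired, equal n)
#'
#' Pooled-proportion standard error and a two-sided normal p-value; the
#' conservative comparison used when paired per-window predictions are not
#' available. Degenerate pooled proportions (0 or 1) yield `p = 1` when the
#' proportions are equal and `p = 0` with a flag otherwise.
#'
#' @param p1,p2 Observed proportions.
#' @param n Trials per group (identical in both groups).
#' @return Named list `z`, `p`, and `flag` (character, possibly empty).
#' @export
two_proportion_z <- function(p1, p2, n) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n >= 1)
  pool <- (p1 + p2) / 2
  if (pool <= 0 || pool >= 1) {
    if (p1 == p2) return(list(z = 0, p = 1, flag = "degenerate pooled proportion"))
    return(list(z = sign(p1 - p2) * Inf, p = 0,
                flag = "degenerate pooled proportion"))
  }
  se <- sqrt(pool * (1 - pool) * 2 / n)
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), flag = character(0))
}

#' Descriptor redundancy check
#'
#' Pearson correlations between per-window descriptor summaries: each of the
#' six descriptor groups (STFT band power, Hurst, DFA, permutation entropy,
#' correlation dimension, Lyapunov exponent) is summarized by its channel
#' mean per window, and the 6x6 correlation matrix plus the maximum
#' off-diagonal |r| are returned. Zero-variance descriptors are flagged and
#' their correlations reported as NA.
#'
#' @param feature_table A data frame from [featurize_windows()] (>= 3 rows).
#' @return List `r_matrix`, `max_abs_r`, `flags`.
#' @export
feature_redundancy <- function(feature_table) {
  stopifnot(nrow(feature_table) >= 3)
  fc <- feature_columns(feature_table)
  groups <- list(stft = "\\.bp_(alpha|beta|gamma)$", hurst = "\\.hurst$",
                 dfa = "\\.dfa$", kolmen = "\\.kolmen$", cd = "\\.cd$",
                 lle = "\\.lle$")
  summaries <- vapply(groups, function(rx) {
    cols <- grep(rx, fc, value = TRUE)
    if (!length(cols)) return(rep(NA_real_, nrow(feature_table)))
    rowMeans(as.matrix(feature_table[, cols, drop = FALSE]))
  }, numeric(nrow(feature_table)))
  keep <- colSums(is.na(summaries)) == 0
  flags <- character(0)
  sds <- apply(summaries, 2L, stats::sd)
  zero_var <- keep & (is.na(sds) | sds == 0)
  if (any(zero_var)) {
    flags <- paste("zero-variance descriptor:", names(groups)[zero_var])
  }
  r <- suppressWarnings(stats::cor(summaries[, keep, drop = FALSE]))
  r[!is.finite(r)] <- NA
  off <- abs(r[upper.tri(r)])
  list(r_matrix = r, max_abs_r = if (all(is.na(off))) NA else max(off, na.rm = TRUE),
       flags = flags)
}
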