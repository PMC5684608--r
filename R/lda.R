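#' Random undersampling to balance classes
#'
#' Reduces the majority class to the minority-class count by uniform
#' sampling without replacement; the retained rows keep their original
#' order. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per epoch.
#' @param labels 0/1 vector (1 = preictal).
#' @param seed integer seed.
#' @return List with balanced `features`, `labels` and the retained row
#'   indices `idx`.
#' @export
undersample <- function(features, labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  if (n1 == n0) {
    idx <- seq_along(labels)
  } else {
    maj <- if (n0 > n1) 0L else 1L
    keep_maj <- withr::with_seed(seed,
      sample(which(labels == maj), min(n0, n1)))
    idx <- sort(c(which(labels != maj), keep_maj))
  }
  list(features = features[idx, , drop = FALSE], labels = labels[idx], idx = idx)
}

#' Fit a two-class linear discriminant in closed form
#'
#' Equal-prior LDA on a (near-)balanced training set: the weight vector is
#' `w = S^-1 (mu1 - mu0)` with `S` the pooled within-class covariance shrunk
#' toward its diagonal by `shrinkage`, and the bias places the decision
#' boundary at the midpoint of the projected class means:
#' `b = -w . (mu1 + mu0) / 2`. The decision for a feature vector `x` is
#' preictal iff `w . x + b > 0`.
#'
#' @param features numeric matrix, one row per epoch.
#' @param labels 0/1 vector (1 = preictal).
#' @param shrinkage coefficient in `[0, 1]` pulling the pooled covariance
#'   toward its diagonal; the default 1e-3 guards against ill-conditioned
#'   pooled covariances when preictal epochs are scarce.
#' @return An object of class `lda_model` with `w`, `b`, `mu1`, `mu0`,
#'   `pooled_cov`, `shrinkage`.
#' @export
fit_lda <- function(features, labels, shrinkage = 1e-3) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("feature/label length mismatch", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  X1 <- X[labels == 1L, , drop = FALSE]
  X0 <- X[labels == 0L, , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X0) < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  mu1 <- colMeans(X1)
  mu0 <- colMeans(X0)
  S <- ((nrow(X1) - 1L) * stats::cov(X1) + (nrow(X0) - 1L) * stats::cov(X0)) /
    (nrow(X1) + nrow(X0) - 2L)
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow(S))
  md <- mu1 - mu0
  w <- tryCatch(solve(S, md), error = function(e) {
    stop("pooled covariance is singular; use shrinkage > 0", call. = FALSE)
  })
  if (sqrt(sum(md^2)) < 1e-10) {
    warning("identical class means: degenerate discriminant (w ~ 0)", call. = FALSE)
  }
  b <- -sum(w * (mu1 + mu0) / 2)
  structure(list(w = as.numeric(w), b = b, mu1 = mu1, mu0 = mu0,
                 pooled_cov = S, shrinkage = shrinkage),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, |w| = %.4g, b = %.4g, shrinkage = %g\n",
              length(x$w), sqrt(sum(x$w^2)), x$b, x$shrinkage))
  invisible(x)
}

#' Binary classifier output series
#'
#' One decision per epoch, in order: 1 iff `w . x + b > 0` (ties classify as
#' interictal, the conservative choice for an alarm system).
#'
#' @param model an `lda_model`.
#' @param features epochs-by-features matrix, rows in temporal order.
#' @param times optional global epoch start times (seconds), one per row.
#' @param step_s series step in seconds (default 1).
#' @return An object of class `binary_series`: list with integer `values`,
#'   `times`, `step_s`.
#' @export
predict_series <- function(model, features, times = NULL, step_s = 1) {
  X <- as.matrix(features)
  if (nrow(X) == 0L) {
    return(binary_series(integer(0), numeric(0), step_s))
  }
  if (ncol(X) != length(model$w)) stop("feature dimension mismatch", call. = FALSE)
  if (!all(is.finite(X))) {
    bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))[1L]
    stop(sprintf("non-finite feature in epoch %d", bad), call. = FALSE)
  }
  if (is.null(times)) times <- (seq_len(nrow(X)) - 1L) * step_s
  score <- as.numeric(X %*% model$w + model$b)
  binary_series(as.integer(score > 0), times, step_s)
}

#' Construct a binary decision series
#' @param values 0/1 values, one per epoch step.
#' @param times global epoch start times in seconds.
#' @param step_s series step in seconds.
#' @return A `binary_series` object.
#' @export
binary_series <- function(values, times, step_s = 1) {
  values <- as.integer(values)
  if (!all(values %in% c(0L, 1L))) stop("series values must be 0/1", call. = FALSE)
  if (length(values) != length(times)) stop("values/times length mismatch", call. = FALSE)
  structure(list(values = values, times = as.numeric(times), step_s = step_s),
            class = "binary_series")
}

#' Median-filter a binary series
#'
#' Sliding median of odd order (default 7, i.e. a seventh-order median
#' filter) centered at each position; edges are handled by reflecting the
#' series, which avoids the spurious edge zeros truncation would cause.
#' Output length equals input length.
#'
#' @param series a `binary_series` or plain 0/1 vector.
#' @param order odd window length (default 7).
#' @return Same type as the input, smoothed.
#' @export
median_smooth <- function(series, order = 7L) {
  if (order < 1L || order %% 2L == 0L) {
    stop("median filter order must be odd and >= 1", call. = FALSE)
  }
  x <- if (inherits(series, "binary_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n == 0L || order == 1L) {
    sm <- x
  } else {
    h <- (order - 1L) %/% 2L
    reflect <- function(j) {  # symmetric reflection including the edge sample
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      j
    }
    sm <- vapply(seq_len(n), function(i) {
      stats::median(x[vapply((i - h):(i + h), reflect, integer(1))])
    }, numeric(1))
  }
  if (inherits(series, "binary_series")) {
    binary_series(sm, series$times, series$step_s)
  } else {
    sm
  }
}
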