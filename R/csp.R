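#' Trace-normalized epoch covariance
#'
#' For a channels-by-samples data segment `D`, computes
#' `C = D D' / trace(D D')`: the uncentered spatial covariance normalized to
#' unit trace, so epochs contribute to class averages independently of their
#' amplitude scale.
#'
#' @param D numeric matrix, channels in rows (>= 2 samples).
#' @return Symmetric unit-trace matrix of class `csp_cov` with attribute
#'   `n_source = 1`.
#' @export
normalized_covariance <- function(D) {
  D <- as.matrix(D)
  if (ncol(D) < 2L) stop("need at least 2 samples per epoch", call. = FALSE)
  M <- tcrossprod(D)
  tr <- sum(diag(M))
  if (tr <= 0) {
    stop("degenerate epoch: zero trace (all-zero segment)", call. = FALSE)
  }
  C <- (M + t(M)) / (2 * tr)
  structure(C, class = c("csp_cov", class(C)), n_source = 1L)
}

#' Average covariance of one class
#'
#' Element-wise arithmetic mean of per-epoch normalized covariances; the
#' unit trace is preserved by linearity.
#'
#' @param covs non-empty list of equal-dimension covariance matrices.
#' @return The mean covariance (class `csp_cov`), with `n_source` equal to
#'   the total number of source epochs.
#' @export
class_mean_covariance <- function(covs) {
  if (!length(covs)) stop("empty covariance list", call. = FALSE)
  dims <- vapply(covs, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("covariance dimensions differ", call. = FALSE)
  M <- Reduce(`+`, lapply(covs, unclass)) / length(covs)
  ns <- sum(vapply(covs, function(x) {
    s <- attr(x, "n_source"); if (is.null(s)) 1L else s
  }, integer(1)))
  structure(M, class = c("csp_cov", class(M)), n_source = ns)
}

# deterministic eigenvector sign: first coefficient above tolerance positive
.fix_signs <- function(V, tol = 1e-8) {
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > tol)
    if (length(nz) && V[nz[1L], j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit a common spatial pattern model
#'
#' Derives the CSP projection from the two class covariances
#' (`C1` = preictal, `C2` = interictal):
#' \enumerate{
#' \item composite covariance `Cc = C1 + C2`, eigendecomposed as
#'   `Cc = Fc psi Fc'`;
#' \item square-root whitening `P = psi^(-1/2) Fc'`, so that `P Cc P' = I`;
#' \item whitened class matrices `S1 = P C1 P'` and `S2 = P C2 P'`, which
#'   share eigenvectors `U` with eigenvalue diagonals satisfying
#'   `Lambda1 + Lambda2 = I`;
#' \item projection matrix `W = U' P`, rows ordered by descending preictal
#'   eigenvalue, so leading filters maximize preictal variance and trailing
#'   ones maximize interictal variance.
#' }
#' A ridge of `1e-10 * trace(Cc)` is added (with a message) if `Cc` is
#' conditioned worse than 1e12. Eigenvector signs are fixed by making the
#' first non-negligible coefficient positive, so the fit is reproducible.
#'
#' @param C1 preictal class covariance (symmetric positive-semidefinite).
#' @param C2 interictal class covariance, same dimension.
#' @return An object of class `csp_model` with all intermediates: `C1`,
#'   `C2`, `Cc`, `Fc`, `psi`, `P`, `U`, `lambda1`, `lambda2`, `W`.
#' @export
fit_csp <- function(C1, C2) {
  C1 <- unclass(as.matrix(C1)); C2 <- unclass(as.matrix(C2))
  if (!identical(dim(C1), dim(C2))) stop("covariance dimensions differ", call. = FALSE)
  if (max(abs(C1 - t(C1))) > 1e-8 || max(abs(C2 - t(C2))) > 1e-8) {
    stop("class covariances must be symmetric", call. = FALSE)
  }
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (ec$values[1L] <= 0) {
    stop("composite covariance is not positive-definite; supply more data",
         call. = FALSE)
  }
  if (min(ec$values) <= 0 || ec$values[1L] / min(ec$values) > 1e12) {
    ridge <- 1e-10 * sum(diag(Cc))
    message(sprintf("ill-conditioned composite covariance; adding ridge %.3g", ridge))
    Cc <- Cc + diag(ridge, nrow(Cc))
    ec <- eigen(Cc, symmetric = TRUE)
    if (min(ec$values) <= 0) {
      stop("composite covariance singular beyond regularization; supply more data or a larger ridge",
           call. = FALSE)
    }
  }
  Fc <- .fix_signs(ec$vectors)
  psi <- ec$values
  P <- diag(1 / sqrt(psi), length(psi)) %*% t(Fc)
  S1 <- P %*% C1 %*% t(P)
  S2 <- P %*% C2 %*% t(P)
  eu <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)  # values descending
  U <- .fix_signs(eu$vectors)
  lambda1 <- eu$values
  lambda2 <- diag(t(U) %*% S2 %*% U)
  W <- t(U) %*% P
  structure(
    list(C1 = C1, C2 = C2, Cc = Cc, Fc = Fc, psi = psi, P = P, U = U,
         lambda1 = lambda1, lambda2 = lambda2, W = W),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d spatial filters; preictal eigenvalues: %s\n",
              nrow(x$W), paste(sprintf("%.3f", x$lambda1), collapse = " ")))
  invisible(x)
}

#' Spatially filter an epoch
#'
#' Applies the CSP projection to a channels-by-samples epoch, returning one
#' filtered time series per spatial filter (`W X`; epochs are stored
#' channels x samples throughout the package).
#'
#' @param epoch channels-by-samples matrix.
#' @param model a `csp_model`, or a projection matrix `W` directly.
#' @return Filters-by-samples matrix.
#' @export
csp_project <- function(epoch, model) {
  W <- if (inherits(model, "csp_model")) model$W else as.matrix(model)
  epoch <- as.matrix(epoch)
  if (ncol(W) != nrow(epoch)) {
    stop(sprintf("dimension mismatch: model has %d channels, epoch has %d",
                 ncol(W), nrow(epoch)), call. = FALSE)
  }
  W %*% epoch
}

#' Log-variance feature vector
#'
#' The classical CSP feature: the natural log of the sample variance of each
#' spatially filtered row.
#'
#' @param projected filters-by-samples matrix (>= 2 samples).
#' @return Numeric vector, one feature per filter.
#' @export
log_variance_features <- function(projected) {
  projected <- as.matrix(projected)
  if (ncol(projected) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- unname(apply(projected, 1L, stats::var))
  if (any(v <= 0)) {
    stop("degenerate projection: a filtered row has zero variance", call. = FALSE)
  }
  log(v)
}

# ---- fast path over precomputed epoch cross-products -----------------------
# For a fixed record set the per-epoch 2nd-moment matrices are computed once
# and reused across cross-validation rounds:
#   raw:      vec(D D' / tr(D D'))  -> class-mean covariances by rowMeans
#   centered: vec(Dc Dc')           -> log-variance features as
#             log(diag(W M W') / (L-1)) via the row-wise Kronecker trick.

.epoch_xprods <- function(es) {
  n <- nrow(es$recording$signal)
  k <- n_epochs(es)
  raw <- matrix(0, n * n, k)
  cen <- matrix(0, n * n, k)
  for (i in seq_len(k)) {
    D <- epoch_matrix(es, i)
    M <- tcrossprod(D)
    raw[, i] <- as.numeric(M / sum(diag(M)))
    Dc <- D - rowMeans(D)
    cen[, i] <- as.numeric(tcrossprod(Dc))
  }
  list(raw = raw, centered = cen, n_channels = n, window_n = es$window_n)
}

.mean_cov_from_xprods <- function(xp, idx) {
  if (!length(idx)) stop("no epochs in class", call. = FALSE)
  m <- matrix(rowMeans(xp$raw[, idx, drop = FALSE]), xp$n_channels, xp$n_channels)
  structure((m + t(m)) / 2, class = "csp_cov", n_source = length(idx))
}

.features_from_xprods <- function(W, xp, idx = seq_len(ncol(xp$centered))) {
  K <- t(apply(W, 1L, function(w) as.numeric(outer(w, w))))  # n x n^2
  v <- K %*% xp$centered[, idx, drop = FALSE] / (xp$window_n - 1L)
  if (any(v <= 0)) stop("degenerate projection in feature fast path", call. = FALSE)
  t(log(v))  # epochs x filters
}

#' Log-variance CSP features for every epoch of an epoch set
#'
#' Convenience wrapper: projects each epoch with the model and extracts the
#' log-variance features, returning an epochs-by-filters matrix.
#'
#' @param es an `epoch_set`.
#' @param model a `csp_model` or projection matrix.
#' @param idx optional epoch indices to restrict to.
#' @return Numeric matrix, one row per epoch.
#' @export
csp_features <- function(es, model, idx = seq_len(n_epochs(es))) {
  W <- if (inherits(model, "csp_model")) model$W else as.matrix(model)
  out <- matrix(0, length(idx), nrow(W))
  for (j in seq_along(idx)) {
    out[j, ] <- log_variance_features(csp_project(epoch_matrix(es, idx[j]), W))
  }
  out
}
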