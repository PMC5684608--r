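# Independent brute-force oracles and fixture builders shared across tests.

# random symmetric positive-definite matrix
rand_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}

# epoch count by explicit enumeration of window start times
brute_epoch_count <- function(duration, window, step) {
  k <- 0L
  s <- 0
  while (s + window <= duration + 1e-9) {
    k <- k + 1L
    s <- s + step
  }
  k
}

# per-position sliding median with symmetric edge reflection
brute_sliding_median <- function(x, order) {
  n <- length(x)
  h <- (order - 1L) %/% 2L
  refl <- function(j) {
    while (j < 1L || j > n) {
      if (j < 1L) j <- 1L - j
      if (j > n) j <- 2L * n + 1L - j
    }
    j
  }
  vapply(seq_len(n), function(i) {
    median(x[vapply((i - h):(i + h), refl, integer(1))])
  }, numeric(1))
}

# one alarm per maximal 1-run of length >= alpha, via run-length encoding
brute_run_alarms <- function(values, times, alpha) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values == 1L & r$lengths >= alpha)
  times[starts[idx] + alpha - 1L]
}

# draw epochs (channels x len) from a fixed spatial covariance
draw_epochs <- function(C, k, len, seed) {
  L <- t(chol(C))
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) L %*% matrix(rnorm(nrow(C) * len), nrow(C), len))
  })
}

# synthetic patient: n_rec consecutive recordings of rec_len seconds,
# a seizure late in every odd recording, even recordings seizure-free
build_synth_set <- function(separation, seed, fs = 256, n_rec = 6,
                            rec_len = 600, n_channels = 8) {
  onsets <- (seq(1, n_rec, by = 2) - 1) * rec_len + rec_len - 60
  spec <- make_state_covariances(n_channels, separation, seed = seed)
  tl <- timeline_spec(n_rec * rec_len, seizure_onsets = onsets,
                      seizure_durations = 40, preictal_len_s = 180,
                      fs = fs, seed = seed)
  simulate_record_set(tl, spec, record_len_s = rec_len)
}

# CSP + LDA trained on one subset of recordings, epoch accuracy on another;
# uses only exported functions so it exercises the public pipeline surface
heldout_epoch_accuracy <- function(rs, train_ids, test_ids,
                                   seg = segmentation_config(),
                                   shrinkage = 1e-3, seed = 1L,
                                   return_model = FALSE) {
  ann <- apply_seizure_policy(rs$annotations, postictal_len = seg$postictal_s,
                              min_preictal = seg$preictal_len_s,
                              coverage = rs$coverage)
  eslist <- lapply(rs$recordings, sliding_epochs, config = seg)
  lab <- label_epochs(eslist, ann, seg, gaps = rs$gaps)

  class_cov <- function(ids, cls, train_only) {
    covs <- list()
    for (rid in ids) {
      li <- lab[lab$record_id == rid, ]
      idx <- if (train_only) li$epoch[li$class == cls & li$interictal_train]
             else li$epoch[li$class == cls]
      covs <- c(covs, lapply(idx, function(i)
        normalized_covariance(epoch_matrix(eslist[[rid]], i))))
    }
    covs
  }
  feats <- function(ids, model) {
    X <- NULL; y <- NULL
    for (rid in ids) {
      li <- lab[lab$record_id == rid, ]
      i_pre <- li$epoch[li$class == "preictal"]
      i_int <- li$epoch[li$class == "interictal"]
      if (length(i_pre)) X <- rbind(X, csp_features(eslist[[rid]], model, i_pre))
      if (length(i_int)) X <- rbind(X, csp_features(eslist[[rid]], model, i_int))
      y <- c(y, rep(c(1L, 0L), c(length(i_pre), length(i_int))))
    }
    list(X = X, y = y)
  }

  model <- fit_csp(class_mean_covariance(class_cov(train_ids, "preictal", FALSE)),
                   class_mean_covariance(class_cov(train_ids, "interictal", TRUE)))
  tr <- feats(train_ids, model)
  bal <- undersample(tr$X, tr$y, seed = seed)
  lda <- fit_lda(bal$features, bal$labels, shrinkage = shrinkage)
  te <- feats(test_ids, model)
  pred <- predict_series(lda, te$X)$values
  acc <- mean(pred == te$y)
  if (return_model) list(accuracy = acc, csp = model, lda = lda) else acc
}

# downstream epoch accuracy as a function of covariance separation
accuracy_at_separation <- function(separation, seed, n_channels = 8,
                                   len = 192, n_train = 60, n_test = 40) {
  spec <- make_state_covariances(n_channels, separation, seed = seed)
  ep <- function(C, k, s) draw_epochs(C, k, len, s)
  covs <- function(es) lapply(es, normalized_covariance)
  tr1 <- ep(spec$preictal_cov, n_train, seed + 1L)
  tr0 <- ep(spec$interictal_cov, n_train, seed + 2L)
  model <- fit_csp(class_mean_covariance(covs(tr1)),
                   class_mean_covariance(covs(tr0)))
  fx <- function(es) t(vapply(es, function(e)
    log_variance_features(csp_project(e, model)), numeric(n_channels)))
  lda <- fit_lda(rbind(fx(tr1), fx(tr0)), rep(c(1L, 0L), each = n_train))
  te1 <- ep(spec$preictal_cov, n_test, seed + 3L)
  te0 <- ep(spec$interictal_cov, n_test, seed + 4L)
  pred <- predict_series(lda, rbind(fx(te1), fx(te0)))$values
  mean(pred == rep(c(1L, 0L), each = n_test))
}
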