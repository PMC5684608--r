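#' Run configuration for the full predictor
#'
#' Bundles segmentation, classifier and alarm settings for a pipeline run.
#'
#' @param seg a [segmentation_config()].
#' @param alarm an [alarm_config()].
#' @param shrinkage LDA shrinkage coefficient.
#' @param median_order median filter order (odd).
#' @param inner_folds folds for inner alpha selection (default 5; capped at
#'   the number of training recordings).
#' @param seed base seed; per-round undersampling seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seg = segmentation_config(), alarm = alarm_config(),
                       shrinkage = 1e-3, median_order = 7L, inner_folds = 5L,
                       seed = 1L) {
  structure(list(seg = seg, alarm = alarm, shrinkage = shrinkage,
                 median_order = median_order, inner_folds = inner_folds,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Per-record preprocessed state reused across cross-validation rounds:
# epoch geometry, labels and epoch-level cross products.
.prepare_records <- function(rs, config) {
  ann <- apply_seizure_policy(rs$annotations,
                              postictal_len = config$alarm$postictal_s,
                              min_preictal = config$seg$preictal_len_s +
                                config$seg$preictal_offset_s,
                              coverage = rs$coverage)
  prep <- lapply(rs$recordings, function(r) {
    es <- sliding_epochs(r, config$seg)
    list(es = es, xp = .epoch_xprods(es))
  })
  labels <- label_epochs(lapply(prep, `[[`, "es"), ann, config$seg, gaps = rs$gaps)
  list(ann = ann, prep = prep, labels = labels)
}

# fit CSP + LDA from the labeled epochs of the given record ids
.fit_round <- function(state, train_ids, config, seed) {
  lab <- state$labels
  covs1 <- list(); covs2 <- list()
  feats_parts <- list(); y_parts <- list()
  pre_n <- 0L
  for (rid in train_ids) {
    li <- lab[lab$record_id == rid, , drop = FALSE]
    xp <- state$prep[[rid]]$xp
    i_pre <- li$epoch[li$class == "preictal"]
    i_int <- li$epoch[li$class == "interictal" & li$interictal_train]
    if (length(i_pre)) covs1 <- c(covs1, list(.mean_cov_from_xprods(xp, i_pre)))
    if (length(i_int)) covs2 <- c(covs2, list(.mean_cov_from_xprods(xp, i_int)))
    pre_n <- pre_n + length(i_pre)
  }
  if (!length(covs1) || !length(covs2)) return(NULL)
  # weight per-record means by their epoch counts
  wsum <- function(cl) {
    ns <- vapply(cl, attr, integer(1), "n_source")
    M <- Reduce(`+`, Map(function(m, w) unclass(m) * w, cl, ns)) / sum(ns)
    structure((M + t(M)) / 2, class = "csp_cov", n_source = sum(ns))
  }
  model <- fit_csp(wsum(covs1), wsum(covs2))
  for (rid in train_ids) {
    li <- lab[lab$record_id == rid, , drop = FALSE]
    xp <- state$prep[[rid]]$xp
    i_pre <- li$epoch[li$class == "preictal"]
    i_int <- li$epoch[li$class == "interictal" & li$interictal_train]
    idx <- c(i_pre, i_int)
    if (!length(idx)) next
    feats_parts <- c(feats_parts, list(.features_from_xprods(model$W, xp, idx)))
    y_parts <- c(y_parts, list(rep(c(1L, 0L), c(length(i_pre), length(i_int)))))
  }
  X <- do.call(rbind, feats_parts)
  y <- unlist(y_parts)
  bal <- undersample(X, y, seed = seed)
  lda <- fit_lda(bal$features, bal$labels, shrinkage = config$shrinkage)
  list(csp = model, lda = lda, n_preictal = pre_n)
}

# smoothed decision series for one record under a fitted round
.record_series <- function(state, rid, fit, config) {
  xp <- state$prep[[rid]]$xp
  es <- state$prep[[rid]]$es
  if (!n_epochs(es)) return(NULL)
  X <- .features_from_xprods(fit$csp$W, xp)
  s <- predict_series(fit$lda, X, times = es$times, step_s = config$seg$step_s)
  median_smooth(s, order = config$median_order)
}

# seizures of a record, in global time, from the policy-applied table
.record_seizures <- function(state, rid) {
  a <- state$ann
  a[!is.na(a$record_id) & a$record_id == rid, , drop = FALSE]
}

#' Leave-one-recording-out evaluation of the full predictor
#'
#' For each recording of the set, fits CSP and the linear discriminant on
#' the remaining recordings (preictal epochs from their seizures,
#' interictal epochs from their seizure-free records, balanced by random
#' undersampling), selects the run-length threshold `alpha` by inner
#' cross-validation over the training recordings (unless the config fixes
#' it), then freezes all parameters and evaluates alarms on the held-out
#' recording. Rounds without preictal training epochs are skipped with a
#' logged reason. Averages are arithmetic means over rounds where a metric
#' is applicable (e.g. sensitivity only over rounds whose held-out recording
#' contains an evaluable seizure).
#'
#' @param rs a `record_set` with at least two recordings and at least one
#'   non-excluded seizure.
#' @param config a [run_config()].
#' @return An object of class `cv_report`: list with `rounds` (per-round
#'   list: `record_id`, `alpha`, `train_ids`, `result`, `skipped`),
#'   `average` (named numeric vector), `config`.
#' @export
loocv_run <- function(rs, config = run_config()) {
  if (length(rs$recordings) < 2L) {
    stop("leave-one-out needs at least 2 recordings", call. = FALSE)
  }
  state <- .prepare_records(rs, config)
  if (!any(!state$ann$excluded)) {
    stop("no evaluable seizure in the record set", call. = FALSE)
  }
  ids <- names(rs$recordings)
  rounds <- vector("list", length(ids))

  for (r in seq_along(ids)) {
    held <- ids[r]
    train_ids <- setdiff(ids, held)
    seed_r <- config$seed + 101L * r
    fit <- .fit_round(state, train_ids, config, seed = seed_r)
    if (is.null(fit)) {
      message(sprintf("round %d (%s) skipped: no preictal or interictal training epochs",
                      r, held))
      rounds[[r]] <- list(record_id = held, skipped = TRUE,
                          reason = "no training epochs for one class")
      next
    }
    alpha <- config$alarm$alpha
    if (is.null(alpha)) {
      alpha <- .inner_alpha(state, train_ids, config, seed_r)
    }
    series <- .record_series(state, held, fit, config)
    alarms <- if (is.null(series)) numeric(0) else raise_alarms(series, alpha)
    res <- evaluate_alarms(alarms, .record_seizures(state, held),
                           coverage = rec_interval(rs$recordings[[held]]),
                           config = config$alarm, gaps = rs$gaps)
    rounds[[r]] <- list(record_id = held, skipped = FALSE, alpha = alpha,
                        train_ids = train_ids, result = res)
  }

  done <- Filter(function(x) !isTRUE(x$skipped), rounds)
  pick <- function(f) vapply(done, function(x) f(x$result), numeric(1))
  avg <- c(sensitivity = mean(pick(function(z) z$sensitivity), na.rm = TRUE),
           specificity = mean(pick(function(z) z$specificity), na.rm = TRUE),
           fpr = mean(pick(function(z) z$fpr), na.rm = TRUE),
           mean_prediction_time_min =
             mean(pick(function(z) z$mean_prediction_time_min), na.rm = TRUE))
  structure(list(rounds = rounds, average = avg, config = config,
                 patient_id = rs$patient_id),
            class = "cv_report")
}

# inner alpha selection: split training recordings into folds; each fold's
# series comes from a model fit on the other folds
.inner_alpha <- function(state, train_ids, config, seed_r) {
  k <- max(2L, min(config$inner_folds, length(train_ids)))
  fold_of <- rep_len(seq_len(k), length(train_ids))
  runs <- list()
  for (f in seq_len(k)) {
    inner_train <- train_ids[fold_of != f]
    inner_val <- train_ids[fold_of == f]
    fit <- .fit_round(state, inner_train, config, seed = seed_r + f)
    if (is.null(fit)) next
    for (rid in inner_val) {
      series <- .record_series(state, rid, fit, config)
      if (is.null(series)) next
      runs <- c(runs, list(list(series = series,
                                seizures = .record_seizures(state, rid),
                                coverage = rec_interval(state$prep[[rid]]$es$recording))))
    }
  }
  n_sz <- sum(vapply(runs, function(r) sum(!r$seizures$excluded), numeric(1)))
  if (!length(runs) || n_sz == 0) {
    warning("inner folds yielded no evaluable training seizure; using the most conservative alpha",
            call. = FALSE)
    return(max(config$alarm$alpha_grid))
  }
  select_alpha(runs, config$alarm$horizon_s, config$alarm$alpha_grid,
               gaps = NULL, postictal_s = config$alarm$postictal_s,
               gap_margin_s = config$alarm$gap_margin_s)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report '%s'> %d rounds (%d evaluated)\n", x$patient_id,
              length(x$rounds), sum(!vapply(x$rounds, function(r)
                isTRUE(r$skipped), logical(1)))))
  cat(sprintf("  avg sens %.3f | spec %.3f | FPR %.3f/h | pred time %.1f min\n",
              x$average["sensitivity"], x$average["specificity"],
              x$average["fpr"], x$average["mean_prediction_time_min"]))
  invisible(x)
}

#' Per-round metric table of a cross-validation report
#'
#' @param report a `cv_report`.
#' @return Data frame with one row per evaluated round: `record_id`,
#'   `alpha`, `sensitivity`, `specificity`, `fpr`,
#'   `mean_prediction_time_min`, `n_false`, `evaluated_h`.
#' @export
cv_round_table <- function(report) {
  done <- Filter(function(x) !isTRUE(x$skipped), report$rounds)
  do.call(rbind, lapply(done, function(r) {
    data.frame(record_id = r$record_id, alpha = r$alpha,
               sensitivity = r$result$sensitivity,
               specificity = r$result$specificity,
               fpr = r$result$fpr,
               mean_prediction_time_min = r$result$mean_prediction_time_min,
               n_false = r$result$n_false,
               evaluated_h = r$result$evaluated_h,
               stringsAsFactors = FALSE)
  }))
}
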