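#' Extract peri-peak pyramidal LFP traces
#'
#' Fixed-length 200-ms traces centred on each ripple peak, for waveform
#' featurization.
#' @param lfp_pyr pyramidal-layer trace.
#' @param peak_times_s event peaks (s).
#' @param fs sampling rate (Hz).
#' @param window_ms full window (default 200).
#' @return events x samples matrix; edge events dropped (attribute `kept`).
#' @export
ripple_traces <- function(lfp_pyr, peak_times_s, fs, window_ms = 200) {
  half <- round(window_ms / 2000 * fs)
  peaks <- round(peak_times_s * fs) + 1L
  kept <- which(peaks - half >= 1L & peaks + half - 1L <= length(lfp_pyr))
  out <- t(vapply(peaks[kept], function(p) lfp_pyr[(p - half):(p + half - 1L)],
                  numeric(2L * half)))
  attr(out, "kept") <- kept
  out
}

#' Waveform features: low-pass, per-trace z-score, PCA
#'
#' Each trace is low-pass filtered at 30 Hz (4th-order zero-phase
#' Butterworth) to isolate the sharp-wave component, z-scored per trace, and
#' projected on the first `n_comp` principal components. When `basis` is
#' given (from a training fold) the traces are projected onto it instead of
#' fitting a new PCA, so no test information leaks into the embedding.
#'
#' @param traces events x samples matrix of equal-length peri-peak traces.
#' @param fs sampling rate (Hz).
#' @param n_comp number of components (default 6).
#' @param basis optional feature basis returned by a previous call.
#' @return list of class `waveform_features`: `features` (events x n_comp),
#'   `basis` (list with `rotation`, `center`), `n_comp`.
#' @export
preprocess_waveforms <- function(traces, fs, n_comp = 6, basis = NULL) {
  if (is.null(dim(traces)) || any(is.na(traces))) {
    stop("preprocess_waveforms: traces must form a complete matrix of equal length")
  }
  filt <- t(apply(traces, 1L, lowpass, cutoff_hz = 30, fs = fs))
  z <- t(scale(t(filt)))  # per-trace z-score
  z[!is.finite(z)] <- 0
  if (is.null(basis)) {
    p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    k <- min(n_comp, ncol(p$rotation))
    basis <- list(rotation = p$rotation[, seq_len(k), drop = FALSE],
                  center = p$center)
    feats <- p$x[, seq_len(k), drop = FALSE]
  } else {
    feats <- sweep(z, 2L, basis$center) %*% basis$rotation
  }
  structure(list(features = feats, basis = basis, n_comp = ncol(feats)),
            class = "waveform_features")
}

#' Cross-validated explained variance of layer CSD from LFP features
#'
#' For each CA1 layer, a linear regression predicts the per-ripple
#' (unit-variance normalized) CSD from the waveform features over 20 random
#' 80/20 splits; the reported R^2 = 1 - SSE/SST on the test split, averaged.
#' Chance comes from refitting after shuffling the CSD values across
#' ripples.
#'
#' @param features events x p feature matrix.
#' @param csd_by_layer events x layers matrix (columns named by layer).
#' @param n_splits number of random splits (default 20).
#' @param n_shuffle shuffles for the chance distribution (default 500).
#' @param seed RNG seed.
#' @return data frame per layer: `r2`, `chance_mean`, `chance_hi`
#'   (97.5th percentile of shuffled R^2).
#' @export
explain_csd_from_lfp <- function(features, csd_by_layer, n_splits = 20,
                                 n_shuffle = 500, seed = 1L) {
  n <- nrow(features)
  if (n < 10L) stop("explain_csd_from_lfp: need at least 10 ripples")
  set.seed(seed)
  X <- cbind(1, features)
  cv_r2 <- function(y) {
    mean(vapply(seq_len(n_splits), function(s) {
      tr <- sample.int(n, round(0.8 * n))
      te <- setdiff(seq_len(n), tr)
      b <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])$coefficients
      b[is.na(b)] <- 0
      pred <- X[te, , drop = FALSE] %*% b
      1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[te]))^2)
    }, numeric(1)))
  }
  res <- lapply(colnames(csd_by_layer), function(layer) {
    y <- csd_by_layer[, layer]
    y <- y / stats::sd(y)
    obs <- cv_r2(y)
    chance <- vapply(seq_len(n_shuffle), function(i) {
      ys <- sample(y)
      tr <- sample.int(n, round(0.8 * n))
      te <- setdiff(seq_len(n), tr)
      b <- stats::lm.fit(X[tr, , drop = FALSE], ys[tr])$coefficients
      b[is.na(b)] <- 0
      pred <- X[te, , drop = FALSE] %*% b
      1 - sum((ys[te] - pred)^2) / sum((ys[te] - mean(ys[te]))^2)
    }, numeric(1))
    data.frame(layer = layer, r2 = obs, chance_mean = mean(chance),
               chance_hi = stats::quantile(chance, 0.975, names = FALSE))
  })
  do.call(rbind, res)
}

#' LDA ripple-type classifier with leave-one-subject-out validation
#'
#' Trains a linear discriminant classifier to predict the CSD-based ripple
#' class (Rad / intermediate / LM) from the pyramidal waveform features.
#' Validation leaves each subject out in turn; within each fold the training
#' classes are downsampled to the smallest class, repeated `n_repeats`
#' times, and for every repeat a label-shuffled null model is trained
#' identically. The chance-normalized gain is
#' `100 * (mean true accuracy - mean null accuracy) / mean null accuracy`.
#'
#' @param traces events x samples raw trace matrix (features are re-derived
#'   inside each fold from training data only).
#' @param labels class labels per event (3 classes).
#' @param subject_ids subject identifier per event (>= 2 subjects).
#' @param fs sampling rate (Hz).
#' @param n_repeats balanced-resampling repeats per fold (default 100;
#'   increase to 1000 for full runs).
#' @param n_comp PCA components (default 6).
#' @param seed RNG seed.
#' @return list of class `classifier_report`: `folds` (per-subject mean true
#'   and null accuracies), `gain_pct`, `acc_true`, `acc_null`, per-repeat
#'   accuracy draws, and `final_model` fit on all subjects (list with
#'   `basis` and the trained `MASS::lda` object).
#' @export
train_ripple_lda <- function(traces, labels, subject_ids, fs,
                             n_repeats = 100, n_comp = 6, seed = 1L) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2L) stop("train_ripple_lda: need at least 2 subjects")
  labels <- as.character(labels)
  set.seed(seed)
  folds <- list()
  for (s in subjects) {
    te <- subject_ids == s
    tr <- !te
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 1L) {
      warning(sprintf("train_ripple_lda: subject %s lacks classes; fold skipped", s))
      next
    }
    wf_tr <- preprocess_waveforms(traces[tr, , drop = FALSE], fs, n_comp)
    wf_te <- preprocess_waveforms(traces[te, , drop = FALSE], fs, n_comp,
                                  basis = wf_tr$basis)
    ytr <- labels[tr]; yte <- labels[te]
    n_min <- min(table(ytr))
    acc_t <- acc_n <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      idx <- unlist(lapply(split(seq_along(ytr), ytr),
                           function(ix) sample(ix, n_min)))
      fit <- MASS::lda(wf_tr$features[idx, , drop = FALSE],
                       grouping = factor(ytr[idx]))
      pred <- stats::predict(fit, wf_te$features)$class
      acc_t[r] <- mean(as.character(pred) == yte)
      ysh <- sample(ytr[idx])
      fit0 <- MASS::lda(wf_tr$features[idx, , drop = FALSE],
                        grouping = factor(ysh))
      pred0 <- stats::predict(fit0, wf_te$features)$class
      acc_n[r] <- mean(as.character(pred0) == yte)
    }
    folds[[as.character(s)]] <- list(acc_true = acc_t, acc_null = acc_n)
  }
  if (length(folds) == 0L) stop("train_ripple_lda: all folds skipped")
  acc_true <- vapply(folds, function(f) mean(f$acc_true), numeric(1))
  acc_null <- vapply(folds, function(f) mean(f$acc_null), numeric(1))
  gain <- 100 * (mean(acc_true) - mean(acc_null)) / mean(acc_null)
  wf_all <- preprocess_waveforms(traces, fs, n_comp)
  n_min <- min(table(labels))
  idx <- unlist(lapply(split(seq_along(labels), labels),
                       function(ix) sample(ix, n_min)))
  final <- MASS::lda(wf_all$features[idx, , drop = FALSE],
                     grouping = factor(labels[idx]))
  structure(list(folds = folds, acc_true = acc_true, acc_null = acc_null,
                 gain_pct = gain,
                 final_model = list(basis = wf_all$basis, lda = final,
                                    n_comp = n_comp)),
            class = "classifier_report")
}

#' Predicted-class mean CSD at sink-optimal lags
#'
#' Validates that predicted classes recover the expected sink polarity: sink
#' lags are estimated on the training set (the LM class aligned to the
#' deepest lacunosum-moleculare sink, the others to the deepest radiatum
#' sink), and per predicted class the mean CSD in a 10-ms window at those
#' lags is computed on held-out events.
#'
#' @param pred_labels predicted class per test event.
#' @param csd_rad,csd_lm events x time matrices of layer CSD around the peak
#'   (train and test stacked; rows aligned with `train_mask`).
#' @param train_mask logical: rows used for lag estimation.
#' @param fs sampling rate (Hz).
#' @return data frame per class: `class`, `mean_rad_csd`, `mean_lm_csd`
#'   (`NA` for classes with no members).
#' @export
validate_predicted_csd <- function(pred_labels, csd_rad, csd_lm, train_mask, fs) {
  nt <- ncol(csd_rad)
  win <- round(0.005 * fs)
  lag_rad <- which.min(colMeans(csd_rad[train_mask, , drop = FALSE]))
  lag_lm <- which.min(colMeans(csd_lm[train_mask, , drop = FALSE]))
  win_at <- function(center) max(1L, center - win):min(nt, center + win)
  te <- which(!train_mask)
  classes <- c("Rad", "intermediate", "LM")
  res <- lapply(classes, function(cl) {
    rows <- te[pred_labels == cl]
    if (length(rows) == 0L) {
      return(data.frame(class = cl, mean_rad_csd = NA_real_,
                        mean_lm_csd = NA_real_))
    }
    lag <- if (cl == "LM") lag_lm else lag_rad
    data.frame(class = cl,
               mean_rad_csd = mean(csd_rad[rows, win_at(lag), drop = FALSE]),
               mean_lm_csd = mean(csd_lm[rows, win_at(lag), drop = FALSE]))
  })
  do.call(rbind, res)
}

#' Discrimination index for Rad/LM predictions
#'
#' For each of the two extreme classes the ratio of correctly classified
#' events to events misclassified as the opposite class; the smaller of the
#' two ratios is returned (conservative rule). Zero misclassifications give
#' `Inf`.
#'
#' @param predictions predicted labels ("Rad"/"LM", others ignored).
#' @param truth true labels.
#' @return scalar >= 0, possibly `Inf`.
#' @export
discrimination_index <- function(predictions, truth) {
  ratio <- function(cl, other) {
    correct <- sum(predictions == cl & truth == cl)
    swapped <- sum(predictions == other & truth == cl)
    if (swapped == 0L) Inf else correct / swapped
  }
  min(ratio("Rad", "LM"), ratio("LM", "Rad"))
}
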