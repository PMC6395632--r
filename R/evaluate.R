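# Train/test evaluation and cross-validation schemes (repeated
# stratified k-fold and jackknife). Supervised components -- positional
# profiles, feature ranking, the classifier -- are refit on each
# training fold by default; `paper_mode = TRUE` fits the profiles once
# on the full dataset before splitting (the convention some published
# predictors used; it leaks label information across folds and is kept
# only for comparison).

#' Pipeline configuration
#'
#' Collects every knob of the encode-rank-select-classify pipeline in
#' one validated list. Unknown arguments are rejected so that typos in
#' configs fail loudly.
#'
#' @param encoders encoder names in block order (see
#'   [encode_features()]).
#' @param lam,w pseudo amino acid composition parameters.
#' @param selection `"none"`, `"ig"` or `"mrmd"`: how to rank features
#'   before truncation.
#' @param variant MRMD distance variant (ignored for IG).
#' @param dimension number of top-ranked features kept; `NULL` keeps
#'   all.
#' @param classifier an [sno_classifier()] spec or its name.
#' @param smoothing Laplace pseudocount for the positional profiles.
#' @param seed integer seed controlling all pipeline randomness.
#' @return A validated list of class `sno_config`.
#' @export
sno_config <- function(encoders = ENCODERS, lam = 5L, w = 0.5,
                       selection = c("none", "ig", "mrmd"),
                       variant = c("ed", "cos", "tc", "mean"),
                       dimension = NULL,
                       classifier = sno_classifier("svm"),
                       smoothing = 0, seed = 1L) {
  selection <- match.arg(selection)
  variant <- match.arg(variant)
  if (is.character(classifier)) classifier <- sno_classifier(classifier)
  stopifnot(is.list(classifier), is.function(classifier$fit),
            is.function(classifier$predict))
  unknown <- setdiff(encoders, ENCODERS)
  if (length(unknown))
    stop("unknown encoder(s): ", paste(unknown, collapse = ", "))
  structure(list(encoders = encoders, lam = as.integer(lam), w = w,
                 selection = selection, variant = variant,
                 dimension = if (!is.null(dimension)) as.integer(dimension),
                 classifier = classifier, smoothing = smoothing,
                 seed = as.integer(seed)),
            class = "sno_config")
}

# Fit the full pipeline on a training set; returns everything needed to
# encode and classify new windows.
fit_pipeline <- function(train, config, profile = NULL) {
  needs_profile <- any(config$encoders %in% PROFILE_ENCODERS)
  if (needs_profile && is.null(profile))
    profile <- fit_positional_profiles(train, smoothing = config$smoothing)
  X <- encode_features(train, encoders = config$encoders,
                       profile = profile, lam = config$lam, w = config$w)
  features <- colnames(X)
  if (config$selection != "none" && !is.null(config$dimension) &&
      config$dimension < ncol(X)) {
    rk <- if (config$selection == "ig") {
      rank_features_ig(X, train$label)
    } else {
      mrmd_rank(X, train$label, variant = config$variant)
    }
    features <- rk$order[seq_len(config$dimension)]
    X <- subset_features(X, features)
  }
  scaler <- fit_scaler(X)
  state <- config$classifier$fit(apply_scaler(scaler, X), train$label)
  list(config = config, profile = profile, features = features,
       scaler = scaler, state = state)
}

predict_pipeline <- function(fitted, dataset) {
  X <- encode_features(dataset, encoders = fitted$config$encoders,
                       profile = fitted$profile, lam = fitted$config$lam,
                       w = fitted$config$w)
  X <- subset_features(X, fitted$features)
  fitted$config$classifier$predict(fitted$state,
                                   apply_scaler(fitted$scaler, X))
}

#' Train on one dataset, evaluate on another
#'
#' Fits positional profiles, feature selection and the classifier on
#' `train` only, then scores `test`; the anti-leakage contract of the
#' whole package.
#'
#' @param train,test labeled [sno_dataset]s with the same window
#'   half-width.
#' @param config an [sno_config()].
#' @return List with `predictions` (data frame: `peptide`, `score`,
#'   `label`, `truth`) and `metrics` ([sno_metrics][compute_metrics]).
#' @export
train_predict <- function(train, test, config = sno_config()) {
  if (window_t(train) != window_t(test))
    stop("train and test window half-widths differ")
  set.seed(config$seed)
  fitted <- fit_pipeline(train, config)
  out <- predict_pipeline(fitted, test)
  list(predictions = data.frame(peptide = test$peptide,
                                score = out$score,
                                label = out$label,
                                truth = test$label,
                                stringsAsFactors = FALSE),
       metrics = compute_metrics(test$label, out$label,
                                 warn_degenerate = FALSE))
}

# Selection + scaling + classification on already-encoded matrices
# (rows of Xte were encoded with profiles fitted on the Xtr rows only).
select_fit_predict <- function(Xtr, ytr, Xte, config) {
  features <- colnames(Xtr)
  if (config$selection != "none" && !is.null(config$dimension) &&
      config$dimension < ncol(Xtr)) {
    rk <- if (config$selection == "ig") rank_features_ig(Xtr, ytr)
          else mrmd_rank(Xtr, ytr, variant = config$variant)
    features <- rk$order[seq_len(config$dimension)]
    Xtr <- Xtr[, features, drop = FALSE]
    Xte <- Xte[, features, drop = FALSE]
  }
  scaler <- fit_scaler(Xtr)
  state <- config$classifier$fit(apply_scaler(scaler, Xtr), ytr)
  config$classifier$predict(state, apply_scaler(scaler, Xte))
}

# Seeded stratified fold assignment: within each class, shuffle and deal
# into k folds round-robin.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated evaluation
#'
#' Repeated stratified k-fold cross-validation or the jackknife
#' (leave-one-out). Every supervised stage -- positional profiles,
#' feature ranking/selection, feature scaling, classifier -- is refit on
#' each training fold; `paper_mode = TRUE` instead fits the positional
#' profiles once on the complete dataset (leaky; for comparison with
#' predictors that did so). Confusion counts are pooled within each
#' repeat; the summary reports the per-repeat metrics plus their mean
#' and the best (maximum-accuracy) repeat.
#'
#' @param dataset a labeled [sno_dataset].
#' @param scheme `"kfold"` or `"jackknife"`.
#' @param k number of folds (ignored for jackknife, where k = N).
#' @param repeats number of repetitions with different fold seeds
#'   (jackknife is deterministic; repeats forced to 1).
#' @param config an [sno_config()].
#' @param paper_mode logical; fit profiles once on the full dataset.
#' @return Object of class `sno_cv`: list with `per_repeat` (list of
#'   [sno_metrics][compute_metrics]), `mean` and `max` summaries, and
#'   the call parameters.
#' @export
cross_validate <- function(dataset, scheme = c("kfold", "jackknife"),
                           k = 10L, repeats = 1L, config = sno_config(),
                           paper_mode = FALSE) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset)
  if (any(is.na(dataset$label))) stop("dataset must be fully labeled")
  if (scheme == "jackknife") { k <- n; repeats <- 1L }
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of windows")
  prof_enc <- intersect(config$encoders, PROFILE_ENCODERS)
  comp_enc <- intersect(config$encoders, COMPOSITION_ENCODERS)
  full_profile <- NULL
  if (paper_mode && length(prof_enc))
    full_profile <- fit_positional_profiles(dataset,
                                            smoothing = config$smoothing)
  # composition blocks depend only on the window: encode once
  Xcomp <- if (length(comp_enc))
    encode_features(dataset, encoders = comp_enc,
                    lam = config$lam, w = config$w)
  assemble <- function(Xprof) {
    comp_b <- attr(Xcomp, "blocks"); prof_b <- attr(Xprof, "blocks")
    do.call(cbind, lapply(config$encoders, function(e) {
      if (e %in% comp_enc) Xcomp[, comp_b[[e]], drop = FALSE]
      else Xprof[, prof_b[[e]], drop = FALSE]
    }))
  }
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- if (scheme == "jackknife") seq_len(n)
             else stratified_folds(dataset$label, k,
                                   seed = config$seed + r - 1L)
    tp <- fp <- tn <- fn <- 0L
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      if (!length(test_idx)) next
      set.seed(config$seed * 1000L + r * 100L + f)
      if (length(prof_enc)) {
        profile <- if (!is.null(full_profile)) full_profile
                   else {
                     train <- dataset[-test_idx, , drop = FALSE]
                     attr(train, "t") <- window_t(dataset)
                     class(train) <- class(dataset)
                     fit_positional_profiles(train,
                                             smoothing = config$smoothing)
                   }
        Xprof <- encode_features(dataset$peptide, encoders = prof_enc,
                                 profile = profile)
        X <- assemble(Xprof)
      } else {
        X <- Xcomp
      }
      out <- select_fit_predict(X[-test_idx, , drop = FALSE],
                                dataset$label[-test_idx],
                                X[test_idx, , drop = FALSE], config)
      truth <- dataset$label[test_idx]
      tp <- tp + sum(truth == 1L & out$label == 1L)
      fp <- fp + sum(truth == 0L & out$label == 1L)
      tn <- tn + sum(truth == 0L & out$label == 0L)
      fn <- fn + sum(truth == 1L & out$label == 0L)
    }
    per_repeat[[r]] <- metrics_from_counts(tp, fp, tn, fn)
  }
  summarize <- function(fun) {
    vals <- function(field) vapply(per_repeat, `[[`, numeric(1L), field)
    list(sn = fun(vals("sn")), sp = fun(vals("sp")),
         acc = fun(vals("acc")), mcc = fun(vals("mcc")))
  }
  best <- which.max(vapply(per_repeat, `[[`, numeric(1L), "acc"))
  structure(list(scheme = scheme, k = k, repeats = repeats,
                 paper_mode = paper_mode,
                 per_repeat = per_repeat,
                 mean = summarize(mean),
                 max = per_repeat[[best]]),
            class = "sno_cv")
}

#' @export
print.sno_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (k = %d, repeats = %d%s)\n",
              x$scheme, x$k, x$repeats,
              if (x$paper_mode) ", paper-mode profiles" else ""))
  cat(sprintf("mean: Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f\n",
              x$mean$sn, x$mean$sp, x$mean$acc, x$mean$mcc))
  if (x$repeats > 1L)
    cat(sprintf("best: Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f\n",
                x$max$sn, x$max$sp, x$max$acc, x$max$mcc))
  invisible(x)
}
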