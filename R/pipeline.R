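#' Stratified train/test split
#'
#' Shuffles within each class and splits at the given fraction; the two
#' index sets are disjoint and exhaustive. Reproducible from `seed`.
#'
#' @param labels Vector of class labels (any type with equality).
#' @param train_frac Fraction assigned to training, in (0, 1);
#'   default 0.8.
#' @param seed Integer seed.
#' @return List of integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) stop("every class needs at least 2 samples")
    k <- round(train_frac * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L)
    train <- c(train, sample(idx)[seq_len(k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Confusion table and accuracy
#'
#' @param true_labels,pred_labels Equal-length vectors of 0-based class
#'   indices in `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return List: `confusion` (`n_classes x n_classes`, entry `[i, j]` =
#'   count of true class i predicted j), `accuracy`, `per_class_recall`.
#' @export
confusion_and_accuracy <- function(true_labels, pred_labels, n_classes) {
  true_labels <- as.integer(true_labels)
  pred_labels <- as.integer(pred_labels)
  stopifnot(length(true_labels) == length(pred_labels))
  if (any(true_labels < 0L | true_labels >= n_classes) ||
      any(pred_labels < 0L | pred_labels >= n_classes)) {
    stop("label out of range")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(true_labels)) {
    i <- true_labels[k] + 1L
    j <- pred_labels[k] + 1L
    cm[i, j] <- cm[i, j] + 1L
  }
  rs <- rowSums(cm)
  list(
    confusion = cm,
    accuracy = sum(diag(cm)) / length(true_labels),
    per_class_recall = ifelse(rs > 0, diag(cm) / rs, NA_real_)
  )
}

#' Compute the feature table of a signal collection
#'
#' Preprocesses each raw signal (background subtraction + smoothing),
#' fits the hyperbolic law, and extracts the ten-feature vector.
#'
#' @param dataset List with `signals` and `labels` as returned by
#'   [generate_dataset()].
#' @param background Background level subtracted before smoothing.
#' @param window Sliding-average window width.
#' @param ... Passed to [extract_features()].
#' @return List: `X` (numeric matrix, one row per sample, columns
#'   [feature_names()]), `labels` (character), `fits` (list of
#'   `hyper_fit`).
#' @export
dataset_features <- function(dataset, background = 9, window = 5L, ...) {
  n <- length(dataset$signals)
  X <- matrix(NA_real_, n, 10L, dimnames = list(NULL, feature_names()))
  fits <- vector("list", n)
  for (k in seq_len(n)) {
    pp <- preprocess_signal(dataset$signals[[k]], background, window)
    fit <- fit_hyperbolic(pp)
    fits[[k]] <- fit
    X[k, ] <- extract_features(pp, fit, ...)
  }
  list(X = X, labels = dataset$labels, fits = fits)
}

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end comparison: class profiles,
#' acquisition, preprocessing, feature settings, split fraction and the
#' training configuration shared by both head modes.
#'
#' @param profiles List of [class_profile()]s
#'   (default [default_class_profiles()]).
#' @param n_per_class Samples per class (default 100).
#' @param acq An [acquisition_config()].
#' @param train_frac Training fraction of the stratified split
#'   (default 0.8).
#' @param train Training settings, a [train_config()].
#' @param kaiser_shape,apen_m,apen_r_factor Feature-extraction settings.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(profiles = default_class_profiles(),
                              n_per_class = 100L,
                              acq = acquisition_config(),
                              train_frac = 0.8,
                              train = train_config(),
                              kaiser_shape = 5, apen_m = 2L,
                              apen_r_factor = 0.2,
                              seed = 1L) {
  structure(
    list(profiles = profiles, n_per_class = as.integer(n_per_class),
         acq = acq, train_frac = train_frac, train = train,
         kaiser_shape = kaiser_shape, apen_m = apen_m,
         apen_r_factor = apen_r_factor, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the full one-hot vs Walsh comparison experiment
#'
#' Simulate -> preprocess -> fit -> features -> stratified split ->
#' z-score (statistics from the training partition only) -> train a
#' one-hot Bi-LSTM and a Walsh-Bi-LSTM on identical splits with
#' identical seeds -> evaluate both on the held-out set. The two models
#' differ only in the label codec.
#'
#' @param config An [experiment_config()].
#' @return List with one `evaluation` per model (`onehot`, `walsh`),
#'   each holding the train/test accuracy, confusion table, per-class
#'   recalls and training history, plus the shared `split`, `labels`
#'   and `norm_stats`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  ds <- generate_dataset(config$profiles, config$n_per_class, config$acq,
                         seed = config$seed)
  feats <- dataset_features(ds, background = config$acq$background,
                            window = 5L,
                            kaiser_shape = config$kaiser_shape,
                            apen_m = config$apen_m,
                            apen_r_factor = config$apen_r_factor)
  class_names <- vapply(config$profiles, `[[`, character(1L), "label")
  y <- match(feats$labels, class_names) - 1L
  n_classes <- length(class_names)

  split <- stratified_split(feats$labels, config$train_frac,
                            seed = config$seed + 1L)
  ns <- zscore_fit(feats$X[split$train, , drop = FALSE])
  Xtr <- zscore_apply(feats$X[split$train, , drop = FALSE], ns)
  Xte <- zscore_apply(feats$X[split$test, , drop = FALSE], ns)
  ytr <- y[split$train]
  yte <- y[split$test]

  # Noise is added to all data before the model: training inputs are
  # perturbed per presentation inside train_bilstm; held-out inputs get
  # one seeded corruption here, shared by both models.
  if (config$train$feature_noise_sd > 0) {
    old <- .save_rng_state()
    set.seed(config$seed + 3L)
    Xte <- Xte + stats::rnorm(length(Xte), 0, config$train$feature_noise_sd)
    .restore_rng_state(old)
  }

  tcfg <- config$train
  tcfg$seed <- config$seed + 2L
  codebook <- walsh_codebook(n_classes, 8L)

  eval_one <- function(codec) {
    fit <- train_bilstm(Xtr, ytr, tcfg, codebook = codec)
    pred_tr <- predict_bilstm(fit$model, Xtr)
    pred_te <- predict_bilstm(fit$model, Xte)
    ev_te <- confusion_and_accuracy(yte, pred_te, n_classes)
    list(
      train_accuracy = mean(pred_tr == ytr),
      test_accuracy = ev_te$accuracy,
      confusion = ev_te$confusion,
      per_class_recall = ev_te$per_class_recall,
      history = fit$history,
      model = fit$model
    )
  }

  list(
    onehot = eval_one(NULL),
    walsh = eval_one(codebook),
    split = split,
    class_names = class_names,
    norm_stats = ns
  )
}
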