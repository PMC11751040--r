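#' Training specification
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed governing data order, initialization and dropout.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (\code{NULL} disables early stopping; it also requires
#'   validation data at [train_model()] time).
#' @return A \code{train_spec} list.
#' @export
train_spec <- function(epochs = 100L, batch_size = 64L, learning_rate = 1e-3,
                       seed = 1L, early_stopping_patience = 10L) {
  stopifnot(epochs > 0, batch_size > 0, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stopping_patience = if (is.null(early_stopping_patience)) NULL
                                           else as.integer(early_stopping_patience)),
            class = "train_spec")
}

#' Train the classifier on a labeled window dataset
#'
#' Minibatch Adam on cross-entropy. Fully seeded: initialization comes from
#' the model seed, shuffling and dropout from \code{spec$seed}, so the same
#' model, data and spec reproduce identical parameters. When a validation
#' dataset is supplied and \code{early_stopping_patience} is set, the
#' parameters with the best validation loss are kept.
#'
#' @param model A \code{bwe_model} from [build_model()].
#' @param dataset A \code{window_dataset} containing both classes.
#' @param encoding An [encoding_config()] (defines the BWE weights).
#' @param spec A [train_spec()].
#' @param encoder Encoder name (\code{"bwe"} or \code{"binary"}).
#' @param validation Optional \code{window_dataset} for early stopping.
#' @return The trained \code{bwe_model}, with \code{$history} (per-epoch
#'   mean training cross-entropy), \code{$val_history} and \code{$best_epoch}.
#' @export
train_model <- function(model, dataset, encoding = encoding_config(L = model$L),
                        spec = train_spec(), encoder = "bwe", validation = NULL) {
  if (length(unique(dataset$label)) < 2L)
    stop("training data must contain both classes")
  X <- as_nn_input(dataset, model, encoding, encoder)
  y <- as.integer(dataset$label)
  Xval <- NULL; yval <- NULL
  patience <- spec$early_stopping_patience
  if (!is.null(validation)) {
    Xval <- as_nn_input(validation, model, encoding, encoder)
    yval <- as.integer(validation$label)
  }
  if (is.null(validation) || is.null(patience)) patience <- 0L
  fit <- .nn_train(X, y, model$params,
                   cfg_for_cpp(model$config, model$L, model$feature_dim),
                   spec$epochs, spec$batch_size, spec$learning_rate,
                   spec$seed, patience, Xval, yval)
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- as.numeric(fit$loss_history)
  model$val_history <- as.numeric(fit$val_loss_history)
  model$best_epoch <- fit$best_epoch
  model$encoder <- encoder
  model$encoding <- encoding
  model
}

#' Repeated group-aware k-fold cross-validation
#'
#' For each repeat \code{r}, folds come from [group_kfold()] with seed
#' \code{spec$seed + r - 1}; the model is rebuilt and retrained from scratch
#' on each training split and evaluated on the held-out fold. All windows of
#' a protein stay on one side of every split.
#'
#' @param dataset A \code{window_dataset}.
#' @param config A [model_config()].
#' @param encoding An [encoding_config()].
#' @param spec A [train_spec()].
#' @param k Number of folds (default 5).
#' @param repeats Cross-validation repeats (default 10).
#' @param encoder Encoder name.
#' @param threshold Decision threshold for confusion metrics.
#' @return A \code{cv_summary}: list with \code{folds} (one
#'   [evaluate_predictions()] row per fold x repeat), \code{summary}
#'   (per-metric mean and population SD), \code{predictions} (per-window
#'   held-out scores: window_index, repeat, fold, score, label) and the
#'   call parameters.
#' @export
cross_validate <- function(dataset, config = model_config(),
                           encoding = encoding_config(L = attr(dataset, "L")),
                           spec = train_spec(), k = 5L, repeats = 10L,
                           encoder = "bwe", threshold = 0.5) {
  L <- attr(dataset, "L")
  fold_rows <- list(); pred_rows <- list()
  for (r in seq_len(repeats)) {
    folds <- group_kfold(dataset, k = k, seed = spec$seed + r - 1L)
    for (f in sort(unique(folds))) {
      test_ix <- which(folds == f)
      train_ds <- dataset[-test_ix, , drop = FALSE]
      test_ds <- dataset[test_ix, , drop = FALSE]
      attr(train_ds, "L") <- L; attr(test_ds, "L") <- L
      model <- build_model(config, L = L, feature_dim = 20L,
                           seed = spec$seed + 1000L * r + f)
      fit_spec <- spec
      fit_spec$seed <- spec$seed + 1000L * r + f
      # no early stopping inside CV: the held-out fold must stay untouched
      model <- train_model(model, train_ds, encoding, fit_spec, encoder)
      pr <- predict(model, test_ds, encoding = encoding, encoder = encoder)
      ev <- evaluate_predictions(pr$prob, test_ds$label, threshold)
      ev$repeat_ <- r; ev$fold <- f
      fold_rows[[length(fold_rows) + 1L]] <- ev
      pred_rows[[length(pred_rows) + 1L]] <-
        data.frame(window_index = test_ix, repeat_ = r, fold = f,
                   score = pr$prob, label = test_ds$label)
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  metrics <- c("sn", "sp", "acc", "mcc", "auroc", "aupr")
  summary_df <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]]), numeric(1), USE.NAMES = FALSE),
    sd = vapply(metrics, function(m) pop_sd(folds_df[[m]]), numeric(1), USE.NAMES = FALSE),
    row.names = NULL)
  structure(list(folds = folds_df, summary = summary_df,
                 predictions = do.call(rbind, pred_rows),
                 k = k, repeats = repeats, encoder = encoder,
                 threshold = threshold),
            class = "cv_summary")
}

# population SD across fold x repeat evaluations
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s), encoder '%s'\n",
              x$k, x$repeats, x$encoder))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %.4f ± %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Classical baseline classifiers on flattened encodings
#'
#' Thin harness over established implementations (random forest via
#' \pkg{randomForest}, SVM via \pkg{e1071}, gradient boosting via
#' \pkg{xgboost}) fed flattened window encodings, for architecture
#' comparisons against the neural model.
#'
#' @param train_x,train_y Training feature matrix and 0/1 labels.
#' @param test_x Feature matrix to score.
#' @param method \code{"rf"}, \code{"svm"} or \code{"xgboost"}.
#' @param seed Integer seed.
#' @param ... Passed through to the underlying fit function.
#' @return Numeric vector of positive-class scores for \code{test_x}.
#' @export
baseline_scores <- function(train_x, train_y, test_x,
                            method = c("rf", "svm", "xgboost"), seed = 1L, ...) {
  method <- match.arg(method)
  pkg <- switch(method, rf = "randomForest", svm = "e1071", xgboost = "xgboost")
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("baseline '", method, "' needs the ", pkg, " package")
  with_seed(seed, switch(method,
    rf = {
      fit <- randomForest::randomForest(train_x, factor(train_y, levels = c(0, 1)), ...)
      unname(predict(fit, test_x, type = "prob")[, "1"])
    },
    svm = {
      fit <- e1071::svm(train_x, factor(train_y, levels = c(0, 1)),
                        probability = TRUE, ...)
      pr <- predict(fit, test_x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    xgboost = {
      fit <- xgboost::xgboost(data = train_x, label = train_y,
                              objective = "binary:logistic", nrounds = 100,
                              verbose = 0, ...)
      unname(predict(fit, test_x))
    }))
}
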