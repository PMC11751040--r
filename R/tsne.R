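#' Extract per-window features after each model stage
#'
#' Hooks the forward pass after the encoding, CNN, BiLSTM and attention
#' stages, for visualizing how class separation develops through the model.
#'
#' @param model A trained \code{bwe_model}.
#' @param dataset A \code{window_dataset} (or pre-encoded array).
#' @param stage One of \code{"encoding"}, \code{"cnn"}, \code{"bilstm"},
#'   \code{"attention"}; stages must be enabled in the model config.
#' @param encoding An [encoding_config()].
#' @param encoder Encoder name.
#' @param allow_untrained Permit an untrained model.
#' @return Numeric matrix, one row per window.
#' @export
layer_features <- function(model, dataset, stage = "attention",
                           encoding = encoding_config(L = model$L), encoder = "bwe",
                           allow_untrained = FALSE) {
  stages <- c("encoding",
              if (model$config$use_cnn) "cnn",
              if (model$config$use_bilstm) "bilstm",
              if (model$config$use_attention) "attention")
  if (!stage %in% stages)
    stop("unknown or disabled stage '", stage, "'; valid stages: ",
         paste(stages, collapse = ", "))
  if (!model$trained && !allow_untrained)
    stop("model is untrained; pass allow_untrained = TRUE to override")
  X <- as_nn_input(dataset, model, encoding, encoder)
  out <- .nn_forward(X, model$params,
                     cfg_for_cpp(model$config, model$L, model$feature_dim),
                     features = TRUE)
  out$features[[stage]]
}

#' Exact t-SNE embedding into two dimensions
#'
#' Compact exact (non-tree-accelerated) t-distributed stochastic neighbour
#' embedding: Gaussian input affinities calibrated per point to the target
#' perplexity by bisection, Student-t output affinities, gradient descent
#' with momentum and early exaggeration. Intended for the dataset sizes this
#' package works at (a few thousand windows); seeded and deterministic.
#'
#' @param X Feature matrix (rows = observations).
#' @param perplexity Target perplexity (default 30, capped at
#'   \code{(n - 1) / 3}).
#' @param n_iter Gradient-descent iterations (default 500).
#' @param seed Integer seed for the initial layout.
#' @return An \code{n x 2} matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 500L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 observations")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (hi >= 1e20) beta * 2 else (lo + hi) / 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5; eta <- 200
  for (iter in seq_len(n_iter)) {
    Pit <- if (iter <= 100) P * 4 else P  # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  Y
}

#' Two-dimensional stage-feature embedding table
#'
#' Convenience wrapper: extracts [layer_features()] for one or more stages
#' and embeds each with [tsne_embed()].
#'
#' @inheritParams layer_features
#' @param stages Character vector of stage names.
#' @param perplexity,n_iter,seed Passed to [tsne_embed()].
#' @return Data.frame with columns \code{index}, \code{x}, \code{y},
#'   \code{label}, \code{stage}.
#' @export
embed_stages <- function(model, dataset, stages = "attention",
                         encoding = encoding_config(L = model$L), encoder = "bwe",
                         perplexity = 30, n_iter = 500L, seed = 1L) {
  out <- lapply(stages, function(st) {
    f <- layer_features(model, dataset, st, encoding, encoder)
    Y <- tsne_embed(f, perplexity = perplexity, n_iter = n_iter, seed = seed)
    data.frame(index = seq_len(nrow(dataset)), x = Y[, 1], y = Y[, 2],
               label = dataset$label, stage = st)
  })
  do.call(rbind, out)
}
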