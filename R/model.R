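#' Classifier architecture configuration
#'
#' Hyperparameters of the CNN-BiLSTM-attention classifier. The three stage
#' flags express the architecture ablations: \code{use_cnn = FALSE} feeds the
#' encoding straight into the BiLSTM, \code{use_bilstm = FALSE} applies
#' attention over the convolutional timesteps, \code{use_attention = FALSE}
#' replaces the attention context with the final BiLSTM hidden state (or the
#' mean convolutional feature when both are off).
#'
#' @param conv_channels Output channels of the two 1-D convolutions.
#' @param kernel_sizes Kernel widths of the two convolutions ('valid', no
#'   padding).
#' @param pool_size Non-overlapping max-pool width after the convolutions.
#' @param lstm_hidden Hidden units per BiLSTM direction.
#' @param attention_dim Projection width of the additive attention.
#' @param fc_sizes Widths of the two fully connected layers.
#' @param dropout Dropout probability after each fully connected layer.
#' @param use_cnn,use_bilstm,use_attention Stage flags (all \code{TRUE} for
#'   the full model).
#' @return A \code{model_config} list.
#' @export
model_config <- function(conv_channels = c(32L, 64L), kernel_sizes = c(5L, 5L),
                         pool_size = 2L, lstm_hidden = 64L, attention_dim = 64L,
                         fc_sizes = c(64L, 32L), dropout = 0.5,
                         use_cnn = TRUE, use_bilstm = TRUE, use_attention = TRUE) {
  stopifnot(length(conv_channels) == 2L, length(kernel_sizes) == 2L,
            length(fc_sizes) == 2L, all(c(conv_channels, kernel_sizes,
                                          pool_size, lstm_hidden, attention_dim,
                                          fc_sizes) > 0),
            dropout >= 0, dropout < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 pool_size = as.integer(pool_size),
                 lstm_hidden = as.integer(lstm_hidden),
                 attention_dim = as.integer(attention_dim),
                 fc_sizes = as.integer(fc_sizes),
                 dropout = dropout,
                 use_cnn = isTRUE(use_cnn), use_bilstm = isTRUE(use_bilstm),
                 use_attention = isTRUE(use_attention)),
            class = "model_config")
}

cfg_for_cpp <- function(config, L, feature_dim) {
  c(unclass(config), list(L = as.integer(L), feature_dim = as.integer(feature_dim)))
}

#' Build an (untrained) classifier
#'
#' Instantiates the parameter tensors of the CNN-BiLSTM-attention stack with
#' seeded Glorot-uniform initialization. The same config and seed always
#' produce identical initial parameters.
#'
#' @param config A [model_config()].
#' @param L Window length the model will accept.
#' @param feature_dim Encoder row width (20 for binary/BWE).
#' @param seed Integer seed for the initialization.
#' @return A \code{bwe_model} object (untrained).
#' @export
build_model <- function(config = model_config(), L = 41L, feature_dim = 20L, seed = 1L) {
  cfg <- cfg_for_cpp(config, L, feature_dim)
  params <- .nn_init(cfg, as.integer(seed))
  structure(list(config = config, L = as.integer(L),
                 feature_dim = as.integer(feature_dim),
                 params = params, trained = FALSE,
                 timesteps = .nn_timesteps(cfg),
                 init_seed = as.integer(seed)),
            class = "bwe_model")
}

#' @export
print.bwe_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  stages <- c("cnn", "bilstm", "attention")[c(x$config$use_cnn, x$config$use_bilstm,
                                              x$config$use_attention)]
  cat(sprintf("bwe_model (%s): L = %d, %d feature channels, %d retained timesteps, %d parameters, %s\n",
              if (length(stages)) paste(stages, collapse = "+") else "fnn-only",
              x$L, x$feature_dim, x$timesteps, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# dataset (n x L x F array or window_dataset) -> cube expected by the C++ core
as_nn_input <- function(x, model, config_enc = NULL, encoder = "bwe") {
  if (inherits(x, "window_dataset")) {
    L <- attr(x, "L")
    if (L != model$L) stop("window length ", L, " does not match model L = ", model$L)
    if (is.null(config_enc)) config_enc <- encoding_config(L = L)
    x <- encode_windows(x, encoder = encoder, config = config_enc)
  }
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[2] != model$L || dim(x)[3] != model$feature_dim)
    stop("encoded array is ", dim(x)[2], " x ", dim(x)[3],
         " per window; model expects ", model$L, " x ", model$feature_dim)
  aperm(x, c(2, 3, 1))
}

#' Predict modification probabilities and attention profiles
#'
#' Runs the classifier in evaluation mode (dropout disabled): the forward
#' pass is deterministic and row order follows input order.
#'
#' @param object A trained \code{bwe_model} (or untrained with
#'   \code{allow_untrained = TRUE}).
#' @param newdata A \code{window_dataset} or a pre-encoded
#'   \code{n x L x feature_dim} array.
#' @param encoding An [encoding_config()] used when \code{newdata} is a
#'   dataset.
#' @param encoder Encoder name used when \code{newdata} is a dataset.
#' @param allow_untrained Permit prediction from an untrained model.
#' @param ... Unused.
#' @return A list: \code{prob} (length-n probability of the positive class),
#'   \code{probs} (n x 2 matrix), \code{attention} (n x timesteps matrix,
#'   each row on the simplex) and \code{class} (0/1 at threshold 0.5, ties
#'   to 0).
#' @export
predict.bwe_model <- function(object, newdata, encoding = NULL, encoder = "bwe",
                              allow_untrained = FALSE, ...) {
  if (!object$trained && !allow_untrained)
    stop("model is untrained; pass allow_untrained = TRUE to override")
  X <- as_nn_input(newdata, object, encoding, encoder)
  out <- .nn_forward(X, object$params, cfg_for_cpp(object$config, object$L, object$feature_dim))
  prob <- out$probs[, 2]
  list(prob = prob, probs = out$probs, attention = out$attention,
       class = as.integer(prob > 0.5))
}

#' Additive (Bahdanau) attention over a timestep matrix
#'
#' Reference implementation of the attention stage used inside the
#' classifier: per timestep \eqn{t}, \eqn{score_t = v^\top \tanh(w_1 O_t +
#' w_2 H)}; the scores are softmax-normalized into weights and the context
#' is the weighted sum of the timestep features.
#'
#' @param O Timesteps x features matrix.
#' @param H State vector (here: the concatenated final BiLSTM hidden states).
#' @param w1 Attention projection of the timestep features (A x ncol(O)).
#' @param w2 Attention projection of the state (A x length(H)).
#' @param v Scoring vector (length A).
#' @return List with \code{context} (length ncol(O)) and \code{scores}
#'   (length nrow(O), nonnegative, summing to 1).
#' @export
additive_attention <- function(O, H, w1, w2, v) {
  O <- as.matrix(O)
  if (nrow(O) == 0L) stop("O must have at least one timestep")
  if (ncol(w1) != ncol(O) || ncol(w2) != length(H) || length(v) != nrow(w1) ||
      nrow(w2) != nrow(w1))
    stop("attention parameter dimensions are incompatible with O / H")
  u <- tanh(w1 %*% t(O) + as.vector(w2 %*% H))  # A x T
  s <- as.vector(t(u) %*% v)
  e <- exp(s - max(s))
  a <- e / sum(e)
  list(context = as.vector(t(O) %*% a), scores = a)
}

#' Save / load a model checkpoint
#'
#' The fitted parameters go to an \code{.rds} file; a JSON sidecar
#' (\code{<path>.json}) records the architecture config, dimensions and
#' training provenance so a checkpoint is self-describing.
#'
#' @param model A \code{bwe_model}.
#' @param path Checkpoint path (\code{.rds}).
#' @return \code{save_model}: the path, invisibly; \code{load_model}: the
#'   restored \code{bwe_model}.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(class = "bwe_model", L = model$L, feature_dim = model$feature_dim,
               trained = model$trained, config = unclass(model$config),
               n_parameters = sum(vapply(model$params, length, integer(1))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bwe_model"))
  model
}
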