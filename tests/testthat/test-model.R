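test_that("model building is seeded and dimension-checked", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, L = 15L, seed = 5)
  m2 <- build_model(cfg, L = 15L, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, L = 15L, seed = 6)
  expect_false(identical(m1$params, m3$params))
  # parameter count is a deterministic function of the config
  expect_equal(vapply(m1$params, length, integer(1)),
               vapply(m3$params, length, integer(1)))
  expect_error(build_model(cfg, L = 5L), "minimum L is 6")
})

test_that("forward pass yields normalized probabilities and attention", {
  ds <- tiny_dataset(6, 6, L = 15L, seed = 1)
  m <- build_model(tiny_model_config(), L = 15L, seed = 1)
  expect_error(predict(m, ds), "untrained")
  pr <- predict(m, ds, allow_untrained = TRUE)
  expect_equal(rowSums(pr$probs), rep(1, 12), tolerance = 1e-6)
  expect_equal(rowSums(pr$attention), rep(1, 12), tolerance = 1e-6)
  expect_true(all(pr$attention >= 0))
  expect_equal(pr$prob, pr$probs[, 2])

  # wrong window length is rejected
  ds9 <- tiny_dataset(3, 3, L = 9L, seed = 1)
  expect_error(predict(m, ds9, allow_untrained = TRUE), "does not match model L")
})

test_that("evaluation-mode prediction is deterministic and stateless", {
  ds <- tiny_dataset(5, 5, L = 15L, seed = 2)
  m <- train_model(build_model(tiny_model_config(), L = 15L, seed = 1), ds,
                   encoding_config(L = 15L),
                   train_spec(epochs = 3L, batch_size = 4L, seed = 1,
                              early_stopping_patience = NULL))
  pr1 <- predict(m, ds)
  pr2 <- predict(m, ds)
  expect_identical(pr1$probs, pr2$probs)  # bitwise

  # duplicate window in a batch gets identical probabilities
  dup <- ds[c(1, 1, 2), , drop = FALSE]
  attr(dup, "L") <- 15L
  prd <- predict(m, dup)
  expect_identical(prd$probs[1, ], prd$probs[2, ])

  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2, 5, 10, 9, 8, 7, 6)
  dsp <- ds[perm, , drop = FALSE]
  attr(dsp, "L") <- 15L
  expect_identical(predict(m, dsp)$probs, pr1$probs[perm, ])
})

test_that("additive attention matches a step-by-step scalar recomputation", {
  # single timestep: softmax of a singleton
  out <- additive_attention(matrix(1:4, 1, 4), H = c(1, 0, 2, 1),
                            w1 = matrix(0.1, 2, 4), w2 = matrix(0.2, 2, 4),
                            v = c(1, -1))
  expect_equal(out$scores, 1)
  expect_equal(out$context, as.numeric(1:4))

  # two identical timesteps share the weight
  O <- rbind(c(1, 2), c(1, 2))
  out <- additive_attention(O, H = c(0.5, -0.5), w1 = diag(2), w2 = diag(2),
                            v = c(0.3, 0.7))
  expect_equal(out$scores, c(0.5, 0.5))

  # three timesteps against explicit loops
  set.seed(3)
  O <- matrix(rnorm(6), 3, 2)
  H <- rnorm(2)
  w1 <- matrix(rnorm(4), 2, 2); w2 <- matrix(rnorm(4), 2, 2); v <- rnorm(2)
  s <- numeric(3)
  for (t in 1:3) {
    u <- numeric(2)
    for (i in 1:2) {
      acc <- 0
      for (j in 1:2) acc <- acc + w1[i, j] * O[t, j] + w2[i, j] * H[j]
      u[i] <- tanh(acc)
    }
    s[t] <- sum(v * u)
  }
  a <- exp(s) / sum(exp(s))
  ctx <- colSums(O * a)
  out <- additive_attention(O, H, w1, w2, v)
  expect_equal(out$scores, a)
  expect_equal(out$context, ctx)
  # shifting all scores by a constant leaves the softmax weights unchanged
  expect_equal(out$scores, exp(s - 5) / sum(exp(s - 5)))

  expect_error(additive_attention(O, H, w1, matrix(0, 2, 3), v), "incompatible")
})

test_that("backpropagation matches finite differences", {
  ds <- tiny_dataset(4, 4, L = 15L, seed = 5)
  cfg <- tiny_model_config()
  m <- build_model(cfg, L = 15L, seed = 11)
  enc <- encoding_config(alpha = 0.05, L = 15L)
  X <- aperm(encode_windows(ds, "bwe", enc), c(2, 3, 1))
  ccfg <- c(unclass(cfg), list(L = 15L, feature_dim = 20L))
  G <- bwenet:::.nn_grad(X, ds$label, m$params, ccfg)
  eps <- 1e-6
  withr::with_seed(1, {
    for (nm in names(m$params)) {
      P <- m$params
      for (i in sample(length(P[[nm]]), min(3, length(P[[nm]])))) {
        P[[nm]][i] <- m$params[[nm]][i] + eps
        lp <- attr(bwenet:::.nn_grad(X, ds$label, P, ccfg), "loss")
        P[[nm]][i] <- m$params[[nm]][i] - eps
        lm <- attr(bwenet:::.nn_grad(X, ds$label, P, ccfg), "loss")
        P[[nm]][i] <- m$params[[nm]][i]
        numeric_grad <- (lp - lm) / (2 * eps)
        expect_equal(G[[nm]][i], numeric_grad, tolerance = 1e-4,
                     label = paste("grad", nm))
      }
    }
  })
})

test_that("ablation flags produce working reduced architectures", {
  ds <- tiny_dataset(6, 6, L = 15L, seed = 4)
  for (flags in list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                     c(FALSE, TRUE, TRUE), c(TRUE, FALSE, FALSE))) {
    cfg <- tiny_model_config(use_cnn = flags[1], use_bilstm = flags[2],
                             use_attention = flags[3])
    m <- build_model(cfg, L = 15L, seed = 2)
    pr <- predict(m, ds, allow_untrained = TRUE)
    expect_equal(rowSums(pr$probs), rep(1, 12), tolerance = 1e-6)
    expect_equal(rowSums(pr$attention), rep(1, 12), tolerance = 1e-6)
  }
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  ds <- tiny_dataset(5, 5, L = 15L, seed = 2)
  m <- train_model(build_model(tiny_model_config(), L = 15L, seed = 1), ds,
                   encoding_config(L = 15L),
                   train_spec(epochs = 2L, batch_size = 4L, seed = 1,
                              early_stopping_patience = NULL))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(predict(m2, ds)$probs, predict(m, ds)$probs)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$L, 15L)
  expect_true(side$trained)
})
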