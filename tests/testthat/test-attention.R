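test_that("profile stretching interpolates, renormalizes and refuses compression", {
  v <- c(0.2, 0.3, 0.5)
  expect_equal(stretch_profile(v, 3), v / sum(v))
  expect_equal(stretch_profile(rep(0.25, 4), 9), rep(1 / 9, 9))
  # midpoint of (0, 1) stretched to length 3 is proportional to (0, 0.5, 1)
  expect_equal(stretch_profile(c(0, 1), 3), c(0, 0.5, 1) / 1.5)
  expect_equal(stretch_profile(5, 4), rep(0.25, 4))  # single value
  s <- stretch_profile(c(0.1, 0.4, 0.2, 0.3), 11)
  expect_equal(sum(s), 1)
  expect_error(stretch_profile(v, 2), "compress")
})

test_that("dtw alignment matches exhaustive path enumeration", {
  r <- dtw_profiles(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$distance, 0)
  expect_equal(unname(r$path), cbind(1:3, 1:3))  # pure diagonal

  r <- dtw_profiles(c(0, 2), 1)
  expect_equal(r$distance, 2)
  expect_equal(unname(r$path), cbind(1:2, c(1, 1)))

  expect_equal(dtw_profiles(c(0, 1), c(0, 1, 1))$distance, 0)

  withr::with_seed(5, {
    for (rep in 1:200) {
      a <- round(runif(sample(1:5, 1)), 2)
      b <- round(runif(sample(1:5, 1)), 2)
      r <- dtw_profiles(a, b)
      expect_equal(r$distance, oracle_dtw(a, b))
      expect_true(valid_dtw_path(r$path, length(a), length(b)))
      # the reported path attains the reported distance
      expect_equal(sum(abs(a[r$path[, 1]] - b[r$path[, 2]])), r$distance)
      # symmetry: same distance, transposed path
      rt <- dtw_profiles(b, a)
      expect_equal(rt$distance, r$distance)
    }
  })
})

test_that("mean attention profile is a normalized average over windows", {
  ds <- tiny_dataset(6, 6, L = 15L, seed = 12)
  m <- build_model(tiny_model_config(), L = 15L, seed = 2)
  expect_error(mean_attention_profile(m, ds), "untrained")
  prof <- mean_attention_profile(m, ds, allow_untrained = TRUE)
  expect_length(prof, m$timesteps)
  expect_equal(sum(prof), 1, tolerance = 1e-6)

  one <- ds[1, , drop = FALSE]; attr(one, "L") <- 15L
  pr <- predict(m, one, allow_untrained = TRUE)
  expect_equal(mean_attention_profile(m, one, allow_untrained = TRUE),
               pr$attention[1, ])

  doubled <- ds[rep(seq_len(nrow(ds)), 2), , drop = FALSE]
  attr(doubled, "L") <- 15L
  expect_equal(mean_attention_profile(m, doubled, allow_untrained = TRUE), prof)

  pos_only <- mean_attention_profile(m, ds, positives_only = TRUE,
                                     allow_untrained = TRUE)
  expect_equal(sum(pos_only), 1, tolerance = 1e-6)
})

test_that("attention report compares against position weights and round-trips", {
  ds <- tiny_dataset(10, 10, L = 15L, seed = 13)
  enc <- encoding_config(alpha = 0.05, L = 15L)
  m <- train_model(build_model(tiny_model_config(), L = 15L, seed = 3), ds, enc,
                   train_spec(epochs = 5L, batch_size = 8L, seed = 3,
                              early_stopping_patience = NULL))
  rep_ <- compare_attention_to_position_weights(m, ds, enc)
  expect_equal(sum(rep_$position_curve), 1)
  expect_equal(sum(rep_$attention_curve), 1, tolerance = 1e-9)
  expect_length(rep_$attention_curve, 15L)
  expect_equal(rep_$normalized_distance, rep_$dtw$distance / nrow(rep_$dtw$path))

  # the position curve compared with itself is at distance zero
  self <- dtw_profiles(rep_$position_curve, rep_$position_curve)
  expect_equal(self$distance, 0)

  path <- withr::local_tempfile(fileext = ".json")
  write_attention_report(rep_, path)
  back <- read_attention_report(path)
  expect_equal(back$attention_curve, rep_$attention_curve)
  expect_equal(back$dtw$distance, rep_$dtw$distance)
  expect_equal(unname(back$dtw$path), unname(rep_$dtw$path))
  expect_equal(back$reversed$normalized_distance,
               rep_$reversed$normalized_distance)
})

test_that("rank reversal inverts the ordering but keeps the value multiset", {
  v <- c(0.1, 0.5, 0.3, 0.5, 0.2)
  expect_setequal(bwenet:::rank_reverse(v), v)
  w <- c(0.4, 0.1, 0.3, 0.2)
  expect_equal(bwenet:::rank_reverse(w), c(0.1, 0.4, 0.2, 0.3))
  # a center-peaked curve becomes center-lowest
  pos <- position_weights(encoding_config(alpha = 0.1, L = 11))
  rr <- bwenet:::rank_reverse(pos / sum(pos))
  expect_equal(which.min(rr), 6L)
})
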