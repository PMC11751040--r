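test_that("binary encoding matches the alphabet order", {
  m <- binary_encode("ACY")
  expect_equal(m[1, ], setNames(c(1, rep(0, 19)), strsplit(AA_ALPHABET, "")[[1]]))
  expect_equal(unname(m[2, ]), c(0, 1, rep(0, 18)))
  expect_equal(unname(m[3, ]), c(rep(0, 19), 1))
  # padding encodes to zero
  expect_equal(unname(binary_encode("XCX")[c(1, 3), ]), matrix(0, 2, 20))
  expect_error(binary_encode("A1C"), "position 2")
})

test_that("position weights decay exponentially and symmetrically", {
  w <- position_weights(encoding_config(alpha = 0, p = 1, L = 21))
  expect_equal(w, rep(1, 21))
  cfg <- encoding_config(alpha = 0.02, p = 1, L = 41)
  w <- position_weights(cfg)
  expect_equal(w[21], 1)                    # center weight is exactly p
  expect_equal(w[1], exp(-0.4))             # d = 20
  expect_equal(w[1], 0.670320, tolerance = 1e-6)
  expect_equal(w, rev(w))                   # symmetry
  expect_true(all(diff(w[1:21]) > 0))       # strictly increasing toward center
  cfg_p <- encoding_config(alpha = 0.1, p = 2.5, L = 11)
  expect_equal(max(position_weights(cfg_p)), 2.5)
})

test_that("bwe reduces to binary at alpha 0 and scales linearly in p", {
  win <- "ARNDCQEGHILKMFPSTWYVACDEFGHIKLMNPQRSTVWYA"
  expect_equal(bwe_encode(win, encoding_config(alpha = 0, p = 1, L = 41)),
               binary_encode(win))
  cfg <- encoding_config(alpha = 0.02, p = 1, L = 41)
  x <- bwe_encode(win, cfg)
  expect_equal(unname(x[1, "A"]), 0.670320, tolerance = 1e-6)
  expect_equal(sum(x[1, ] != 0), 1L)
  cfg3 <- encoding_config(alpha = 0.02, p = 3, L = 41)
  expect_equal(bwe_encode(win, cfg3), 3 * x)
  # row sums are 0 (X) or exactly the position weight
  w <- position_weights(cfg)
  win_x <- paste0("XX", substr(win, 3, 41))
  xx <- bwe_encode(win_x, cfg)
  expect_equal(unname(rowSums(xx)), c(0, 0, w[3:41]))
  expect_error(bwe_encode("ACA", cfg), "length")
})

test_that("EAAC counts subwindow composition excluding X", {
  v <- eaac_encode("AAAAA", sliding_window_size = 5)
  expect_length(v, 20)
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)
  v <- eaac_encode("ACACA", sliding_window_size = 5)
  expect_equal(unname(v[c(1, 2)]), c(0.6, 0.4))
  # X excluded from numerator and denominator
  v <- eaac_encode("AXAXA", sliding_window_size = 5)
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(eaac_encode("XXXXX", sliding_window_size = 5)), 0)
  # blocks sum to 1 when no X present
  v <- eaac_encode("ACDEFGHIK", sliding_window_size = 5)
  block_sums <- colSums(matrix(v, nrow = 20))
  expect_equal(block_sums, rep(1, 5))
  expect_error(eaac_encode("ACA", sliding_window_size = 5), "exceeds")
})

test_that("DPC and TPC are normalized k-mer compositions", {
  v <- dpc_encode("AAA")
  expect_length(v, 400)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  v <- dpc_encode("ACA")
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5))
  # X-containing pairs are skipped
  v <- dpc_encode("AXACA")
  expect_equal(sum(v), 1)
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5))
  t <- tpc_encode("ACDCA")
  expect_length(t, 8000)
  expect_equal(unname(t[c("ACD", "CDC", "DCA")]), rep(1 / 3, 3))
  expect_equal(sum(t), 1)
})

test_that("CTD has the standard 147 components with valid ranges", {
  v <- ctd_encode("ARNDCQEGHILKMFPSTWYVA")
  expect_length(v, 147)
  expect_true(all(v >= 0 & v <= 1))
  # composition blocks sum to 1 per attribute
  comp_ix <- as.vector(outer(1:3, 21 * (0:6), `+`))
  expect_equal(unname(colSums(matrix(v[comp_ix], nrow = 3))), rep(1, 7))
  # all-one-group window: charge composition concentrates on 'positive'
  v <- ctd_encode("KKKKK")
  expect_equal(unname(v["charge.C1"]), 1)
  expect_equal(unname(v["charge.T12"]), 0)
})

test_that("encode_windows produces stacked arrays and matrices", {
  ds <- tiny_dataset(4, 4, L = 15L, seed = 9)
  arr <- encode_windows(ds, "bwe", encoding_config(alpha = 0.02, L = 15L))
  expect_equal(dim(arr), c(8, 15, 20))
  expect_equal(arr[3, , ],
               unname(bwe_encode(ds$sequence[3], encoding_config(alpha = 0.02, L = 15L))))
  flat <- encode_windows(ds, "binary", flatten = TRUE)
  expect_equal(dim(flat), c(8, 300))
  eaac <- encode_windows(ds, "eaac")
  expect_equal(dim(eaac), c(8, 20 * 11))
})
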