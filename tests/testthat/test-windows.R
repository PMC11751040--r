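test_that("read_fasta parses records, folds case and sanitizes", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKC"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "MKC")

  writeLines(c(">p1", "mkc", ">p2", "AC"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$sequence, c("MKC", "AC"))

  writeLines(c(">p1", "MK*C"), fa)
  expect_warning(rec <- read_fasta(fa), "X")
  expect_equal(rec$sequence, "MKXC")
})

test_that("read_fasta rejects empty and malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "no records")
  writeLines(c("", "MKC", ">p1"), fa)
  expect_error(read_fasta(fa), "line 2")
})

test_that("extract_windows centers, pads termini and records positions", {
  expect_equal(extract_windows("p", "ACA", "C", 3L)$sequence, "ACA")
  w <- extract_windows("p", "CAA", "C", 3L)
  expect_equal(w$sequence, "XCA")
  expect_equal(w$center_position, 1L)
  expect_equal(nrow(extract_windows("p", "AAA", "C", 3L)), 0L)
  expect_error(extract_windows("p", "ACA", "C", 4L), "odd")

  # every occurrence yields one window; stripping the padding recovers the
  # center position in the parent
  seqn <- "CCAKRCMKAC"
  w <- extract_windows("p", seqn, "C", 7L)
  expect_equal(nrow(w), 4L)
  for (i in seq_len(nrow(w))) {
    expect_equal(substr(w$sequence[i], 4, 4), "C")
    core <- gsub("X", "", w$sequence[i])
    expect_true(grepl(core, seqn, fixed = TRUE))
    expect_equal(substr(seqn, w$center_position[i], w$center_position[i]), "C")
  }
})

test_that("build_dataset achieves the requested ratio and deduplicates", {
  pos <- extract_windows("pp", paste(rep("ACA", 5), collapse = ""), "C", 3L)
  neg <- do.call(rbind, lapply(1:10, function(i)
    extract_windows(paste0("n", i), "GCKGCRGCDGCEGC", "C", 3L)))
  expect_equal(nrow(pos), 5L)
  # 5 distinct negative 3-mers per protein, 10 proteins -> 5 distinct survive dedup
  ds <- build_dataset(pos[1, , drop = FALSE], neg, ratio = c(1, 1), seed = 3)
  expect_equal(sum(ds$label == 0), 1L)

  pos5 <- data.frame(sequence = c("ACA", "CCA", "DCA", "ECA", "GCA"),
                     protein_id = "pp", center_position = 2L)
  neg50 <- data.frame(sequence = paste0(rep(c("A","C","D","E","G","H","I","K","L","M"),
                                            each = 5),
                                        "C", rep(c("A","C","D","E","G"), 10)),
                      protein_id = rep(paste0("n", 1:10), each = 5),
                      center_position = 2L)
  ds1 <- build_dataset(pos5, neg50, ratio = c(1, 1), seed = 1)
  expect_equal(nrow(ds1), 10L)
  expect_equal(sum(ds1$label == 1), 5L)
  ds10 <- build_dataset(pos5, neg50, ratio = c(1, 10), seed = 1)
  expect_equal(nrow(ds10), 55L)
  expect_error(build_dataset(pos5, neg50[1:10, ], ratio = c(1, 10), seed = 1),
               "short by")

  # duplicated positive window survives once
  ds <- build_dataset(rbind(pos5, pos5[1, ]), neg50, ratio = c(1, 1), seed = 1)
  expect_equal(sum(ds$label == 1), 5L)
})

test_that("group_kfold partitions windows without splitting proteins", {
  ds <- tiny_dataset(25, 25, seed = 2, n_proteins = 10L)
  folds <- group_kfold(ds, k = 5, seed = 7)
  expect_length(folds, nrow(ds))
  expect_setequal(unique(folds), 0:4)
  # no protein spans two folds
  expect_true(all(tapply(folds, ds$protein_id, function(f) length(unique(f))) == 1))
  # determinism
  expect_identical(folds, group_kfold(ds, k = 5, seed = 7))
  expect_error(group_kfold(ds, k = 11, seed = 1), "11 folds")

  # one protein per fold when proteins == k
  ds5 <- window_dataset(data.frame(
    sequence = c("ACA", "DCD", "ECE", "GCG", "HCH"), label = c(1, 0, 1, 0, 1),
    protein_id = paste0("p", 1:5), center_position = 2L))
  expect_setequal(group_kfold(ds5, k = 5, seed = 1), 0:4)
})

test_that("window tables round-trip through the TSV format", {
  ds <- tiny_dataset(8, 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windows(ds, path)
  back <- read_windows(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_equal(attr(back, "L"), attr(ds, "L"))

  fpath <- withr::local_tempfile(fileext = ".tsv")
  folds <- group_kfold(ds, k = 3, seed = 1)
  write_folds(folds, fpath)
  tab <- read.delim(fpath)
  expect_equal(tab$fold, folds)
})

test_that("window_dataset enforces its invariants", {
  df <- data.frame(sequence = c("ACA", "AC"), label = c(0, 1),
                   protein_id = c("a", "b"))
  expect_error(window_dataset(df), "mixed lengths")
  df <- data.frame(sequence = c("ACA", "AAA"), label = c(0, 1),
                   protein_id = c("a", "b"))
  expect_error(window_dataset(df), "center")
  df <- data.frame(sequence = "ACA", label = 2, protein_id = "a")
  expect_error(window_dataset(df), "0/1")
})
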