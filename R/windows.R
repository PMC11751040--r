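#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' package's sequence conventions: sequences are uppercased and any character
#' outside the 21-letter extended alphabet (the 20 standard amino acids plus
#' \code{X} for unknown) is replaced by \code{X} with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{id} (first whitespace-delimited
#'   token of the header) and \code{sequence}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKCAVLL"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no records in FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA header at line ", nonblank[1], ": expected '>'")
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aas))
  bad <- gsub(sprintf("[%sX]", AA_ALPHABET), "", seqs)
  if (any(nzchar(bad))) {
    offenders <- unique(unlist(strsplit(paste(bad, collapse = ""), "")))
    warning("replaced non-standard characters (",
            paste(offenders, collapse = ", "), ") by 'X'")
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      chars[!chars %in% AA_EXTENDED] <- "X"
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence for record ", ids[!nzchar(seqs)][1])
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Extract fixed-length peptide windows centered on a residue
#'
#' One window is produced per occurrence of \code{center_residue} in the
#' protein. Windows that would run past a terminus are padded with \code{X}
#' so that every window has length exactly \code{L} and the candidate
#' residue sits at position \code{(L + 1) / 2}.
#'
#' @param id Parent protein accession.
#' @param sequence Protein sequence (uppercase, extended alphabet).
#' @param center_residue Residue to center windows on (default \code{"C"}).
#' @param L Odd window length, at least 3 (default 41).
#' @return A data.frame with columns \code{sequence}, \code{protein_id} and
#'   \code{center_position} (1-based position in the parent protein); zero
#'   rows when the residue does not occur.
#' @export
extract_windows <- function(id, sequence, center_residue = "C", L = 41L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(center_residue) == 1L)
  L <- as.integer(L)
  if (L < 3L || L %% 2L == 0L) stop("L must be odd and >= 3, got ", L)
  chars <- strsplit(sequence, "")[[1]]
  centers <- which(chars == center_residue)
  flank <- (L - 1L) %/% 2L
  padded <- c(rep("X", flank), chars, rep("X", flank))
  wins <- vapply(centers, function(pos) {
    paste(padded[pos:(pos + 2L * flank)], collapse = "")
  }, character(1))
  data.frame(sequence = as.character(wins),
             protein_id = rep(as.character(id), length(centers)),
             center_position = as.integer(centers),
             stringsAsFactors = FALSE)
}

#' Validate and tag a labeled window dataset
#'
#' A dataset is an ordinary data.frame with columns \code{sequence},
#' \code{label}, \code{protein_id}, \code{center_position} and an \code{L}
#' attribute; this constructor checks the window invariants (uniform odd
#' length, center residue, binary labels).
#'
#' @param df Data.frame with the four columns above (\code{center_position}
#'   optional, filled with \code{NA}).
#' @param center_residue Expected residue at the window center, or \code{NULL}
#'   to skip the check.
#' @return The validated data.frame of class \code{window_dataset}.
#' @export
window_dataset <- function(df, center_residue = "C") {
  stopifnot(all(c("sequence", "label", "protein_id") %in% names(df)))
  if (!"center_position" %in% names(df)) df$center_position <- NA_integer_
  if (nrow(df) == 0L) stop("empty dataset")
  lens <- unique(nchar(df$sequence))
  if (length(lens) != 1L) stop("windows have mixed lengths: ", paste(lens, collapse = ", "))
  L <- lens
  if (L %% 2L == 0L) stop("window length must be odd, got ", L)
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!is.null(center_residue)) {
    ctr <- substr(df$sequence, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
    if (!all(ctr == center_residue))
      stop("window(s) without '", center_residue, "' at the center: row ",
           which(ctr != center_residue)[1])
  }
  df$label <- as.integer(df$label)
  df$protein_id <- as.character(df$protein_id)
  rownames(df) <- NULL
  structure(df, L = as.integer(L), class = c("window_dataset", "data.frame"))
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("window_dataset: %d windows (L = %d), %d positive / %d negative, %d proteins\n",
              nrow(x), attr(x, "L"), sum(x$label == 1L), sum(x$label == 0L),
              length(unique(x$protein_id))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Assemble a labeled dataset at a requested class ratio
#'
#' Exact duplicate windows are removed within each class, then negatives are
#' subsampled (seeded, stratified across parent proteins so no single protein
#' dominates) to reach the requested positives:negatives ratio. Use
#' \code{ratio = "all"} to keep every negative.
#'
#' @param positives,negatives Data.frames of windows (as from
#'   [extract_windows()]), each with \code{sequence} and \code{protein_id}.
#' @param ratio Either \code{"all"} or a numeric pair \code{c(pos, neg)},
#'   e.g. \code{c(1, 1)} for a balanced set, \code{c(1, 10)} for 1:10.
#' @param seed Integer seed for the negative subsample.
#' @param center_residue Passed to [window_dataset()].
#' @return A \code{window_dataset}.
#' @export
build_dataset <- function(positives, negatives, ratio = c(1, 1), seed = 1L,
                          center_residue = "C") {
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    stop("both positive and negative windows are required")
  positives <- positives[!duplicated(positives$sequence), , drop = FALSE]
  negatives <- negatives[!duplicated(negatives$sequence), , drop = FALSE]
  if (identical(ratio, "all")) {
    n_neg <- nrow(negatives)
  } else {
    stopifnot(is.numeric(ratio), length(ratio) == 2L, all(ratio > 0))
    n_neg <- as.integer(round(nrow(positives) * ratio[2] / ratio[1]))
    if (n_neg > nrow(negatives))
      stop(sprintf("requested ratio needs %d negatives but only %d are available (short by %d)",
                   n_neg, nrow(negatives), n_neg - nrow(negatives)))
    negatives <- subsample_stratified(negatives, n_neg, seed)
  }
  positives$label <- 1L
  negatives$label <- 0L
  cols <- c("sequence", "label", "protein_id", "center_position")
  for (col in cols) {
    if (!col %in% names(positives)) positives[[col]] <- NA_integer_
    if (!col %in% names(negatives)) negatives[[col]] <- NA_integer_
  }
  window_dataset(rbind(positives[cols], negatives[cols]), center_residue = center_residue)
}

# round-robin over shuffled proteins so the subsample spreads across parents
subsample_stratified <- function(df, n, seed) {
  with_seed(seed, {
    by_prot <- split(seq_len(nrow(df)), df$protein_id)
    by_prot <- by_prot[sample(length(by_prot))]
    by_prot <- lapply(by_prot, sample)
    take <- integer(0)
    while (length(take) < n) {
      picks <- vapply(by_prot, function(ix) if (length(ix)) ix[1] else NA_integer_, integer(1))
      picks <- picks[!is.na(picks)]
      take <- c(take, picks)
      by_prot <- lapply(by_prot, function(ix) ix[-1])
    }
    df[sort(take[seq_len(n)]), , drop = FALSE]
  })
}

#' Group-aware k-fold assignment
#'
#' Partitions windows into \code{k} folds such that all windows sharing a
#' \code{protein_id} land in the same fold (no homology leakage between a
#' training and its validation split). Proteins are assigned greedily,
#' largest group first, into the currently smallest fold; ties are broken by
#' a seeded shuffle, so the assignment is deterministic given the seed.
#'
#' @param dataset A \code{window_dataset}.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in \code{0:(k-1)}, one per window.
#' @export
group_kfold <- function(dataset, k = 5L, seed = 1L) {
  k <- as.integer(k)
  groups <- split(seq_len(nrow(dataset)), dataset$protein_id)
  if (length(groups) < k)
    stop(sprintf("only %d distinct proteins for k = %d folds", length(groups), k))
  with_seed(seed, {
    groups <- groups[sample(length(groups))]
  })
  groups <- groups[order(-lengths(groups))]  # stable: keeps shuffled order within size ties
  fold_of <- integer(nrow(dataset))
  fold_sizes <- integer(k)
  for (g in groups) {
    target <- which.min(fold_sizes)
    fold_of[g] <- target - 1L
    fold_sizes[target] <- fold_sizes[target] + length(g)
  }
  fold_of
}

#' Write / read the tab-separated window-table format
#'
#' Columns \code{sequence}, \code{label}, \code{protein_id},
#' \code{center_position}, tab-separated with a header line.
#'
#' @param dataset A \code{window_dataset}.
#' @param path Output / input file path.
#' @param center_residue Passed to [window_dataset()] when reading.
#' @return \code{write_windows}: the path, invisibly. \code{read_windows}:
#'   a \code{window_dataset}.
#' @export
write_windows <- function(dataset, path) {
  df <- as.data.frame(dataset)[c("sequence", "label", "protein_id", "center_position")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path, center_residue = "C") {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sequence = "character", label = "integer",
                                  protein_id = "character", center_position = "integer"))
  window_dataset(df, center_residue = center_residue)
}

#' @rdname write_windows
#' @param folds Integer fold vector from [group_kfold()].
#' @export
write_folds <- function(folds, path) {
  write.table(data.frame(index = seq_along(folds) - 1L, fold = folds),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
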