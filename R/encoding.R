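#' Binary-weight encoding configuration
#'
#' Parameters of the positional weighting \eqn{W_i = p e^{-\alpha d_i}},
#' where \eqn{d_i} is the distance (in residues) of position \eqn{i} from
#' the window center. \code{alpha = 0} recovers plain one-hot encoding;
#' \code{p} only rescales all features uniformly.
#'
#' @param alpha Decay coefficient, \eqn{\ge 0}; default 0.02 (the value at
#'   which 41-mer models perform best).
#' @param p Source strength at the center, \eqn{> 0}; default 1.
#' @param L Odd window length; default 41.
#' @param alphabet Ordered 20-letter encoder alphabet.
#' @return An \code{encoding_config} list.
#' @export
encoding_config <- function(alpha = 0.02, p = 1, L = 41L, alphabet = AA_ALPHABET) {
  stopifnot(alpha >= 0, p > 0, nchar(alphabet) == 20L)
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 3L) stop("L must be odd and >= 3")
  structure(list(alpha = alpha, p = p, L = L, alphabet = alphabet),
            class = "encoding_config")
}

#' Positional weight vector of the binary-weight encoding
#'
#' @param config An [encoding_config()].
#' @return Numeric vector of length \code{L}: \eqn{W_i = p e^{-\alpha d_i}},
#'   symmetric about the center, maximal (exactly \code{p}) at the center.
#' @export
#' @examples
#' position_weights(encoding_config(alpha = 0.02, L = 41))
position_weights <- function(config = encoding_config()) {
  d <- abs(seq_len(config$L) - (config$L + 1L) / 2)
  config$p * exp(-config$alpha * d)
}

aa_index <- function(chars, alphabet, what = "window") {
  letters20 <- strsplit(alphabet, "")[[1]]
  idx <- match(chars, letters20)
  bad <- which(is.na(idx) & chars != "X")
  if (length(bad))
    stop(sprintf("invalid character '%s' at %s position %d", chars[bad[1]], what, bad[1]))
  idx  # NA for 'X'
}

#' One-hot (binary) encoding of a peptide window
#'
#' Row \code{i} is the one-hot vector of residue \code{i} in alphabet order
#' (\code{A} is 1 followed by nineteen 0s, \code{C} has the 1 in column 2,
#' \code{Y} in column 20); \code{X} rows are all zero.
#'
#' @param window Window sequence (character scalar).
#' @param config An [encoding_config()]; only the alphabet is used here.
#' @return \code{L x 20} numeric matrix with columns named by residue.
#' @export
binary_encode <- function(window, config = encoding_config(L = nchar(window))) {
  chars <- strsplit(window, "")[[1]]
  idx <- aa_index(chars, config$alphabet)
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, strsplit(config$alphabet, "")[[1]]))
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Binary-weight encoding (BWE) of a peptide window
#'
#' The one-hot row of each position is scaled by its positional weight:
#' \eqn{X_i = B_i W_i}. With \code{alpha = 0, p = 1} this is exactly the
#' plain binary encoding.
#'
#' @inheritParams binary_encode
#' @return \code{L x 20} numeric matrix.
#' @export
bwe_encode <- function(window, config = encoding_config(L = nchar(window))) {
  if (nchar(window) != config$L)
    stop("window length ", nchar(window), " != config L ", config$L)
  binary_encode(window, config) * position_weights(config)
}

#' Enhanced amino-acid composition (EAAC)
#'
#' Amino-acid frequencies within a sliding subwindow, concatenated over all
#' subwindow positions. \code{X} is excluded from both numerator and
#' denominator; an all-\code{X} subwindow yields zeros.
#'
#' @inheritParams binary_encode
#' @param sliding_window_size Subwindow width (default 5).
#' @return Numeric vector of length \code{20 * (L - size + 1)}.
#' @export
eaac_encode <- function(window, sliding_window_size = 5L,
                        config = encoding_config(L = nchar(window))) {
  w <- as.integer(sliding_window_size)
  L <- nchar(window)
  if (w > L) stop("sliding window size ", w, " exceeds window length ", L)
  chars <- strsplit(window, "")[[1]]
  idx <- aa_index(chars, config$alphabet)
  nblock <- L - w + 1L
  out <- numeric(20L * nblock)
  for (b in seq_len(nblock)) {
    sub <- idx[b:(b + w - 1L)]
    sub <- sub[!is.na(sub)]
    if (length(sub)) {
      freq <- tabulate(sub, nbins = 20L) / length(sub)
      out[(20L * (b - 1L) + 1L):(20L * b)] <- freq
    }
  }
  names(out) <- paste0("w", rep(seq_len(nblock), each = 20L), ".",
                       rep(strsplit(config$alphabet, "")[[1]], nblock))
  out
}

#' Dipeptide / tripeptide composition (DPC / TPC)
#'
#' Normalized counts of overlapping residue pairs (400-vector) or triples
#' (8000-vector); any k-mer containing \code{X} is skipped.
#'
#' @inheritParams binary_encode
#' @return Named numeric vector (length 400 for DPC, 8000 for TPC).
#' @export
dpc_encode <- function(window, config = encoding_config(L = nchar(window))) {
  kmer_composition(window, 2L, config$alphabet)
}

#' @rdname dpc_encode
#' @export
tpc_encode <- function(window, config = encoding_config(L = nchar(window))) {
  kmer_composition(window, 3L, config$alphabet)
}

kmer_composition <- function(window, k, alphabet) {
  chars <- strsplit(window, "")[[1]]
  if (length(chars) < k + 1L) stop("window too short for ", k, "-mer composition")
  idx <- aa_index(chars, alphabet)
  letters20 <- strsplit(alphabet, "")[[1]]
  n <- length(chars) - k + 1L
  # flat index over the 20^k k-mer table, base-20 big-endian
  pos <- 0L
  counts <- numeric(20L^k)
  for (s in seq_len(n)) {
    win <- idx[s:(s + k - 1L)]
    if (anyNA(win)) next
    flat <- sum((win - 1L) * 20L^((k - 1L):0L)) + 1L
    counts[flat] <- counts[flat] + 1
  }
  total <- sum(counts)
  if (total > 0) counts <- counts / total
  grids <- do.call(expand.grid, rev(replicate(k, letters20, simplify = FALSE)))
  names(counts) <- do.call(paste0, rev(grids))
  counts
}

# Standard 7-attribute / 3-group physicochemical classification used by the
# composition/transition/distribution descriptor.
CTD_GROUPS <- list(
  hydrophobicity    = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  vdw_volume        = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity          = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability    = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge            = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondary_struct  = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_access    = c("ALFCGIVW", "RKQEND", "MPSTHY"))

#' Composition / transition / distribution (CTD) descriptor
#'
#' For each of 7 physicochemical attributes residues are mapped to 3 groups;
#' the descriptor concatenates group composition (3), transition frequencies
#' between distinct groups (3) and, per group, the relative sequence
#' positions of the first, 25\%, 50\%, 75\% and last occurrence (15), giving
#' 21 values per attribute (147 total). \code{X} positions are dropped
#' before computing the descriptor.
#'
#' @inheritParams binary_encode
#' @return Named numeric vector of length 147.
#' @export
ctd_encode <- function(window, config = encoding_config(L = nchar(window))) {
  chars <- strsplit(window, "")[[1]]
  aa_index(chars, config$alphabet)  # validation only
  chars <- chars[chars != "X"]
  n <- length(chars)
  out <- numeric(0)
  for (attr_name in names(CTD_GROUPS)) {
    groups <- CTD_GROUPS[[attr_name]]
    g <- integer(n)
    for (j in 1:3) g[chars %in% strsplit(groups[j], "")[[1]]] <- j
    comp <- if (n) tabulate(g, 3L) / n else numeric(3)
    trans <- numeric(3)  # pairs 1-2, 1-3, 2-3 (orderless)
    if (n > 1L) {
      a <- g[-n]; b <- g[-1]
      trans[1] <- sum((a == 1 & b == 2) | (a == 2 & b == 1))
      trans[2] <- sum((a == 1 & b == 3) | (a == 3 & b == 1))
      trans[3] <- sum((a == 2 & b == 3) | (a == 3 & b == 2))
      trans <- trans / (n - 1L)
    }
    distr <- numeric(15)
    for (j in 1:3) {
      where <- which(g == j)
      if (length(where)) {
        qpos <- where[pmax(1L, ceiling(length(where) * c(.Machine$double.eps, .25, .5, .75, 1)))]
        distr[(5 * (j - 1) + 1):(5 * j)] <- qpos / n
      }
    }
    block <- c(comp, trans, distr)
    names(block) <- paste0(attr_name, ".", c(paste0("C", 1:3), "T12", "T13", "T23",
                                             paste0("D", rep(1:3, each = 5), ".",
                                                    rep(c(0, 25, 50, 75, 100), 3))))
    out <- c(out, block)
  }
  out
}

#' Encode every window of a dataset
#'
#' Matrix encoders (\code{bwe}, \code{binary}) return an
#' \code{n x L x 20} array suitable for the neural classifier; vector
#' encoders (\code{eaac}, \code{dpc}, \code{tpc}, \code{ctd}) return an
#' \code{n x D} matrix suitable for classical baselines. Use
#' \code{flatten = TRUE} to get a flat matrix from the matrix encoders too.
#'
#' @param dataset A [window_dataset()].
#' @param encoder One of \code{"bwe"}, \code{"binary"}, \code{"eaac"},
#'   \code{"dpc"}, \code{"tpc"}, \code{"ctd"}.
#' @param config An [encoding_config()]; \code{alpha} is forced to 0 for
#'   \code{encoder = "binary"}.
#' @param flatten Return a 2-D matrix even for matrix encoders.
#' @param ... Extra encoder arguments (e.g. \code{sliding_window_size}).
#' @return Array or matrix; see details.
#' @export
encode_windows <- function(dataset, encoder = "bwe",
                           config = encoding_config(L = attr(dataset, "L")),
                           flatten = FALSE, ...) {
  encoder <- match.arg(encoder, c("bwe", "binary", "eaac", "dpc", "tpc", "ctd"))
  L <- attr(dataset, "L")
  if (is.null(L)) L <- unique(nchar(dataset$sequence))
  if (config$L != L) config$L <- L
  seqs <- dataset$sequence
  if (encoder %in% c("bwe", "binary")) {
    if (encoder == "binary") config$alpha <- 0
    arr <- array(0, dim = c(length(seqs), L, 20L))
    for (i in seq_along(seqs)) arr[i, , ] <- bwe_encode(seqs[i], config)
    if (!flatten) return(arr)
    return(matrix(arr, nrow = length(seqs)))
  }
  fn <- switch(encoder, eaac = eaac_encode, dpc = dpc_encode,
               tpc = tpc_encode, ctd = ctd_encode)
  rows <- lapply(seqs, fn, config = config, ...)
  do.call(rbind, rows)
}
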