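#' Mean attention profile over a dataset
#'
#' Averages the per-window softmax attention weights across windows; since
#' each row lies on the simplex, the mean profile also sums to 1.
#'
#' @param model A trained \code{bwe_model} (with attention enabled).
#' @param dataset A \code{window_dataset}.
#' @param encoding An [encoding_config()].
#' @param encoder Encoder name.
#' @param positives_only Average over positive-label windows only.
#' @param allow_untrained Permit an untrained model (for plumbing tests).
#' @return Numeric vector of length equal to the model's retained timesteps.
#' @export
mean_attention_profile <- function(model, dataset, encoding = encoding_config(L = model$L),
                                   encoder = "bwe", positives_only = FALSE,
                                   allow_untrained = FALSE) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (positives_only) {
    dataset <- dataset[dataset$label == 1L, , drop = FALSE]
    if (nrow(dataset) == 0L) stop("no positive windows to average over")
  }
  pr <- predict(model, dataset, encoding = encoding, encoder = encoder,
                allow_untrained = allow_untrained)
  colMeans(pr$attention)
}

#' Stretch a weight profile to a longer length
#'
#' Linear interpolation of the \code{T} profile values at positions mapped
#' uniformly onto \code{[0, L-1]}, then renormalization to sum 1.
#' Order-preserving; constant profiles stay constant. Compression
#' (\code{L < T}) is refused.
#'
#' @param values Numeric profile of length \code{T >= 1}.
#' @param L Target length, \code{L >= T}.
#' @return Numeric vector of length \code{L} summing to 1.
#' @export
stretch_profile <- function(values, L) {
  T_ <- length(values)
  if (T_ < 1L) stop("empty profile")
  if (L < T_) stop("cannot compress a profile: L = ", L, " < T = ", T_)
  out <- if (T_ == 1L) rep(values, L)
         else approx(x = seq(0, L - 1, length.out = T_), y = values, xout = 0:(L - 1))$y
  out / sum(out)
}

#' Dynamic time warping of two weight profiles
#'
#' Classic dynamic program with steps (1,0), (0,1), (1,1), pointwise cost
#' \eqn{|a_i - b_j|} and no window constraint. The optimal path is recovered
#' by backtrace with a deterministic tie-break: diagonal, then vertical
#' (advance in \code{a}), then horizontal.
#'
#' @param a,b Non-empty numeric profiles.
#' @return List of class \code{dtw_result}: \code{distance} (sum of costs
#'   along the path) and \code{path}, a two-column matrix of 1-based index
#'   pairs from \code{(1, 1)} to \code{(length(a), length(b))}.
#' @export
dtw_profiles <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("profiles must be non-empty")
  cost <- abs(outer(a, b, `-`))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1L, j + 1L] <- cost[i, j] + min(D[i, j], D[i, j + 1L], D[i + 1L, j])
  # backtrace, preferring diagonal, then vertical, then horizontal
  i <- n; j <- m
  path <- list(c(i, j))
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L && D[i, j] <= D[i, j + 1L] && D[i, j] <= D[i + 1L, j]) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && (j == 1L || D[i, j + 1L] <= D[i + 1L, j])) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("i", "j")
  structure(list(distance = D[n + 1L, m + 1L], path = path), class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW distance %.6g over a path of %d steps\n", x$distance, nrow(x$path)))
  invisible(x)
}

# mirror a curve about its ranks: position with the r-th largest value gets
# the r-th smallest (same multiset of values, ordering inverted)
rank_reverse <- function(values) {
  r <- rank(values, ties.method = "first")
  sort(values)[length(values) + 1L - r]
}

#' Compare the learned attention profile with the BWE position weights
#'
#' The mean attention profile (length = retained timesteps) is stretched to
#' the window length and compared by DTW against the normalized positional
#' weight curve \eqn{W_i = p e^{-\alpha d_i}} of the encoder. As a
#' contrast, the same comparison is run against the rank-reversed position
#' curve (center-lowest): attention that concentrates near the center is
#' closer to the decay curve than to its reversal.
#'
#' @inheritParams mean_attention_profile
#' @return List of class \code{attention_report}: \code{attention_curve}
#'   (stretched, length L), \code{position_curve} (normalized), \code{dtw}
#'   (a \code{dtw_result}), \code{normalized_distance} (distance / path
#'   length), and \code{reversed} (same two numbers against the
#'   rank-reversed curve).
#' @export
compare_attention_to_position_weights <- function(model, dataset,
                                                  encoding = encoding_config(L = model$L),
                                                  encoder = "bwe",
                                                  positives_only = FALSE) {
  prof <- mean_attention_profile(model, dataset, encoding, encoder, positives_only)
  att <- stretch_profile(prof, model$L)
  pos <- position_weights(encoding)
  pos <- pos / sum(pos)
  al <- dtw_profiles(att, pos)
  rev_pos <- rank_reverse(pos)
  al_rev <- dtw_profiles(att, rev_pos)
  structure(list(
    attention_profile = prof,
    attention_curve = att,
    position_curve = pos,
    dtw = al,
    normalized_distance = al$distance / nrow(al$path),
    reversed = list(distance = al_rev$distance,
                    normalized_distance = al_rev$distance / nrow(al_rev$path))),
    class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf(paste0("attention vs position-weight curve: DTW %.5f ",
                     "(normalized %.5f); vs rank-reversed curve: normalized %.5f\n"),
              x$dtw$distance, x$normalized_distance,
              x$reversed$normalized_distance))
  invisible(x)
}

#' Serialize / restore an attention report as JSON
#'
#' @param report An \code{attention_report}.
#' @param path JSON file path.
#' @return \code{write_attention_report}: the path, invisibly;
#'   \code{read_attention_report}: the restored report.
#' @export
write_attention_report <- function(report, path) {
  out <- list(attention_profile = report$attention_profile,
              attention_curve = report$attention_curve,
              position_curve = report$position_curve,
              distance = report$dtw$distance,
              normalized_distance = report$normalized_distance,
              path = unname(apply(report$dtw$path, 1, as.integer, simplify = FALSE)),
              reversed = report$reversed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attention_report
#' @export
read_attention_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pathmat <- if (is.matrix(x$path)) x$path else do.call(rbind, x$path)
  colnames(pathmat) <- c("i", "j")
  structure(list(attention_profile = x$attention_profile,
                 attention_curve = x$attention_curve,
                 position_curve = x$position_curve,
                 dtw = structure(list(distance = x$distance, path = pathmat),
                                 class = "dtw_result"),
                 normalized_distance = x$normalized_distance,
                 reversed = as.list(x$reversed)),
            class = "attention_report")
}
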