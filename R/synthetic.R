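#' Specification of the synthetic center-concentrated signal
#'
#' The generator emulates the assumed structure of real PTM window data: a
#' compositional signal (enrichment of a few residues) that is strongest
#' next to the modified center cysteine and decays exponentially with
#' distance. At off-center distance \eqn{d}, a positive-class residue is
#' drawn from \code{signal_residues} with probability
#' \eqn{s_0 e^{-\beta d}} and from the background composition otherwise;
#' negatives are background throughout.
#'
#' @param L Odd window length (default 41).
#' @param signal_residues Residues carrying the signal (default K, R, E).
#' @param signal_strength \eqn{s_0 \in [0, 1]}: signal probability adjacent
#'   to the center.
#' @param signal_decay \eqn{\beta \ge 0}: per-residue decay rate.
#' @param background Length-20 composition over the alphabet (default
#'   uniform).
#' @param n_proteins Number of synthetic parent proteins windows are
#'   attributed to (round-robin), so grouped CV is exercisable.
#' @param center_residue Fixed center residue (default \code{"C"}).
#' @param seed Integer seed.
#' @return A \code{signal_spec} list.
#' @export
signal_spec <- function(L = 41L, signal_residues = c("K", "R", "E"),
                        signal_strength = 0.8, signal_decay = 0.05,
                        background = rep(1 / 20, 20), n_proteins = 50L,
                        center_residue = "C", seed = 1L) {
  stopifnot(signal_strength >= 0, signal_strength <= 1, signal_decay >= 0,
            length(background) == 20L, all(background >= 0),
            abs(sum(background) - 1) < 1e-8,
            all(signal_residues %in% AA_LETTERS), n_proteins >= 1L)
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 3L) stop("L must be odd and >= 3")
  structure(list(L = L, signal_residues = signal_residues,
                 signal_strength = signal_strength, signal_decay = signal_decay,
                 background = background, n_proteins = as.integer(n_proteins),
                 center_residue = center_residue, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a labeled synthetic window dataset
#'
#' Every window has the center residue fixed; positive windows carry the
#' center-concentrated compositional signal of the [signal_spec()],
#' negatives are i.i.d. background. Windows are attributed to
#' \code{n_proteins} synthetic protein ids round-robin. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec A [signal_spec()].
#' @param n_pos,n_neg Positive / negative window counts (both > 0).
#' @return A \code{window_dataset} of \code{n_pos + n_neg} rows.
#' @export
generate_dataset <- function(spec, n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0) stop("n_pos and n_neg must be positive")
  L <- spec$L
  center <- (L + 1L) %/% 2L
  d <- abs(seq_len(L) - center)
  p_signal <- spec$signal_strength * exp(-spec$signal_decay * d)
  with_seed(spec$seed, {
    draw_window <- function(positive) {
      chars <- sample(AA_LETTERS, L, replace = TRUE, prob = spec$background)
      if (positive) {
        hit <- runif(L) < p_signal
        hit[center] <- FALSE
        if (any(hit))
          chars[hit] <- sample(spec$signal_residues, sum(hit), replace = TRUE)
      }
      chars[center] <- spec$center_residue
      paste(chars, collapse = "")
    }
    seqs <- c(vapply(seq_len(n_pos), function(i) draw_window(TRUE), character(1)),
              vapply(seq_len(n_neg), function(i) draw_window(FALSE), character(1)))
  })
  n <- n_pos + n_neg
  df <- data.frame(
    sequence = seqs,
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    protein_id = sprintf("SYNP%03d", (seq_len(n) - 1L) %% spec$n_proteins + 1L),
    center_position = rep(center, n),
    stringsAsFactors = FALSE)
  window_dataset(df, center_residue = spec$center_residue)
}

#' Analytic signal-residue frequency at distance d
#'
#' For a positive-class window, the probability that the residue at
#' off-center distance \code{d} is one of the signal residues:
#' \deqn{s_0 e^{-\beta d} + (1 - s_0 e^{-\beta d})\, m}
#' where \eqn{m} is the background mass of the signal residues. Used as the
#' closed-form oracle when validating the generator empirically.
#'
#' @param spec A [signal_spec()].
#' @param d Integer distance from the center, \code{1 <= d <= (L-1)/2}
#'   (the center itself is fixed to the center residue and excluded).
#' @return The analytic frequency.
#' @export
expected_signal_frequency <- function(spec, d) {
  if (any(d < 1L) || any(d > (spec$L - 1L) %/% 2L))
    stop("d must be in 1..(L-1)/2; the center position is fixed to '",
         spec$center_residue, "'")
  m <- sum(spec$background[match(spec$signal_residues, AA_LETTERS)])
  s <- spec$signal_strength * exp(-spec$signal_decay * d)
  s + (1 - s) * m
}
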