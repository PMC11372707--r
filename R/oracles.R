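# Independent reference implementations, written as literal loop-based
# transcriptions of the measure definitions. They share no code with the
# vectorized production routines in measures.R and exist as a second route
# for cross-checking on small fixtures; do not use them on long series.

#' Brute-force DFA reference implementation
#'
#' Literal, loop-based transcription of the DFA procedure: integrate the
#' mean-centered series, cut into non-overlapping windows of length `m`
#' from the start, fit a line to each window with [stats::lm()], average the
#' per-window RMS residuals, and regress `log F(m)` on `log m` with
#' [stats::lm()]. Intended only as an independent cross-check for
#' [dfa_alpha()] on short fixtures.
#'
#' @param x numeric vector.
#' @param window_sizes integer window sizes.
#' @return list with `window_sizes`, `fluctuation`, `alpha`.
#' @keywords internal
#' @export
dfa_brute_force <- function(x, window_sizes) {
  x <- as_series_values(x)
  ms <- sort(unique(as.integer(window_sizes)))
  y <- cumsum(x - mean(x))
  Fm <- numeric(length(ms))
  for (i in seq_along(ms)) {
    m <- ms[i]
    n_seg <- length(y) %/% m
    rms <- numeric(n_seg)
    for (s in seq_len(n_seg)) {
      idx <- ((s - 1L) * m + 1L):(s * m)
      seg <- y[idx]
      t <- seq_len(m)
      fit <- stats::lm(seg ~ t)
      rms[s] <- sqrt(mean(stats::residuals(fit)^2))
    }
    Fm[i] <- mean(rms)
  }
  lfit <- stats::lm(log(Fm) ~ log(ms))
  list(window_sizes = ms, fluctuation = Fm,
       alpha = unname(stats::coef(lfit)[2]))
}

#' Brute-force sample entropy reference implementation
#'
#' Double loop over all ordered template pairs at lengths `m` and `m + 1`
#' (both taken at the first `N - m` starting positions, self-matches
#' excluded), counting pairs whose distance falls below `r`, then
#' `ln(Cm / Cm+1)`. Quadratic in series length; intended only as an
#' independent cross-check for [sample_entropy()] on short fixtures.
#'
#' @param x z-scaled numeric vector.
#' @param m template length.
#' @param r radius.
#' @param norm `"euclidean"` or `"chebyshev"`.
#' @return list with `sen`, `cm`, `cm1` (`sen` is `NA` if `cm1` is 0).
#' @keywords internal
#' @export
sen_brute_force <- function(x, m = 2L, r = 0.25, norm = "euclidean") {
  x <- as_series_values(x)
  N <- length(x)
  nt <- N - m
  count_pairs <- function(len) {
    cnt <- 0L
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        a <- x[i:(i + len - 1L)]
        b <- x[j:(j + len - 1L)]
        d <- if (norm == "euclidean") sqrt(sum((a - b)^2)) else max(abs(a - b))
        if (d < r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  cm <- count_pairs(m)
  cm1 <- count_pairs(m + 1L)
  list(sen = if (cm1 == 0) NA_real_ else log(cm / cm1), cm = cm, cm1 = cm1)
}
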