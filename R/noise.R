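#' Specify a benchmark noise series
#'
#' Describes one of the three reference signal classes used to anchor the
#' complexity measures: Gaussian white noise (DFA scaling exponent
#' alpha ~ 0.5), Brownian noise, i.e. integrated white noise
#' (alpha ~ 1.5), and power-law ("1/f^beta") noise with a tunable target
#' exponent in between. Identical specs always generate identical series.
#'
#' @param kind one of `"white"`, `"brownian"`, `"power_law"`.
#' @param n_samples number of samples (at least 16).
#' @param target_alpha target DFA scaling exponent, used only for
#'   `kind = "power_law"`; must lie in `[0.3, 1.7]`.
#' @param seed integer seed controlling the draw.
#' @return an object of class `noise_spec`.
#' @seealso [gen_noise()]
#' @export
noise_spec <- function(kind = c("white", "brownian", "power_law"),
                       n_samples, target_alpha = NULL, seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar_number(n_samples, "n_samples")
  assert_scalar_number(seed, "seed")
  n_samples <- as.integer(n_samples)
  if (n_samples < 16L)
    ff_stop("`n_samples` must be at least 16", "forcefluct_invalid_argument")
  if (kind == "power_law") {
    if (is.null(target_alpha))
      ff_stop("`target_alpha` is required for power_law noise",
              "forcefluct_invalid_argument")
    assert_scalar_number(target_alpha, "target_alpha")
    if (target_alpha < 0.3 || target_alpha > 1.7)
      ff_stop("`target_alpha` must lie in [0.3, 1.7]",
              "forcefluct_invalid_argument")
  } else if (!is.null(target_alpha)) {
    ff_stop("`target_alpha` only applies to power_law noise",
            "forcefluct_invalid_argument")
  }
  structure(list(kind = kind, n_samples = n_samples,
                 target_alpha = target_alpha, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a benchmark noise series
#'
#' White noise is i.i.d. standard Gaussian; Brownian noise is its cumulative
#' sum. Power-law noise is synthesized in the frequency domain: Fourier
#' amplitudes proportional to `f^(-beta/2)` with `beta = 2*target_alpha - 1`
#' and i.i.d. uniform random phases, inverse-transformed to a real series and
#' standardized. The spectral route gives analytic control of the scaling
#' exponent, so DFA applied to the output recovers `target_alpha`.
#'
#' @param spec a [noise_spec()].
#' @return numeric vector of `spec$n_samples` dimensionless samples.
#' @examples
#' x <- gen_noise(noise_spec("white", 1680, seed = 7))
#' b <- gen_noise(noise_spec("brownian", 1680, seed = 7))
#' @export
gen_noise <- function(spec) {
  if (!inherits(spec, "noise_spec"))
    ff_stop("`spec` must be a noise_spec", "forcefluct_invalid_argument")
  n <- spec$n_samples
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  switch(spec$kind,
    white = stats::rnorm(n),
    brownian = cumsum(stats::rnorm(n)),
    power_law = synth_power_law(n, spec$target_alpha)
  )
}

# Spectral synthesis of 1/f^beta noise with beta = 2*alpha - 1.
synth_power_law <- function(n, alpha) {
  beta <- 2 * alpha - 1
  nf <- n %/% 2L
  f <- (1:nf) / n
  amp <- f^(-beta / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    # Nyquist bin must be real for a real-valued series.
    full[nf + 1L] <- complex(real = amp[nf] * sign(cos(phase[nf])))
    if (nf > 1L) full[n:(n - nf + 2L)] <- Conj(full[2:nf])
  } else {
    full[n:(n - nf + 1L)] <- Conj(full[2:(nf + 1L)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Save/restore the global RNG state so generators with their own seeds do
# not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
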