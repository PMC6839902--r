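# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# colored (1/f^alpha) Gaussian noise by spectral shaping of white noise;
# target one-sided PSD: scale^2 / max(f, floor_hz)^alpha  (units^2/Hz)
.one_over_f_noise <- function(n, fs, scale, alpha, floor_hz = 1) {
  freqs <- (0:(n - 1)) * fs / n
  f_fold <- pmin(freqs, fs - freqs) # two-sided axis
  s1 <- scale^2 / pmax(f_fold, floor_hz)^alpha
  # complex white spectrum with hermitian symmetry via rnorm in time domain
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  X <- W * sqrt(s1 * fs / 2) # |X_j|^2 scaled for one-sided density s1
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x
}

# expected one-sided background PSD at frequency f (units^2/Hz)
.background_psd <- function(f, scale, alpha, floor_hz = 1) {
  scale^2 / pmax(f, floor_hz)^alpha
}

# Lorentzian line share: fraction of a phase-diffusing sinusoid's power
# in [lo, hi], for diffusion D rad^2/s (half-width gamma = D/(4*pi) Hz)
.lorentzian_band_fraction <- function(f0, lo, hi, d_rate) {
  gamma <- d_rate / (4 * pi)
  if (gamma <= 0) return(as.numeric(lo <= f0 & f0 <= hi))
  (atan((hi - f0) / gamma) - atan((lo - f0) / gamma)) / pi
}
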