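# Discrete prolate spheroidal (Slepian) tapers.
#
# Computed from the symmetric tridiagonal matrix that commutes with the
# time-limited concentration operator; its eigenvectors are the DPSS in
# descending concentration order.  Concentrations are then evaluated
# exactly as quadratic forms with the sinc (Toeplitz) concentration
# kernel.  Results are cached per (n, nw, k) for the R session.

.taper_cache <- new.env(parent = emptyenv())

#' Compute a set of Slepian (DPSS) tapers
#'
#' Returns the `k` most concentrated discrete prolate spheroidal
#' sequences of length `n` with time-bandwidth product `nw`, the basis
#' behind all multitaper estimates in this package.  The half-bandwidth
#' of the resulting spectral window is `nw / n` cycles per sample
#' (`nw / T` Hz for a window of duration `T` seconds).
#'
#' @param n Number of samples per taper. Must be at least 8.
#' @param nw Time-bandwidth product (dimensionless), typically 1.5-4.
#' @param k Number of tapers. Values above `2 * nw - 1` have poor
#'   concentration; a warning is issued but computation proceeds.
#' @return An object of class `taper_set`: a list with `tapers` (an
#'   `n` by `k` matrix of orthonormal columns, concentration-ordered),
#'   `concentrations` (eigenvalues in (0, 1), strictly decreasing),
#'   `n`, `nw`, and `k`.
#' @examples
#' tp <- compute_tapers(512, nw = 3, k = 5)
#' round(tp$concentrations, 5)
#' @export
compute_tapers <- function(n, nw, k) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 8)
  stopifnot(is.numeric(nw), length(nw) == 1, nw > 0)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  n <- as.integer(n)
  k <- as.integer(k)
  if (k > floor(2 * nw) - 1) {
    warning(sprintf(
      "k = %d exceeds 2*nw - 1 = %g; higher-order tapers are poorly concentrated",
      k, 2 * nw - 1
    ))
  }
  key <- paste(n, nw, k, sep = "|")
  cached <- .taper_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }

  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]

  # sign convention: symmetric orders have positive mean; antisymmetric
  # orders start positive (matches the usual numerical libraries)
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-10) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] < 0) {
      V[, j] <- -V[, j]
    }
  }

  lambda <- .dpss_concentrations(V, w)

  out <- structure(
    list(tapers = V, concentrations = lambda, n = n, nw = nw, k = k),
    class = "taper_set"
  )
  .taper_cache[[key]] <- out
  out
}

# exact concentrations: lambda_j = v_j' S v_j with S the sinc kernel
.dpss_concentrations <- function(V, w) {
  n <- nrow(V)
  i <- 0:(n - 1)
  s <- ifelse(i == 0, 2 * w, sin(2 * pi * w * i) / (pi * i))
  S <- stats::toeplitz(s)
  as.numeric(colSums(V * (S %*% V)))
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf(
    "<taper_set> n = %d, nw = %g, k = %d\n  concentrations: %s\n",
    x$n, x$nw, x$k, paste(signif(x$concentrations, 6), collapse = ", ")
  ))
  invisible(x)
}
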