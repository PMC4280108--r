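# Shared signal-processing primitives: zero-phase filtering with reflection
# padding, FFT analytic signal, and DPSS (Slepian) tapers via the symmetric
# tridiagonal eigenproblem. These back the preprocessing, spectral,
# connectivity, entrainment and cross-frequency modules.

# two-pass (forward-backward) filtering of each row of a matrix, with
# reflection padding to suppress edge transients; pad is trimmed afterwards.
filtfilt_pad <- function(filt, a = 1, x, pad = NULL) {
  one <- is.null(dim(x))
  if (one) x <- matrix(x, nrow = 1)
  obj <- inherits(filt, c("Arma", "Ma", "Zpg"))  # fir1/butter return classed filters
  nb <- if (inherits(filt, "Arma")) length(filt$b) else length(unclass(filt))
  if (is.null(pad)) pad <- min(max(3L * nb, 100L), ncol(x) - 1L)
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(2 * xi[1] - rev(xi[seq_len(pad) + 1L]),
            xi,
            2 * xi[length(xi)] - xi[length(xi) - seq_len(pad)])
    yp <- if (obj) signal::filtfilt(filt, xp) else signal::filtfilt(filt, a, xp)
    out[i, ] <- yp[pad + seq_along(xi)]
  }
  if (one) out[1, ] else out
}

# zero-phase FIR band-pass applied to rows; order ~ 3 cycles of the low corner
fir_bandpass_rows <- function(x, rate, lo, hi, order = NULL) {
  nyq <- rate / 2
  if (!(lo > 0 && hi > lo && hi < nyq)) {
    stop("invalid corner frequencies: need 0 < lo < hi < rate/2")
  }
  if (is.null(order)) {
    order <- ceiling(3 * rate / lo)  # three periods of the slowest component
    order <- min(order, max(32L, floor((if (is.null(dim(x))) length(x) else ncol(x)) / 3) - 1L))
    if (order %% 2 == 1) order <- order + 1L  # even order -> symmetric FIR
  }
  b <- signal::fir1(order, c(lo, hi) / nyq, type = "pass")
  filtfilt_pad(b, 1, x)
}

# analytic signal via FFT (one-sided spectrum doubling)
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

instantaneous_phase <- function(x) Arg(hilbert_analytic(x))
instantaneous_amplitude <- function(x) Mod(hilbert_analytic(x))

# ---- DPSS (Slepian) tapers --------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with half-bandwidth
#' `w` (in cycles per sample), as eigenvectors of the standard symmetric
#' tridiagonal matrix. Tapers are unit-energy and sign-normalized
#' (first taper positive mean, subsequent tapers positive first lag), and
#' memoised per (n, w, k).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (N x W).
#' @param k number of tapers (defaults to `floor(2 * nw) - 1`).
#' @return n x k matrix, columns are tapers with unit sum of squares.
#' @export
dpss_tapers <- function(n, nw, k = max(1L, floor(2 * nw) - 1L)) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("n%d_nw%.6g_k%d", n, nw, k)
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t_ <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  tri <- matrix(0, n, n)
  diag(tri) <- diag_main
  tri[cbind(1:(n - 1), 2:n)] <- diag_off
  tri[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(tri, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (j %% 2 == 1) {
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {
      if (sum((n - 1 - 2 * t_) * v[, j]) < 0) v[, j] <- -v[, j]
    }
  }
  assign(key, v, envir = .dpss_cache)
  v
}
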