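# Empirical mode decomposition and Hilbert spectral helpers.
#
# Sifting with cubic-spline envelopes through local extrema, mirror-extended
# at the boundaries; the analytic signal is formed in the frequency domain.

# indices of strict local maxima (or minima of -x)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# spline envelope through extrema, mirrored about the record ends to tame
# boundary swing
envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) < 2) return(NULL)
  k <- min(2L, length(idx))
  left_t <- 2 - rev(idx[seq_len(k)])          # mirror about t = 1
  right_t <- 2 * n - rev(idx[length(idx) - seq_len(k) + 1])
  tt <- c(left_t, idx, right_t)
  vv <- c(rev(x[idx[seq_len(k)]]), x[idx],
          rev(x[idx[length(idx) - seq_len(k) + 1]]))
  stats::spline(tt, vv, xout = seq_len(n), method = "natural")$y
}

sift_imf <- function(x, max_sift = 50, sd_tol = 0.2) {
  h <- x
  for (i in seq_len(max_sift)) {
    up_i <- local_maxima(h)
    lo_i <- local_maxima(-h)
    if (length(up_i) < 2 || length(lo_i) < 2) return(NULL)
    up <- envelope(h, up_i)
    lo <- -envelope(-h, lo_i)
    m <- (up + lo) / 2
    h_new <- h - m
    denom <- sum(h^2)
    if (denom == 0) break
    if (sum((h - h_new)^2) / denom < sd_tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by iterative
#' sifting: each IMF is obtained by repeatedly subtracting the mean of the
#' upper and lower cubic-spline extrema envelopes until the standard
#' Cauchy-type criterion falls below 0.2, then removed from the residual.
#' Decomposition stops when the residual has fewer than two maxima/minima or
#' `max_imfs` is reached.
#'
#' @param x Numeric series.
#' @param max_imfs Maximum number of IMFs to extract.
#' @return List with `imfs` (matrix, one column per IMF; may have zero
#'   columns) and `residual`.
#' @export
emd_decompose <- function(x, max_imfs = 8) {
  res <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    imf <- sift_imf(res)
    if (is.null(imf) || all(imf == 0)) break
    imfs[[length(imfs) + 1]] <- imf
    res <- res - imf
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs) else
         matrix(numeric(0), length(x), 0),
       residual = res)
}

#' Analytic signal via the frequency domain
#'
#' @param x Real series.
#' @return Complex series whose real part is `x` and whose imaginary part is
#'   the Hilbert transform of `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# mean instantaneous frequency / amplitude of one component; the outer 5% of
# samples on each side are trimmed to suppress Hilbert edge artifacts
mean_inst_freq_amp <- function(x, fs) {
  z <- analytic_signal(x)
  phase <- unwrap_phase(Arg(z))
  inst_f <- diff(phase) * fs / (2 * pi)
  n <- length(inst_f)
  keep <- seq.int(max(1L, ceiling(0.05 * n)), min(n, floor(0.95 * n)))
  c(freq = mean(inst_f[keep]), amp = mean(Mod(z)[keep]))
}

#' Hilbert-Huang features of a series
#'
#' Empirical mode decomposition followed by, for each of the first
#' `n_imfs` IMFs, the mean analytic-signal instantaneous frequency (Hz) and
#' mean instantaneous amplitude. IMFs the decomposition does not yield are
#' reported as 0 and flagged.
#'
#' @param x Numeric series (length >= 100).
#' @param fs Sampling rate in Hz.
#' @param n_imfs Number of IMFs characterized (default 4).
#' @return Named numeric vector of `2 * n_imfs` values
#'   (`imf1_freq, imf1_amp, ...`) with attribute `missing_imfs` (count).
#' @export
hht_features <- function(x, fs, n_imfs = 4) {
  stopifnot(length(x) >= 100)
  out <- numeric(2 * n_imfs)
  names(out) <- as.vector(rbind(paste0("imf", seq_len(n_imfs), "_freq"),
                                paste0("imf", seq_len(n_imfs), "_amp")))
  missing <- n_imfs
  if (stats::sd(x) > 0) {
    dec <- emd_decompose(x, max_imfs = n_imfs)
    k <- ncol(dec$imfs)
    missing <- n_imfs - min(k, n_imfs)
    for (i in seq_len(min(k, n_imfs))) {
      fa <- mean_inst_freq_amp(dec$imfs[, i], fs)
      out[2 * i - 1] <- fa["freq"]
      out[2 * i] <- fa["amp"]
    }
  }
  attr(out, "missing_imfs") <- missing
  out
}
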