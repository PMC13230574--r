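# Butterworth design in zero-pole-gain form with biquad-cascade (second-order
# sections) zero-phase filtering.
#
# The vital-sign bands (0.1-0.5 Hz and 1.0-1.8 Hz at a 100 Hz slow-time rate)
# are so narrow relative to the sampling rate that a single transfer-function
# polynomial is numerically unstable in double precision (poles leave the unit
# circle after rounding). Designing in zpk form and filtering section by
# section keeps every stage well conditioned.

# Analog lowpass prototype poles for order n (Butterworth circle, Re < 0).
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Design a digital Butterworth as a list of biquad sections.
# type: "low", "high", "pass" (band-pass). W: cutoff(s) in Hz; fs in Hz.
butter_sos <- function(n, W, type = c("low", "high", "pass"), fs) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(W > 0), all(W < fs / 2))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  p_lp <- butter_prototype(n)

  if (type == "low") {
    wc <- warp(W[1])
    poles <- p_lp * wc
    zeros <- complex(0)          # n zeros at infinity
    gain <- wc^n
  } else if (type == "high") {
    wc <- warp(W[1])
    poles <- wc / p_lp
    zeros <- rep(0 + 0i, n)      # n zeros at s = 0
    gain <- 1
  } else {
    stopifnot(length(W) == 2, W[1] < W[2])
    wl <- warp(W[1]); wh <- warp(W[2])
    w0 <- sqrt(wl * wh); bw <- wh - wl
    # each prototype pole maps to a conjugate-completed pair
    b2 <- p_lp * bw / 2
    disc <- sqrt(b2^2 - w0^2)
    poles <- c(b2 + disc, b2 - disc)
    zeros <- rep(0 + 0i, n)      # n zeros at 0, n at infinity
    gain <- bw^n
  }

  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  n_inf <- length(poles) - length(zeros)   # zeros at infinity -> z = -1
  zd <- c(zd, rep(-1 + 0i, n_inf))
  kd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))

  # group roots into conjugate-closed pairs (plus at most one real
  # singleton) so every section has real coefficients; nearly-unstable
  # pairs stay together in their own well-conditioned section
  pg <- group_conjugate_pairs(pd)
  zg <- group_conjugate_pairs(zd)
  stopifnot(length(pg) == length(zg))
  sections <- lapply(seq_along(pg), function(i) {
    list(b = real_poly(zg[[i]]), a = real_poly(pg[[i]]))
  })
  sections[[1]]$b <- sections[[1]]$b * kd
  structure(list(sections = sections, n = n, W = W, type = type, fs = fs),
            class = "butter_sos")
}

# Partition roots into conjugate pairs, real pairs, and at most one real
# singleton, ordered by descending modulus.
group_conjugate_pairs <- function(v) {
  tol <- 1e-6 * max(1, max(Mod(v)))
  used <- logical(length(v))
  groups <- list()
  for (i in order(-Mod(v))) {
    if (used[i] || abs(Im(v[i])) <= tol) next
    j <- which(!used & Mod(v - Conj(v[i])) < tol)
    j <- setdiff(j, i)
    if (length(j) == 0) stop("unpaired complex root in filter design")
    groups[[length(groups) + 1]] <- c(v[i], v[j[1]])
    used[c(i, j[1])] <- TRUE
  }
  reals <- which(!used)
  reals <- reals[order(-Mod(v[reals]))]
  while (length(reals) >= 2) {
    groups[[length(groups) + 1]] <- v[reals[1:2]]
    reals <- reals[-(1:2)]
  }
  if (length(reals) == 1)
    groups[[length(groups) + 1]] <- v[reals]
  groups
}

# monic real polynomial (length 3) from a group of 1-2 roots
real_poly <- function(roots) {
  if (length(roots) == 2)
    c(1, -Re(roots[1] + roots[2]), Re(roots[1] * roots[2]))
  else
    c(1, -Re(roots), 0)
}

# Zero-phase (forward-backward) application of a biquad cascade.
# Order quoted for a filter refers to the designed prototype before the
# bidirectional pass, which squares the magnitude response.
#
# Each pass is run over an odd-symmetric extension of the record (length six
# time constants of the section's slowest pole) with the filter started in
# steady state for the first extended sample, so constants pass through
# exactly and edge transients stay inside the discarded padding.
sos_filtfilt <- function(filt, x) {
  stopifnot(inherits(filt, "butter_sos"))
  for (s in filt$sections) {
    x <- filtfilt_section(s$b, s$a, x)
  }
  x
}

filtfilt_section <- function(b, a, x) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(a))), 0)
  tc <- if (r >= 1) n else 1 / (1 - r)
  pl <- max(12L, min(n - 1L, as.integer(ceiling(6 * tc))))
  ext <- c(2 * x[1] - x[(pl + 1):2], x, 2 * x[n] - x[(n - 1):(n - pl)])
  g <- sum(b) / sum(a)
  one_pass <- function(v) {
    as.numeric(signal::filter(b, a, v, init.x = rep(v[1], 2),
                              init.y = rep(g * v[1], 2)))
  }
  y <- rev(one_pass(rev(one_pass(ext))))
  y[(pl + 1):(pl + n)]
}

# One-call convenience: design + zero-phase filter.
butter_filtfilt <- function(x, n, W, type, fs) {
  sos_filtfilt(butter_sos(n, W, type, fs), x)
}
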