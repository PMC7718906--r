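# Shared fixture builders. Everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_recording <- function(duration_s = 3, seed = 101, ...) {
  make_recording(duration_s, fs = 1000, params = artifact_params(...),
                 seed = seed)
}

# Independent ridge least-squares oracle: solves the same regularized
# problem as solve_frame_coefficients() but through an augmented-matrix
# QR factorization rather than LU on the normal equations.
ridge_qr_oracle <- function(current, prev, reg = 1e-8) {
  G <- prev %*% t(prev)
  lam <- reg * mean(diag(G))
  if (lam <= 0) lam <- reg
  A <- rbind(t(prev), diag(sqrt(lam), nrow(prev)))
  qr.solve(A, c(current, numeric(nrow(prev))))
}

# Offline brute-force re-solve of every frame of the adaptive filter.
adaptive_oracle <- function(x, L, M, reg = 1e-8) {
  n_frames <- length(x) %/% L
  y <- x
  if (n_frames < M + 1) return(y)
  for (k in (M + 1):n_frames) {
    cur <- x[((k - 1) * L + 1):(k * L)]
    prev <- t(vapply(seq_len(M), function(i)
      x[((k - i - 1) * L + 1):((k - i) * L)], numeric(L)))
    b <- ridge_qr_oracle(cur, prev, reg)
    y[((k - 1) * L + 1):(k * L)] <- cur - as.vector(t(prev) %*% b)
  }
  y
}

# Fraction of periodogram power inside a frequency band.
band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(n %/% 2) # exclude DC and Nyquist
  f <- (half - 1) * fs / n
  inside <- f >= band[1] & f <= band[2]
  sum(p[half][inside]) / sum(p[half])
}
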