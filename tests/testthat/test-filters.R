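test_that("comb_delay requires an integer sample-per-period ratio", {
  expect_identical(comb_delay(1000, 25), 40L)
  expect_identical(comb_delay(1000, 12.5), 80L)
  expect_error(comb_delay(1000, 30), class = "vemg_error_config")
  expect_error(comb_delay(0, 25), class = "vemg_error_parameter")
})

test_that("comb_apply nulls periodic inputs and doubles white-noise variance", {
  fs <- 1000
  # 25 Hz square wave: exactly 40-periodic, zero after the first period
  sq <- emg_trace(rep(rep(c(1, -1), each = 20), 25), fs = fs)
  y <- comb_apply(sq, comb_spec(fs, 25))
  expect_equal(y$value[41:1000], numeric(960))
  expect_equal(y$value[1:40], sq$value[1:40]) # zero pre-history start

  # white noise: var(x(n) - x(n - L)) = 2 sigma^2
  wn <- generate_vemg(60, fs, band = c(1, 499), rms = 1, seed = 11)
  yw <- comb_apply(wn, comb_spec(fs, 25))
  expect_lt(abs(mean(yw$value[41:60000]^2) / mean(wn$value^2) - 2), 0.1)

  # b = 0 is the identity
  expect_equal(comb_apply(wn, comb_spec(fs, 25, b = 0))$value, wn$value)

  expect_error(comb_apply(emg_trace(1:10, fs), comb_spec(fs, 25)),
               class = "vemg_error_parameter")
})

test_that("frame_signal splits into aligned non-overlapping frames", {
  tr <- emg_trace(1:35000, fs = 1000)
  f <- frame_signal(tr, 40)
  expect_equal(dim(f), c(40L, 875L))
  expect_equal(f[, 1], 1:40)

  # L = trace length gives a single frame
  expect_equal(ncol(frame_signal(emg_trace(1:40, 1000), 40)), 1L)

  # offset 5 on 85 samples: frames [6, 45] and [46, 85], trailing discarded
  f2 <- frame_signal(emg_trace(1:85, 1000), 40, offset = 5)
  expect_equal(ncol(f2), 2L)
  expect_equal(f2[, 1], 6:45)
  expect_equal(f2[, 2], 46:85)

  expect_error(frame_signal(emg_trace(1:30, 1000), 40),
               class = "vemg_error_parameter")
})

test_that("solve_frame_coefficients matches projection and pseudoinverse oracles", {
  set.seed(21)
  L <- 40; M <- 6

  # current identical to the first previous frame, others orthogonal-ish noise
  f1 <- rnorm(L)
  prev <- rbind(f1, matrix(rnorm((M - 1) * L), M - 1))
  # orthogonalize rows 2..M against f1 so the projection is exact
  for (i in 2:M) prev[i, ] <- prev[i, ] - sum(prev[i, ] * f1) / sum(f1^2) * f1
  b <- solve_frame_coefficients(f1, prev)
  expect_equal(b[1], 1, tolerance = 1e-6)
  expect_equal(b[-1], numeric(M - 1), tolerance = 1e-6)

  # current orthogonal to all previous frames: zero coefficients
  prev2 <- matrix(rnorm(M * L), M)
  cur <- rnorm(L)
  cur <- cur - as.vector(t(prev2) %*% solve(prev2 %*% t(prev2), prev2 %*% cur))
  expect_equal(solve_frame_coefficients(cur, prev2), numeric(M), tolerance = 1e-8)

  # rank-1 degenerate system: all previous frames equal the current frame;
  # ridge resolves to the minimum-norm solution b_i = 1/M
  f <- rnorm(L)
  prev3 <- matrix(rep(f, each = M), M)
  b3 <- solve_frame_coefficients(f, prev3)
  expect_equal(b3, rep(1 / M, M), tolerance = 1e-6)
  expect_equal(sum(b3), 1, tolerance = 1e-6)

  # agreement with an independent augmented-QR ridge solve
  for (k in 1:5) {
    cur <- rnorm(L)
    prev <- matrix(rnorm(M * L), M)
    expect_equal(solve_frame_coefficients(cur, prev),
                 ridge_qr_oracle(cur, prev), tolerance = 1e-9)
  }

  expect_error(solve_frame_coefficients(c(1, NA, numeric(L - 2)), prev),
               class = "vemg_error_data")
})

test_that("adaptive_apply cancels periodic input and matches the per-frame oracle", {
  fs <- 1000
  cfg <- adaptive_config(L = 40, M = 6)

  # exactly 40-periodic input: output ~ 0 after warm-up
  per <- emg_trace(rep(sin(2 * pi * (1:40) / 40) + 0.3, 50), fs = fs)
  res <- adaptive_apply(per, cfg)
  warm <- 6 * 40
  expect_lt(max(abs(res$trace$value[(warm + 1):2000])), 1e-6)
  # warm-up frames pass through by default
  expect_equal(res$trace$value[1:warm], per$value[1:warm])
  # zero-output warm-up policy
  res0 <- adaptive_apply(per, adaptive_config(L = 40, M = 6, warmup = "zero"))
  expect_equal(res0$trace$value[1:warm], numeric(warm))

  # output equals an independent brute-force least-squares re-solve per frame
  rec <- fixture_recording(3, seed = 31)
  out <- adaptive_apply(rec$contaminated, cfg)
  oracle <- adaptive_oracle(rec$contaminated$value, 40, 6)
  expect_lt(max(abs(out$trace$value - oracle)) / max(abs(oracle)), 1e-9)

  # white noise: per-frame coefficients small on average, mean near zero
  wn <- generate_vemg(20, fs, rms = 1, seed = 33)
  stw <- adaptive_apply(wn, cfg)$state
  cm <- colMeans(do.call(rbind, stw$coefficients))
  expect_lt(max(abs(cm)), 0.05)

  # coefficient bookkeeping: history rows = frames_processed - M
  expect_equal(length(stw$coefficients), stw$frames_processed - 6L)
  g <- glance(stw)
  expect_equal(g$frames_fitted, stw$frames_processed - 6L)
  td <- tidy(stw)
  expect_equal(nrow(td), 6L * length(stw$coefficients))

  expect_error(adaptive_apply(emg_trace(1:100, fs), cfg),
               class = "vemg_error_data")
})

test_that("streaming chunked processing is bitwise-identical to one-shot", {
  rec <- fixture_recording(2, seed = 41)
  cfg <- adaptive_config(L = 40, M = 6)
  one <- adaptive_apply(rec$contaminated, cfg, offset = 0)

  st <- new_adaptive_state(cfg, offset = 0, fs = 1000)
  x <- rec$contaminated$value
  out <- numeric(0)
  i <- 1
  set.seed(42)
  while (i <= length(x)) {
    k <- min(sample(1:97, 1), length(x) - i + 1)
    r <- adaptive_push(st, x[i:(i + k - 1)])
    st <- r$state
    out <- c(out, r$output)
    i <- i + k
  }
  out <- c(out, st$pending)
  expect_identical(out, one$trace$value)

  # offset samples pass through and frames align after them
  res_off <- adaptive_apply(rec$contaminated, cfg, offset = 7)
  expect_equal(res_off$trace$value[1:7], x[1:7])
})

test_that("filter_chain composes comb and adaptive stages", {
  rec <- fixture_recording(3, seed = 51)
  cfg <- adaptive_config(L = 40, M = 6)

  # use_comb = FALSE reproduces adaptive_apply exactly
  a <- adaptive_apply(rec$contaminated, cfg)
  b <- filter_chain(rec$contaminated, use_comb = FALSE, config = cfg)
  expect_identical(a$trace$value, b$trace$value)

  # clean uncontaminated Gaussian input: no blow-up (power bounded by the
  # chain's worst-case gain; comb at most doubles power, adaptive removes)
  cl <- generate_vemg(3, 1000, rms = 1, seed = 52)
  y <- filter_chain(cl, use_comb = TRUE, config = cfg)$trace
  expect_lt(mean(y$value^2), 4 * mean(cl$value^2))

  # residual in windows around pulses reduced by >= 20 dB vs input
  res <- filter_chain(rec$contaminated, use_comb = TRUE, config = cfg)$trace
  idx <- rec$pulse_indices[rec$pulse_indices > 7 * 40]
  win <- as.vector(outer(idx, -2:5, `+`))
  win <- win[win >= 1 & win <= nrow(res)]
  reduction <- 10 * log10(mean(res$value[win]^2) /
                          mean(rec$contaminated$value[win]^2))
  expect_lt(reduction, -20)

  expect_error(filter_chain(rec$contaminated, spec = comb_spec(2000, 25)),
               class = "vemg_error_config")
})
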