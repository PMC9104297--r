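test_that("response kernel peaks at the closed-form biexponential peak time", {
  k <- build_response_kernel(0.7, 2.0, fs = 8)
  t_star <- log(2 / 0.7) * (0.7 * 2) / (2 - 0.7) # about 1.13 s
  expect_equal(k$peak_time_s, t_star, tolerance = 1 / 8)
  expect_equal(k$peak_index, 10) # sample index 9, 0-based
  expect_equal(k$kernel[1], 0)   # k(0) = 0
  expect_true(all(k$kernel >= 0))
  expect_error(build_response_kernel(2, 0.7, 8), "tau_rise")
  # long decay limit: the rise dominates, kernel is monotone non-decreasing
  # well past the nominal rise time
  klong <- build_response_kernel(0.7, 5000, fs = 8)
  head_taps <- klong$kernel[1:40] # through 5 s, ~7 rise constants
  expect_true(all(diff(head_taps) >= -1e-12))
})

test_that("recursive kernel operator matches explicit convolution", {
  k <- build_response_kernel(0.7, 2.0, fs = 8, normalize_peak = TRUE)
  set.seed(2)
  p <- pmax(0, rnorm(120))
  y <- kernel_convolve(k, p)
  yref <- stats::convolve(c(p, numeric(length(k$kernel))),
                          rev(k$kernel), type = "open")[1:120]
  expect_equal(y, yref, tolerance = 1e-6)
  # adjoint identity <Kp, v> = <p, K'v>
  v <- rnorm(120)
  expect_equal(sum(y * v), sum(p * kernel_convolve(k, v, transpose = TRUE)),
               tolerance = 1e-8)
})

test_that("constant input decomposes into pure tonic with empty driver", {
  d <- decompose(rep(5, 480), fs = 8)
  expect_true(d$converged)
  expect_lt(max(abs(d$tonic - 5)), 0.05)
  expect_lt(max(abs(d$phasic)), 0.01)
  expect_lt(sum(d$driver), 1e-6)
})

test_that("tonic + phasic + residual reconstructs the input exactly", {
  set.seed(4)
  x <- 5 + cumsum(rnorm(960, 0, 0.02)) + clean_phasic(120, 8, c(20, 70), c(0.5, 0.3))
  d <- decompose(x, fs = 8)
  expect_lt(max(abs(d$tonic + d$phasic + d$residual - x)), 1e-9)
  expect_true(all(d$driver >= -1e-10))
  # phasic equals the kernel convolution of the driver
  expect_equal(d$phasic, kernel_convolve(d$kernel, d$driver), tolerance = 1e-12)
})

test_that("noiseless SCRs are recovered in time and shape", {
  cfg <- clean_sim_config()
  fs <- 8
  onsets <- c(15, 35, 55, 75, 95)
  ph <- clean_phasic(120, fs, onsets, rep(0.5, 5))
  d <- decompose(5 + ph, fs)
  expect_true(d$converged)
  expect_gte(cor(d$phasic, ph), 0.95)
  pk <- detect_scrs(d$driver, fs, 0.05)
  matched <- sum(vapply(onsets, function(o) any(abs(pk$peak_time_s - o) <= 1),
                        logical(1)))
  expect_gte(matched, 4)
})

test_that("driver L1 norm is monotone non-increasing in the sparsity weight", {
  set.seed(8)
  for (i in 1:6) {
    x <- 5 + 0.1 * cumsum(rnorm(160, 0, 0.1)) +
      clean_phasic(20, 8, c(4, 11), runif(2, 0.2, 0.6))
    alphas <- c(4e-4, 8e-4, 1.6e-3, 3.2e-3)
    l1 <- vapply(alphas, function(a) {
      d <- decompose(x, 8, decomposition_config(
        driver_sparsity_alpha = a, solver_tolerance = 1e-11,
        max_iterations = 30000))
      sum(d$driver)
    }, numeric(1))
    expect_true(all(diff(l1) <= 1e-6 + 1e-3 * l1[-length(l1)]))
  }
})

test_that("solver agrees with an independent dual active-set QP solve", {
  skip_if_not_installed("quadprog")
  set.seed(31)
  fs <- 8
  for (i in 1:4) {
    n <- 160
    x <- 5 + 0.2 * sin((1:n) / 30) +
      clean_phasic(n / fs, fs, c(5, 12), runif(2, 0.3, 0.7)) +
      rnorm(n, 0, 0.005)
    dcfg <- decomposition_config(solver_tolerance = 1e-13,
                                 max_iterations = 60000)
    d <- decompose(x, fs, dcfg)

    kern <- build_response_kernel(dcfg$tau_rise_s, dcfg$tau_decay_s, fs,
                                  normalize_peak = TRUE)
    K <- kernel_matrix(kern, n)
    bas <- edasite:::tonic_basis(n, fs, dcfg$tonic_knot_spacing_s,
                                 dcfg$tonic_smoothness_gamma)
    W <- diag(n) - bas$A %*% bas$Minv %*% t(bas$A)
    H <- t(K) %*% W %*% K
    cvec <- dcfg$driver_sparsity_alpha - as.numeric(t(K) %*% W %*% x)
    qp <- quadprog::solve.QP(H + diag(1e-9, n), -cvec, diag(n),
                             rep(0, n))
    phasic_ref <- as.numeric(K %*% qp$solution)
    rms <- sqrt(mean((d$phasic - phasic_ref)^2))
    expect_lt(rms, 1e-4)
  }
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  expect_error(decompose(c(rep(5, 40), NA, rep(5, 40)), 8), "non-finite")
  expect_error(decompose(rep(5, 40), 8), "10 s")
})
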