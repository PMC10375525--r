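test_that("decay model and IRF constructors validate their inputs", {
  m <- decay_components(c(4.39, 0.86), c(64.18, 35.82))
  expect_equal(m$lifetimes, c(0.86, 4.39))      # sorted ascending
  expect_equal(m$amplitudes, c(35.82, 64.18))   # reordered with them
  expect_error(decay_components(c(1, 1 + 1e-10)))  # duplicate lifetimes
  expect_error(decay_components(-1))
  expect_error(decay_components(2, -3))
  expect_error(decay_components(2, 0))             # not normalizable
  expect_error(decay_components(2, 1, background_fraction = 1))
  expect_error(gaussian_irf(fwhm_ps = 0))

  grid <- (0:4095 + 0.5) * 0.016
  expect_equal(sum(irf_profile(gaussian_irf(), grid)), 1, tolerance = 1e-12)
})

test_that("model_intensity matches exponential tail ratios with a delta-like IRF", {
  tau <- 2.5; bw <- 0.016
  m <- decay_components(tau)
  # delta-like IRF centred exactly on a bin centre
  irf <- gaussian_irf(fwhm_ps = 0.1, t0_ns = (31 + 0.5) * bw)
  p <- model_intensity(m, irf, (0:2047 + 0.5) * bw)
  idx <- 200:1200  # past the rise
  expect_equal(p[idx + 1] / p[idx], rep(exp(-bw / tau), length(idx)),
               tolerance = 1e-9)
})

test_that("numeric convolution matches the closed-form Gaussian x exponential", {
  # oracle: exponentially modified Gaussian density,
  # (1/2tau) exp(sigma^2/(2 tau^2) - (t - t0)/tau) *
  #   erfc((sigma/tau - (t - t0)/sigma)/sqrt 2)
  emg <- function(t, tau, sigma, t0) {
    z <- (sigma / tau - (t - t0) / sigma) / sqrt(2)
    0.5 / tau * exp(sigma^2 / (2 * tau^2) - (t - t0) / tau) *
      2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
  }
  bw <- 0.016
  times <- (0:4095 + 0.5) * bw
  for (tau in c(0.86, 4.39)) {
    irf <- gaussian_irf(fwhm_ps = 150, t0_ns = 1.6)
    m <- decay_components(tau)
    p <- model_intensity(m, irf, times, normalize = FALSE)
    # the unit-sum IRF profile absorbs one factor of bin width, so the
    # discrete convolution approximates integral of g(s) exp(-(t-s)/tau) ds
    # = tau * EMG density
    expected <- emg(times, tau, irf$sigma_ns, irf$t0_ns) * tau
    # compare beyond the rising edge, where the discrete sum is a
    # superconvergent quadrature of the continuous convolution
    idx <- times > irf$t0_ns + 10 * irf$sigma_ns & expected > 1e-12
    expect_equal(p[idx], expected[idx], tolerance = 1e-6)
  }
})

test_that("model_intensity is linear in amplitudes and conserves the integral", {
  times <- (0:2047 + 0.5) * 0.016
  irf <- gaussian_irf(t0_ns = 1)
  a <- c(35.82, 64.18); tau <- c(0.86, 4.39)
  p1 <- model_intensity(decay_components(tau, a), irf, times,
                        normalize = FALSE)
  p2 <- model_intensity(decay_components(tau, 3.7 * a), irf, times,
                        normalize = FALSE)
  expect_equal(p2, 3.7 * p1, tolerance = 1e-12)

  # convolution with a unit-sum IRF preserves the summed intensity on a
  # grid long enough that the truncated tail mass is negligible
  long_t <- (0:8191 + 0.5) * 0.016
  p_long <- model_intensity(decay_components(tau, a), irf, long_t,
                            normalize = FALSE)
  decay_sum <- sum(a[1] * exp(-(0:8191) * 0.016 / tau[1]) +
                     a[2] * exp(-(0:8191) * 0.016 / tau[2]))
  expect_equal(sum(p_long), decay_sum, tolerance = 1e-9)

  # zero-amplitude components with background give a flat profile
  flat <- model_intensity(decay_components(1, 0, background_fraction = 0.5),
                          irf, times)
  expect_equal(flat, rep(1 / length(times), length(times)),
               tolerance = 1e-12)

  expect_error(model_intensity(decay_components(1), irf, c(0, 1, 3)))
})

test_that("simulated histograms conserve counts and are seed-reproducible", {
  m <- sample7_components()
  irf <- gaussian_irf()
  h <- simulate_histogram(m, irf, total_counts = 12345, seed = 5)
  expect_equal(sum(h$counts), 12345)
  expect_equal(h$total_counts, 12345)
  h2 <- simulate_histogram(m, irf, total_counts = 12345, seed = 5)
  expect_identical(h$counts, h2$counts)
  h3 <- simulate_histogram(m, irf, total_counts = 12345, seed = 6)
  expect_false(identical(h$counts, h3$counts))
  expect_error(simulate_histogram(m, irf, 0))

  # Poisson option: expected total, not exact
  hp <- simulate_histogram(m, irf, 1e5, seed = 1, noise = "poisson")
  expect_gt(sum(hp$counts), 0.9e5)
  expect_lt(sum(hp$counts), 1.1e5)
})

test_that("empirical mean arrival time matches the exponential mean", {
  tau <- 4.11
  bw <- 0.016
  irf <- gaussian_irf(fwhm_ps = 0.1, t0_ns = 0.5 * bw)  # delta in bin 1
  n <- 1e6
  h <- simulate_histogram(decay_components(tau), irf, n, seed = 3,
                          bin_width = bw, n_bins = 8192)
  # mean lag after the excitation bin; the binned exponential has mean
  # bw / (exp(bw/tau) - 1) = tau - bw/2 + O(bw^2), and the Monte Carlo
  # scatter is ~ tau/sqrt(n)
  mean_lag <- sum((histogram_times(h) - 0.5 * bw) * h$counts) / sum(h$counts)
  expect_equal(mean_lag, bw / (exp(bw / tau) - 1), tolerance = 3 / sqrt(n))
  expect_equal(mean_lag, tau, tolerance = 3 * tau / sqrt(n) / tau + bw / tau)
})

test_that("simulated histograms converge to the model profile as counts grow", {
  m <- sample7_components()
  irf <- gaussian_irf()
  p <- model_intensity(m, irf)
  ks <- sapply(c(1e4, 1e6), function(n) {
    h <- simulate_histogram(m, irf, n, seed = 9)
    max(abs(cumsum(h$counts) / sum(h$counts) - cumsum(p)))
  })
  expect_lt(ks[2], ks[1])
  expect_lt(ks[2], 0.005)
})

test_that("histogram files round-trip exactly and reject malformed input", {
  h <- simulate_histogram(sample3_components(), gaussian_irf(), 5e4,
                          seed = 2, n_bins = 512)
  f <- withr::local_tempfile(fileext = ".txt")
  write_histogram(h, f)
  back <- read_histogram(f)
  expect_identical(back$counts, h$counts)
  expect_equal(back$bin_width, h$bin_width)
  expect_equal(back$total_counts, h$total_counts)

  # negative count
  bad1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.008\t10", "0.024\t-1", "0.040\t3"), bad1)
  expect_error(read_histogram(bad1), "line 2.*non-negative")

  # non-integer count
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.008\t10", "0.024\t1.5"), bad2)
  expect_error(read_histogram(bad2), "line 2")

  # non-uniform time axis
  bad3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0\t1", "1.0\t2", "2.5\t3"), bad3)
  expect_error(read_histogram(bad3), "non-uniform")

  # header total inconsistent with the column sum
  bad4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# total_counts=99", "0.0\t1", "1.0\t2"), bad4)
  expect_error(read_histogram(bad4), "total_counts")
})

test_that("key=value configs drive the generator", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# coupled-sample emulation",
               "lifetimes_ns = 0.86, 4.39",
               "amplitudes = 35.82, 64.18",
               "irf_fwhm_ps = 150",
               "total_counts = 20000",
               "n_bins = 1024",
               "seed = 4"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$model$lifetimes, c(0.86, 4.39))
  expect_equal(cfg$irf$fwhm_ps, 150)
  h <- simulate_histogram(cfg$model, cfg$irf, cfg$total_counts,
                          seed = cfg$seed, n_bins = cfg$n_bins)
  expect_equal(h$total_counts, 20000)
  expect_equal(h$n_bins, 1024)
})
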