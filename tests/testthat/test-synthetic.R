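test_that("gaussian_phase produces the stated bump and a residue-free wrap", {
  g <- gaussian_phase(100, 150, height = 30, sigma = 20)
  expect_equal(max(g$truth), 30)
  expect_identical(residue_count(g$wrapped), 0L)
  expect_identical(wrap_phase(g$truth), g$wrapped)

  # below the wrap threshold nothing wraps
  low <- gaussian_phase(40, 40, height = pi / 2, sigma = 8)
  expect_identical(low$wrapped, low$truth)
})

test_that("wrap-ring count along the central row matches the bump height", {
  g <- gaussian_phase(200, 300, height = 30, sigma = 40)
  row <- g$wrapped[round(g$center[1]), ]
  jumps <- abs(diff(row)) > pi
  # crossings of odd multiples of pi on the way up and down
  expect_identical(sum(jumps), as.integer(2 * floor((30 + pi) / (2 * pi))))
})

test_that("add_phase_noise is the identity in the no-noise limit", {
  g <- gaussian_phase(40, 60, height = 10, sigma = 10)
  out <- add_phase_noise(g$wrapped, speckle_variance = 0, snr = Inf)
  expect_equal(out, g$wrapped, tolerance = 1e-12)
})

test_that("noise generation is seed-reproducible and leaves the RNG stream alone", {
  g <- gaussian_phase(60, 80, height = 30, sigma = 15)
  set.seed(500); marker <- runif(1)
  set.seed(500)
  a <- add_phase_noise(g$wrapped, seed = 8)
  b <- add_phase_noise(g$wrapped, seed = 8)
  expect_identical(a, b)
  expect_gt(residue_count(a), 0L)
  expect_identical(runif(1), marker)  # caller's stream untouched

  c_ <- add_phase_noise(g$wrapped, seed = 9)
  expect_false(identical(a, c_))
})

test_that("realized additive-noise power matches the requested SNR within 5%", {
  g <- gaussian_phase(400, 600, height = 30)
  # replicate the documented construction under the same seed to expose the
  # internal fields, then measure the power ratio actually realized
  seed <- 13
  out <- add_phase_noise(g$wrapped, speckle_variance = 2, snr = 6, seed = seed)
  set.seed(seed)
  z <- exp(1i * g$wrapped)
  a <- sqrt(3 * 2)
  z <- z * (1 + runif(length(z), -a, a))
  s <- sqrt(mean(Mod(z)^2) / 6 / 2)
  noise <- complex(real = rnorm(length(z), sd = s),
                   imaginary = rnorm(length(z), sd = s))
  expect_identical(out, wrap_phase(atan2(Im(z + noise), Re(z + noise))))
  snr_realized <- mean(Mod(z)^2) / mean(Mod(noise)^2)
  expect_lt(abs(snr_realized - 6) / 6, 0.05)
})

test_that("vortex_phase realizes prescribed residue charges", {
  one <- vortex_phase(16, 16, data.frame(row = 8.5, col = 8.5, charge = 1))
  expect_identical(sum(residue_map(one)), 1L)

  pair <- vortex_phase(24, 24, data.frame(row = c(12.5, 12.5),
                                          col = c(10.5, 14.5), charge = c(1, -1)))
  rp <- residue_map(pair)
  expect_identical(sum(rp), 0L)
  expect_identical(sum(rp != 0L), 2L)

  set.seed(6)
  spec5 <- data.frame(row = c(6.5, 6.5, 18.5, 18.5, 12.5),
                      col = c(6.5, 18.5, 6.5, 18.5, 12.5),
                      charge = c(1, -1, 1, -1, 1))
  p5 <- vortex_phase(25, 25, spec5)
  rm5 <- residue_map(p5)
  expect_identical(rm5, bf_residue_map(p5))
  for (k in 1:5) {
    expect_identical(rm5[floor(spec5$row[k]), floor(spec5$col[k])],
                     as.integer(spec5$charge[k]))
  }

  expect_error(vortex_phase(10, 10, data.frame(row = c(5.5, 5.5), col = c(5.5, 5.5),
                                               charge = c(1, 1))), "coincident")
  expect_error(vortex_phase(10, 10, data.frame(row = 5, col = 5, charge = 1)),
               "pixel centers")
})

test_that("textured_phase is wrap-free, residue-free and spectrally broad", {
  tp <- textured_phase(96, 128, seed = 10)
  expect_true(all(tp > -pi & tp <= pi))
  expect_identical(residue_count(tp), 0L)
  expect_identical(tp, textured_phase(96, 128, seed = 10))  # bit-reproducible

  rs <- radial_spectrum(phasor_spectrum(tp), n_bins = 32)
  # intensity stays well above the eps floor out to half of Nyquist
  floor_log <- log(.Machine$double.eps) + max(rs$logI)
  expect_true(all(rs$logI[rs$k <= 0.5] > floor_log + 5))

  # the hard band limit really cuts the spectrum of the phase itself
  bl <- textured_phase(96, 128, seed = 10, kmax = 0.2)
  sp <- .fftshift_for_tests(Mod(stats::fft(bl)))
  ky <- (seq_len(96) - (48 + 1)) / 48; kx <- (seq_len(128) - (64 + 1)) / 64
  k <- sqrt(outer(ky^2, kx^2, "+"))
  expect_lt(max(sp[k > 0.25]), 1e-8 * max(sp))
})
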