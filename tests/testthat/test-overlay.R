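test_that("spectrum I/O parses, rejects bad rows and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("250,0.1", "260,0.4"), f)
  s <- read_spectrum(f)
  expect_s3_class(s, "spectrum")
  expect_equal(s$wavelength, c(250, 260))
  writeLines(c("wavelength,abs", "250,0.1", "260,0.4"), f)
  expect_equal(read_spectrum(f)$intensity, c(0.1, 0.4))
  writeLines(c("250,0.1", "abc,0.4"), f)
  expect_error(read_spectrum(f), "line 2")
  writeLines(c("250,0.1", "250,0.2", "260,0.4"), f)
  expect_error(read_spectrum(f), "duplicate wavelength")
  writeLines("250,0.1", f)
  expect_error(read_spectrum(f), "at least 2")
  # generator output round-trips losslessly
  g <- make_spectrum(list(c(350, 1, 20), c(420, 0.5, 15)),
                     grid = c(250, 500, 1), noise_sd = 0.01, seed = 5)
  write_spectrum(g, f)
  g2 <- read_spectrum(f)
  expect_equal(g2$wavelength, g$wavelength)
  expect_equal(g2$intensity, g$intensity, tolerance = 1e-12)
})

test_that("clipping is inclusive and guards against empty overlap", {
  s <- make_spectrum(list(c(350, 1, 40)), grid = c(190, 900, 1))
  cl <- clip_spectrum(s, c(250, 500))
  expect_equal(range(cl$wavelength), c(250, 500))
  expect_equal(clip_spectrum(s, c(190, 900)), s)
  expect_error(clip_spectrum(make_spectrum(list(c(350, 1, 40)),
                                           grid = c(190, 500, 1)),
                             c(600, 700)), "overlap")
  expect_error(clip_spectrum(s, c(500, 250)), "low < high")
})

test_that("normalisation scales the maximum to 1 and is idempotent", {
  s <- band_spectrum(c(1, 2, 3), c(0.5, 2.0, 1.0))
  n <- normalise_spectrum(s)
  expect_equal(n$intensity, c(0.25, 1, 0.5))
  expect_equal(normalise_spectrum(n), n)
  expect_error(normalise_spectrum(band_spectrum(c(1, 2), c(0, 0))),
               "not positive")
})

test_that("alignment interpolates the standard onto the unknown's grid", {
  u <- band_spectrum(seq(250, 260, 2), rep(1, 6))
  s <- band_spectrum(seq(250, 260, 1), seq(0, 1, length.out = 11))
  p <- align_spectra(u, s)
  expect_equal(p$wavelength, seq(250, 260, 2))
  expect_equal(p$standard, seq(0, 1, length.out = 11)[c(1, 3, 5, 7, 9, 11)])
  expect_error(align_spectra(u, band_spectrum(c(300, 310), c(1, 2))),
               "overlap")
})

test_that("identical spectra score r = 1 and 100% within band", {
  s <- make_spectrum(list(c(350, 1, 20)), grid = c(250, 500, 1))
  res <- score_overlay(s, s, window = c(250, 500))
  expect_equal(res$pearson_r, 1)
  expect_equal(res$percent_within, 100)
  expect_equal(res$n_points, 251)
})

test_that("a constant 0.2 offset on normalised curves scores 0% within", {
  # unknown: triangle with max 1; standard: unknown - 0.2 at every unknown
  # wavelength, with its own maximum of 1 on a narrow spike at 375.5 nm that
  # the unknown's integer grid never samples. Both normalise by 1, so the
  # normalised gap is exactly 0.2 > 0.125 at every compared point.
  u_wl <- seq(250, 500, 1)
  u_y <- 1 - abs(u_wl - 375) / 250 # in [0.5, 1], max 1 at 375
  s_wl <- sort(c(u_wl, 375.5))
  s_y <- c((u_y - 0.2)[u_wl <= 375], 1, (u_y - 0.2)[u_wl > 375])
  u <- band_spectrum(u_wl, u_y)
  s <- band_spectrum(s_wl, s_y)
  res <- score_overlay(u, s, window = c(250, 500))
  expect_equal(res$percent_within, 0)
})

test_that("overlay scores match the direct-summation oracle", {
  # the worked two-Gaussian case first
  u <- make_spectrum(list(c(350, 1, 20)), grid = c(250, 500, 1))
  s <- make_spectrum(list(c(360, 1, 20)), grid = c(250, 500, 1))
  res <- score_overlay(u, s, window = c(250, 500))
  want <- oracle_overlay(u$wavelength, u$intensity, s$wavelength, s$intensity,
                         c(250, 500))
  expect_equal(res$pearson_r, want$r, tolerance = 1e-12)
  expect_equal(res$percent_within, want$pct, tolerance = 1e-12)
  # then random synthetic pairs, including unequal grids and noise
  for (seed in 1:100) {
    withr::with_seed(seed, {
      mk <- function(np) lapply(seq_len(np), function(i)
        c(runif(1, 270, 480), runif(1, 0.3, 2), runif(1, 8, 50)))
      peaks_u <- mk(sample(1:3, 1))
      peaks_s <- mk(sample(1:3, 1))
      step_u <- sample(c(1, 2), 1)
    })
    u <- make_spectrum(peaks_u, grid = c(250, 500, step_u),
                       noise_sd = 0.02, seed = seed)
    s <- make_spectrum(peaks_s, grid = c(248, 502, 1),
                       noise_sd = 0.02, seed = seed + 1000)
    # guard: noise could in principle push all intensities <= 0 (never does)
    res <- score_overlay(u, s, window = c(250, 500))
    want <- oracle_overlay(u$wavelength, u$intensity, s$wavelength,
                           s$intensity, c(250, 500))
    expect_equal(res$pearson_r, want$r, tolerance = 1e-9,
                 label = paste("pearson seed", seed))
    expect_equal(res$percent_within, want$pct, tolerance = 1e-9,
                 label = paste("percent seed", seed))
    expect_equal(res$n_points, want$n)
  }
})

test_that("percent-within never increases as the band shrinks", {
  u <- make_spectrum(list(c(340, 1, 25)), grid = c(250, 500, 1),
                     noise_sd = 0.03, seed = 2)
  s <- make_spectrum(list(c(352, 1.2, 30)), grid = c(250, 500, 1))
  bands <- c(0.3, 0.2, 0.125, 0.08, 0.04, 0.01)
  pct <- vapply(bands, function(b)
    score_overlay(u, s, window = c(250, 500), band = b)$percent_within,
    numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("degenerate constant spectra are rejected", {
  wl <- seq(250, 500, 1)
  flat <- band_spectrum(wl, rep(1, length(wl)))
  ok <- make_spectrum(list(c(350, 1, 20)), grid = c(250, 500, 1))
  expect_error(score_overlay(flat, ok, window = c(250, 500)), "constant")
})
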