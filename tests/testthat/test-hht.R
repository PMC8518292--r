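test_that("the analytic signal recovers a tone's amplitude and frequency", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  a <- analytic_signal(2 * sin(2 * pi * 40 * t), fs)
  interior <- 200:1800
  expect_lt(max(abs(a$amplitude[interior] - 2)) / 2, 0.02)
  expect_lt(max(abs(a$inst_freq[interior] - 40)), 1)
  expect_true(all(a$amplitude >= 0))
  expect_length(a$inst_freq, length(t))

  ac <- analytic_signal(2 * cos(2 * pi * 40 * t), fs)
  expect_equal(ac$amplitude[interior], a$amplitude[interior], tolerance = 1e-3)

  z <- analytic_signal(numeric(512), fs)
  expect_equal(z$amplitude, numeric(512))
})

test_that("the marginal spectrum concentrates a tone and conserves mass", {
  fs <- 4000
  t <- seq(0, 15, by = 1 / fs)
  a <- analytic_signal(sin(2 * pi * 40 * t), fs)
  ms <- marginal_spectrum(a, bin_hz = 1)
  expect_true(all(diff(ms$freqs) > 0))
  expect_lte(max(ms$freqs), fs / 2)
  near <- abs(ms$freqs - 40) <= 5
  expect_gte(sum(ms$amplitude[near]) / sum(ms$amplitude), 0.90)

  # rebinning preserves the accumulated total: sum h(w) == sum amp * dt
  total <- sum(a$amplitude) / fs
  for (bw in c(0.5, 1, 5, 20))
    expect_equal(sum(marginal_spectrum(a, bin_hz = bw)$amplitude), total)

  zero <- marginal_spectrum(analytic_signal(numeric(1000), fs), bin_hz = 1)
  expect_true(all(zero$amplitude == 0))
})

test_that("instantaneous energy is the squared-amplitude sum across IMFs", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)
  a <- analytic_signal(x, fs)
  ie <- instantaneous_energy(list(a))
  interior <- 200:1800
  expect_lt(max(abs(ie[interior] - 1)), 0.05)
  expect_true(all(ie >= 0))

  ie3 <- instantaneous_energy(list(analytic_signal(3 * x, fs)))
  expect_equal(ie3[interior], 9 * ie[interior], tolerance = 1e-9)

  expect_equal(instantaneous_energy(list(analytic_signal(numeric(100), fs))),
               numeric(100))
})

test_that("the ten statistics match hand arithmetic and moment conventions", {
  st <- imf_statistics(c(1, 2, 3, 4))
  expect_equal(st[["mean"]], 2.5)
  expect_equal(st[["var"]], 1.25)       # population divisor N
  expect_equal(st[["sd"]], sqrt(1.25))
  expect_equal(st[["energy"]], 30)      # sum of squares
  expect_equal(st[["skewness"]], 0)
  expect_equal(st[["max"]], 4)
  expect_equal(st[["min"]], 1)
  expect_equal(st[["median"]], 2.5)

  set.seed(7)
  z <- rnorm(2e5)
  stz <- imf_statistics(z)
  expect_equal(stz[["kurtosis"]], 3, tolerance = 0.2 / 3) # non-excess
  expect_lt(abs(stz[["skewness"]]), 0.1)

  const <- imf_statistics(rep(2, 10))
  expect_equal(const[["sd"]], 0)
  expect_equal(const[["kurtosis"]], 0)
  expect_equal(const[["skewness"]], 0)
  expect_true(attr(const, "degenerate"))
  expect_equal(const[["mode"]], 2)
})

test_that("statistics agree with an independent implementation to 1e-10", {
  set.seed(123)
  for (i in 1:100) {
    x <- rnorm(sample(20:200, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.1, 4))
    mine <- imf_statistics(x)
    ref <- oracle_stats(x)
    for (nm in names(ref))
      expect_equal(mine[[nm]], ref[[nm]], tolerance = 1e-10)
  }
})

test_that("feature extraction yields channels x IMFs x statistics features", {
  spec <- synthetic_spec(fs = 2000, duration = 17, n_channels = 4)
  rec <- generate_recording(spec, "moderate", seed = 6)
  segs <- preprocess_recording(rec, duration_s = 1)
  fv <- extract_features(segs, n_imf = 10, ensemble_size = 3, seed = 2)
  expect_length(fv, 400) # 4 channels x 10 IMFs x 10 statistics
  info <- attr(fv, "info")
  expect_equal(nrow(info), 400)
  expect_equal(unique(info$channel), c("L1", "L2", "L3", "L4"))
  expect_equal(names(fv)[1], "L1_imf1_sd")
  expect_equal(attr(fv, "label"), "moderate")

  again <- extract_features(segs, n_imf = 10, ensemble_size = 3, seed = 2)
  expect_identical(as.numeric(fv), as.numeric(again))
})

test_that("feature tables roundtrip through CSV", {
  tab <- demo_feature_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$features, tab$features, tolerance = 1e-12)
  expect_equal(as.character(back$label), as.character(tab$label))
  expect_equal(back$info$channel, tab$info$channel)
  expect_equal(back$info$imf, tab$info$imf)
  expect_equal(back$info$stat, tab$info$stat)
})
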