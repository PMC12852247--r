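sr <- 48000

test_that("a pure tone yields a single-line spectrum at the tone frequency", {
  x <- sin(2 * pi * 2000 * seq_len(sr / 2) / sr)
  f <- extract_features(x, sr)
  bin <- sr / 512 # one FFT bin at the default window
  expect_equal(unname(f["duration"]), 0.5)
  expect_lt(abs(f["peak_frequency"] - 2000), bin + 1e-9)
  for (p in c("q25", "q50", "q75", "spectral_centroid"))
    expect_lt(abs(f[p] - 2000), bin + 1e-9)
})

test_that("white noise has its centroid near half Nyquist", {
  set.seed(1)
  f <- extract_features(rnorm(sr / 2), sr)
  expect_equal(unname(f["spectral_centroid"]), 12000, tolerance = 0.05)
})

test_that("duration is exact bookkeeping", {
  set.seed(2)
  f <- extract_features(rnorm(12000), sr)
  expect_equal(unname(f["duration"]), 0.250)
})

test_that("degenerate segments are rejected", {
  expect_error(extract_features(rnorm(100), sr), "shorter than one")
  expect_error(extract_features(rep(0, 5000), sr), "silent")
  expect_error(extract_features(c(rnorm(5000), NA), sr), "non-finite")
})

test_that("amplitude scaling moves only mean_amplitude", {
  set.seed(3)
  x <- synthesize_call_waveform(
    c(duration = 0.3, q25 = 1500, q50 = 2000, q75 = 2600), sr)
  f1 <- extract_features(x, sr)
  f2 <- extract_features(3.5 * x, sr)
  expect_equal(unname(f2["mean_amplitude"]),
               unname(3.5 * f1["mean_amplitude"]))
  for (p in c("peak_frequency", "q25", "q50", "q75",
              "spectral_centroid", "spectral_slope"))
    expect_equal(unname(f2[p]), unname(f1[p]))
})

test_that("quantile ordering holds for arbitrary band-noise signals", {
  set.seed(4)
  for (i in 1:20) {
    q <- sort(runif(3, 500, 20000))
    w <- synthesize_call_waveform(
      c(duration = runif(1, 0.05, 0.3), q25 = q[1], q50 = q[2], q75 = q[3]),
      sr)
    f <- extract_features(w, sr)
    expect_true(f["q25"] <= f["q50"] && f["q50"] <= f["q75"])
  }
})

test_that("synthesis -> extraction round-trips spectral targets within 10%", {
  set.seed(5)
  for (i in 1:10) {
    centre <- runif(1, 1200, 6000)
    target <- c(duration = 0.25, mean_amplitude = 0.1,
                q25 = centre * 0.85, q50 = centre, q75 = centre * 1.15)
    f <- extract_features(synthesize_call_waveform(target, sr), sr)
    for (p in c("q25", "q50", "q75"))
      expect_lt(abs(f[p] - target[p]) / target[p], 0.10)
    expect_lt(abs(f["spectral_centroid"] - centre) / centre, 0.10)
    expect_equal(unname(f["mean_amplitude"]), 0.1, tolerance = 0.05)
  }
  # narrow band at 2 kHz: centroid within +/- 200 Hz
  f <- extract_features(synthesize_call_waveform(
    c(duration = 0.25, q25 = 1900, q50 = 2000, q75 = 2100), sr), sr)
  expect_lt(abs(f["spectral_centroid"] - 2000), 200)
})

test_that("segmentation finds bursts and ignores silence", {
  expect_identical(nrow(detect_call_boundaries(rep(0, sr), sr)), 0L)
  expect_identical(nrow(detect_call_boundaries(numeric(0), sr)), 0L)
  expect_error(detect_call_boundaries(c(1, NA), sr), "non-finite")

  burst <- sin(2 * pi * 1000 * seq_len(0.1 * sr) / sr)
  sig <- c(rep(0, 0.1 * sr), burst, rep(0, 0.5 * sr), burst, rep(0, 0.1 * sr))
  seg <- detect_call_boundaries(sig, sr, min_gap = 0.05)
  expect_identical(nrow(seg), 2L)
  expect_lt(abs(seg$start[1] - 0.1), 0.005)
  expect_lt(abs(seg$end[1] - 0.2), 0.005)
  expect_lt(abs(seg$start[2] - 0.7), 0.005)

  # gaps below min_gap are bridged
  seg1 <- detect_call_boundaries(sig, sr, min_gap = 0.6)
  expect_identical(nrow(seg1), 1L)

  # bursts shorter than min_duration are discarded
  short <- c(rep(0, 4800), sin(2 * pi * 1000 * seq_len(480) / sr),
             rep(0, 4800))
  expect_identical(
    nrow(detect_call_boundaries(short, sr, min_duration = 0.03)), 0L)
})

test_that("WAV files round-trip and channel selection works", {
  set.seed(6)
  mono <- runif(4800, -0.5, 0.5)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(mono, sr, p)
  back <- read_wav(p)
  expect_identical(back$sample_rate, sr)
  expect_equal(back$samples, mono, tolerance = 1e-4)

  stereo <- cbind(mono, rev(mono))
  write_wav(stereo, sr, p)
  expect_equal(read_wav(p, channel = 2)$samples, rev(mono),
               tolerance = 1e-4)
  expect_error(read_wav(p, channel = 3), "channel")
})

test_that("extract_features_table processes annotated WAV directories", {
  dir <- withr::local_tempdir()
  set.seed(7)
  targets <- list(
    c(duration = 0.2, q25 = 1500, q50 = 1800, q75 = 2200),
    c(duration = 0.3, q25 = 2500, q50 = 3000, q75 = 3600))
  for (i in 1:2) {
    w <- synthesize_call_waveform(targets[[i]], sr)
    pad <- rep(0, 0.05 * sr)
    write_wav(c(pad, w, pad), sr, file.path(dir, sprintf("c%d.wav", i)))
  }
  ann <- data.frame(file = c("c1.wav", "c2.wav"),
                    call_id = c("a", "b"), individual = c("i1", "i2"))
  tab <- extract_features_table(dir, ann)
  expect_identical(nrow(tab), 2L)
  expect_true(all(acoustic_parameter_names() %in% names(tab)))
  expect_equal(tab$duration, c(0.2, 0.3), tolerance = 0.05)
  expect_lt(abs(tab$q50[1] - 1800) / 1800, 0.15)
  expect_lt(abs(tab$q50[2] - 3000) / 3000, 0.15)
})
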