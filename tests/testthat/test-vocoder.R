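spec_default <- vocoder_spec(noise_seed = 7)

test_that("band edges are logarithmically spaced and validated", {
  edges <- spec_default$band_edges
  ratios <- edges[-1] / edges[-length(edges)]
  expect_lt(diff(range(ratios)), 1e-9 * mean(ratios))
  # geometric-progression oracle
  expect_equal(edges, edges[1] * (edges[11] / edges[1])^((0:10) / 10),
               tolerance = 1e-12)
  expect_error(vocoder_spec(overlap = 1), "overlap")
  expect_error(vocoder_spec(band_edges = c(100, 200, 300), n_bands = 2),
               "logarithmically")
  expect_error(vocoder_spec(fft_size = 128, overlap = 0.9), "integer")
})

test_that("the filterbank covers the analysis range with non-empty bands", {
  fb <- design_filterbank(spec_default)
  expect_equal(fb$n_bands, 10)
  freq <- fb$bin_freq
  in_range <- freq >= fb$edges[1] & freq <= freq[length(freq)]
  expect_true(all(fb$assignment[in_range] > 0))       # every bin covered
  expect_true(all(fb$assignment[!in_range] == 0))
  expect_true(all(tabulate(fb$assignment, 10) >= 1))
  expect_equal(fb$centers, sqrt(fb$edges[-11] * fb$edges[-1]))
  # one band spans the whole analysis range
  fb1 <- design_filterbank(vocoder_spec(n_bands = 1))
  expect_equal(max(fb1$assignment), 1)
  # the paper-silent 80 Hz low edge leaves a default band empty
  expect_error(design_filterbank(vocoder_spec(low_edge = 80)), "no FFT bin")
  expect_error(design_filterbank(vocoder_spec(fft_size = 16, overlap = 0.75,
                                              n_bands = 10)), "too few bins")
})

test_that("stft frames advance by fft_size*(1-overlap) and respect linearity", {
  expect_equal(spec_default$hop, 32)
  x0 <- numeric(1000)
  st0 <- stft(x0, spec_default)
  expect_true(all(Mod(st0$spectrum) == 0))
  set.seed(4)
  x <- rnorm(1000)
  st <- stft(x, spec_default)
  expect_equal(st$n_frames, ceiling((1000 - 128) / 32) + 1)
  expect_equal(nrow(st$spectrum), 65)
})

test_that("windowed frame energy equals total bin energy (Parseval)", {
  set.seed(11)
  x <- rnorm(2000)
  N <- 128
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))
  for (start in c(1, 321, 993)) {
    fr <- x[start:(start + N - 1)] * w
    # direct DFT oracle: sum |X_k|^2 / N over the full two-sided spectrum
    expect_equal(sum(Mod(fft(fr))^2) / N, sum(fr^2), tolerance = 1e-10)
  }
  # and the one-sided band decomposition preserves the assigned-bin energy
  spec <- vocoder_spec()
  fb <- design_filterbank(spec)
  st <- stft(x, spec)
  env <- band_envelopes(st, fb)
  direct <- colSums(Mod(st$spectrum[fb$assignment > 0, , drop = FALSE])^2)
  expect_equal(colSums(env$values^2), direct, tolerance = 1e-10)
})

test_that("band envelopes are nonnegative, homogeneous and band-selective", {
  fb <- design_filterbank(spec_default)
  set.seed(5)
  x <- rnorm(4000)
  e1 <- band_envelopes(stft(x, spec_default), fb)
  expect_true(all(e1$values >= 0))
  e3 <- band_envelopes(stft(3 * x, spec_default), fb)
  expect_equal(e3$values, 3 * e1$values, tolerance = 1e-10)
  ez <- band_envelopes(stft(numeric(500), spec_default), fb)
  expect_true(all(ez$values == 0))
  # pure tone at a band center concentrates envelope mass in that band
  for (b in c(2, 5, 9)) {
    t <- seq_len(16000) / 16000
    tone <- sin(2 * pi * fb$centers[b] * t)
    ev <- band_envelopes(stft(tone, spec_default), fb)$values
    mass <- rowSums(ev^2)
    expect_gt(mass[b] / sum(mass), 0.95)
  }
})

test_that("noise carriers decay at the configured spread slope", {
  fb <- design_filterbank(spec_default)
  L <- 4 * 16000
  n_frames <- (L - 128) %/% 32 + 1
  env <- structure(list(values = matrix(0, 10, n_frames), frame_hop = 32,
                        fft_size = 128, band_centers = fb$centers,
                        band_edges = fb$edges, signal_length = L,
                        sample_rate = 16000),
                   class = "envelope_matrix")
  env$values[3, ] <- 1
  out <- synthesize(env, spec_default)
  # Welch periodogram regression over >= 2 octaves above the band
  seg <- 2048; hop <- 1024
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))
  P <- 0
  for (i in 0:((L - seg) %/% hop)) {
    fr <- out[(i * hop + 1):(i * hop + seg)] * w
    P <- P + Mod(fft(fr)[1:(seg / 2 + 1)])^2
  }
  f <- (0:(seg / 2)) * 16000 / seg
  hi <- fb$edges[4]
  sel <- f >= 2 * hi & f <= 7600
  slope <- coef(lm(10 * log10(P[sel]) ~ log2(f[sel])))[2]
  expect_lt(abs(slope - (-spec_default$spread_slope)), 0.5)
})

test_that("synthesis scales band energy with the squared envelope", {
  fb <- design_filterbank(spec_default)
  n_frames <- 200
  L <- (n_frames - 1) * 32 + 128
  mk <- function(amp) {
    e <- structure(list(values = matrix(0, 10, n_frames), frame_hop = 32,
                        fft_size = 128, band_centers = fb$centers,
                        band_edges = fb$edges, signal_length = L,
                        sample_rate = 16000), class = "envelope_matrix")
    e$values[6, ] <- amp
    synthesize(e, spec_default)
  }
  out1 <- mk(1); out2 <- mk(2.5)
  expect_equal(sum(out2^2) / sum(out1^2), 2.5^2, tolerance = 1e-8)
  ez <- mk(0)
  expect_true(all(ez == 0))
})

test_that("vocoding is seed-deterministic, silence-preserving and envelope-faithful", {
  set.seed(8)
  x <- rnorm(8000)
  expect_identical(vocode(x, spec_default), vocode(x, spec_default))
  other <- vocoder_spec(noise_seed = 8)
  expect_false(identical(vocode(x, spec_default), vocode(x, other)))
  expect_true(all(vocode(numeric(2000), spec_default) == 0))
  expect_error(vocode(x, spec_default, sample_rate = 44100), "resample")

  # speech-like AM test signal: tones at band centers, shared 3 Hz envelope
  fb <- design_filterbank(spec_default)
  t <- seq_len(4 * 16000) / 16000
  am <- (1 + sin(2 * pi * 3 * t)) / 2
  sig <- rowSums(sapply(fb$centers, function(fc) sin(2 * pi * fc * t))) * am
  v <- vocode(sig, spec_default)
  expect_equal(length(v), length(sig))
  expect_equal(sqrt(mean(v^2)), sqrt(mean(sig^2)), tolerance = 1e-9)
  e_in <- band_envelopes(stft(sig, spec_default), fb)$values
  e_out <- band_envelopes(stft(v, spec_default), fb)$values
  smooth <- function(r) as.numeric(stats::filter(r, rep(1 / 25, 25), sides = 2))
  for (b in 1:10) {
    a <- smooth(e_in[b, ]); bb <- smooth(e_out[b, ])
    ok <- !is.na(a) & !is.na(bb)
    expect_gt(cor(a[ok], bb[ok]), 0.9)
  }
})

test_that("WAV files round-trip through the vocoder I/O", {
  set.seed(6)
  x <- rnorm(3000) * 0.2
  f <- tempfile(fileext = ".wav")
  write_wav(x, f, sample_rate = 16000)
  w <- read_wav(f)
  expect_equal(w$sample_rate, 16000)
  expect_lt(max(abs(w$samples - x)), 1 / 32768)
  out <- tempfile(fileext = ".wav")
  vocode_wav(f, out, vocoder_spec(noise_seed = 2))
  v <- read_wav(out)
  expect_equal(length(v$samples), length(x))
})
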