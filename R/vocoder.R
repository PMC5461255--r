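#' Specification of the channel (noise) vocoder
#'
#' A cochlear-implant-simulation vocoder: a short-time Fourier transform
#' splits the signal into frames, FFT bins are grouped into
#' logarithmically spaced analysis bands, the root-total-energy envelope
#' of each band modulates a band-limited noise carrier whose power falls
#' off at \code{spread_slope} dB per octave beyond the band edges
#' (simulating spread of excitation), and the modulated carriers are
#' summed.
#'
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param fft_size FFT length in samples (default 128).
#' @param overlap Fractional frame overlap in (0, 1) (default 0.75, i.e.
#'   a 32-sample hop at the defaults).
#' @param n_bands Number of analysis bands (default 10).
#' @param spread_slope Carrier decay outside its band, dB/octave
#'   (default 3.5).
#' @param low_edge Lowest band edge in Hz.  Default 350: the smallest
#'   round value for which every one of the ten default log-spaced bands
#'   contains at least one FFT bin at the default 125 Hz bin spacing.
#' @param high_edge Highest band edge (default Nyquist).
#' @param band_edges Optional explicit vector of \code{n_bands + 1}
#'   strictly increasing, log-spaced edges; overrides
#'   \code{low_edge}/\code{high_edge}.
#' @param noise_seed Integer seed of the carrier noise stream; the whole
#'   transform is deterministic given the seed.
#' @return Object of class \code{"vocoder_spec"}.
#' @export
#' @examples
#' spec <- vocoder_spec()
#' spec
vocoder_spec <- function(sample_rate = 16000, fft_size = 128, overlap = 0.75,
                         n_bands = 10, spread_slope = 3.5, low_edge = 350,
                         high_edge = sample_rate / 2, band_edges = NULL,
                         noise_seed = 1L) {
  if (overlap <= 0 || overlap >= 1) .stopf("overlap must be in (0, 1)")
  if (n_bands < 1) .stopf("n_bands must be at least 1")
  hop <- fft_size * (1 - overlap)
  if (abs(hop - round(hop)) > 1e-9) {
    .stopf("fft_size * (1 - overlap) must be an integer number of samples")
  }
  if (is.null(band_edges)) {
    if (low_edge <= 0 || high_edge <= low_edge) {
      .stopf("band edges require 0 < low_edge < high_edge")
    }
    band_edges <- low_edge * (high_edge / low_edge)^((0:n_bands) / n_bands)
  } else {
    if (length(band_edges) != n_bands + 1) {
      .stopf("band_edges must have n_bands + 1 elements")
    }
    if (any(diff(band_edges) <= 0)) .stopf("band_edges must be strictly increasing")
    ratios <- band_edges[-1] / band_edges[-length(band_edges)]
    if (diff(range(ratios)) > 1e-9 * mean(ratios)) {
      .stopf("band_edges must be logarithmically spaced (constant ratio)")
    }
  }
  structure(list(sample_rate = sample_rate, fft_size = as.integer(fft_size),
                 overlap = overlap, hop = as.integer(round(hop)),
                 n_bands = as.integer(n_bands), spread_slope = spread_slope,
                 band_edges = band_edges, noise_seed = as.integer(noise_seed)),
            class = "vocoder_spec")
}

#' @export
print.vocoder_spec <- function(x, ...) {
  cat(sprintf("Noise vocoder: %d bands %.0f-%.0f Hz, %d-pt FFT at %.0f%% overlap (hop %d), slope %.1f dB/oct, fs %d Hz, seed %d\n",
              x$n_bands, x$band_edges[1], x$band_edges[length(x$band_edges)],
              x$fft_size, 100 * x$overlap, x$hop, x$spread_slope,
              x$sample_rate, x$noise_seed))
  invisible(x)
}

#' Assign FFT bins to analysis bands
#'
#' Every one-sided FFT bin whose center frequency lies between the lowest
#' band edge and the Nyquist frequency is assigned to exactly one band
#' (the interval \code{[edge_k, edge_{k+1})}, the top band closed).  Bins
#' below the lowest edge (including DC) stay unassigned.
#'
#' @param spec A [vocoder_spec()].
#' @return Object of class \code{"vocoder_filterbank"}: \code{assignment}
#'   (integer per bin, 0 = unassigned), \code{bin_freq}, \code{edges} and
#'   \code{centers} (geometric mean of each band's edges).
#' @export
design_filterbank <- function(spec) {
  n_bins <- spec$fft_size %/% 2 + 1
  if (spec$fft_size / 2 < spec$n_bands) {
    .stopf("fft_size/2 = %d gives too few bins for %d bands",
           spec$fft_size %/% 2, spec$n_bands)
  }
  freq <- (seq_len(n_bins) - 1) * spec$sample_rate / spec$fft_size
  edges <- spec$band_edges
  assignment <- integer(n_bins)
  for (b in seq_len(spec$n_bands)) {
    hi_open <- b < spec$n_bands
    inside <- freq >= edges[b] & (if (hi_open) freq < edges[b + 1]
                                  else freq <= edges[b + 1])
    assignment[inside] <- b
  }
  counts <- tabulate(assignment, nbins = spec$n_bands)
  if (any(counts == 0)) {
    .stopf("band(s) %s contain no FFT bin; increase fft_size or raise low_edge",
           paste(which(counts == 0), collapse = ", "))
  }
  structure(list(assignment = assignment, bin_freq = freq, edges = edges,
                 centers = sqrt(edges[-length(edges)] * edges[-1]),
                 n_bands = spec$n_bands),
            class = "vocoder_filterbank")
}

# periodic Hann window; satisfies constant overlap-add at 75% overlap
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Short-time Fourier transform
#'
#' Frames the signal with a periodic Hann window advancing by
#' \code{fft_size * (1 - overlap)} samples.  The signal is zero-padded at
#' the end so that the last frame is complete; the frame count is
#' \code{max(1, ceiling((length - fft_size) / hop) + 1)}.
#'
#' @param signal Mono numeric signal at the spec's sample rate (use
#'   [read_wav()] and resample externally if needed).
#' @param spec A [vocoder_spec()].
#' @return Object of class \code{"stft_frames"}: one-sided complex
#'   \code{spectrum} ((fft_size/2 + 1) x n_frames), \code{hop},
#'   \code{fft_size}, \code{signal_length}, \code{sample_rate}.
#' @export
stft <- function(signal, spec) {
  N <- spec$fft_size
  hop <- spec$hop
  len <- length(signal)
  n_frames <- max(1L, as.integer(ceiling((len - N) / hop)) + 1L)
  padded <- c(signal, numeric((n_frames - 1) * hop + N - len))
  idx <- outer(seq_len(N), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(padded[idx], N, n_frames) * .hann(N)
  spec_full <- mvfft(frames)
  structure(list(spectrum = spec_full[seq_len(N %/% 2 + 1), , drop = FALSE],
                 hop = hop, fft_size = N, n_frames = n_frames,
                 signal_length = len, sample_rate = spec$sample_rate),
            class = "stft_frames")
}

#' Band envelopes from a short-time spectrum
#'
#' The envelope of band b in frame t is the square root of the total
#' energy of the band's bins: \code{sqrt(sum |X(k, t)|^2)}.
#'
#' @param spectrum An [stft()] result.
#' @param filterbank A [design_filterbank()] result with matching bin
#'   count.
#' @return Object of class \code{"envelope_matrix"}: nonnegative
#'   \code{values} (n_bands x n_frames), \code{frame_hop},
#'   \code{band_centers}, \code{signal_length}, \code{sample_rate}.
#' @export
band_envelopes <- function(spectrum, filterbank) {
  S <- spectrum$spectrum
  if (nrow(S) != length(filterbank$assignment)) {
    .stopf("filterbank has %d bins but spectrum has %d",
           length(filterbank$assignment), nrow(S))
  }
  power <- Mod(S)^2
  keep <- filterbank$assignment > 0
  env <- rowsum(power[keep, , drop = FALSE], filterbank$assignment[keep])
  env <- sqrt(matrix(env, filterbank$n_bands, ncol(S)))
  structure(list(values = env, frame_hop = spectrum$hop,
                 fft_size = spectrum$fft_size,
                 band_centers = filterbank$centers,
                 band_edges = filterbank$edges,
                 signal_length = spectrum$signal_length,
                 sample_rate = spectrum$sample_rate),
            class = "envelope_matrix")
}

# amplitude gain of band b at frequencies f: unity inside the band,
# spread_slope dB/octave power decay outside (power, hence /20 on the
# dB -> amplitude conversion with gain^2 carrying the slope)
.band_gain <- function(f, lo, hi, slope_db_oct) {
  g <- numeric(length(f))
  pos <- f > 0
  g[pos & f >= lo & f <= hi] <- 1
  below <- pos & f < lo
  g[below] <- 10^(-slope_db_oct * log2(lo / f[below]) / 20)
  above <- f > hi
  g[above] <- 10^(-slope_db_oct * log2(f[above] / hi) / 20)
  g
}

# seeded white Gaussian noise spectrally shaped in the FFT domain,
# normalized to unit RMS
.shaped_noise <- function(n, lo, hi, slope, sample_rate) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)        # fold to two-sided symmetric gains
  X <- X * .band_gain(f, lo, hi, slope)
  out <- Re(fft(X, inverse = TRUE)) / n
  r <- .rms(out)
  if (r > 0) out / r else out
}

#' Synthesize a vocoded signal from band envelopes
#'
#' Each band's unit-RMS noise carrier — spectrally flat inside the band
#' and decaying at \code{spread_slope} dB/octave outside it — is
#' amplitude-modulated by the band envelope (linearly interpolated from
#' frame centers to sample rate) and the bands are summed.  Carriers are
#' drawn band after band from a single RNG stream seeded with
#' \code{noise_seed}, so the output is deterministic.
#'
#' @param envelopes A [band_envelopes()] result.
#' @param spec The [vocoder_spec()] used for analysis.
#' @return Numeric signal of length \code{envelopes$signal_length}.
#' @export
synthesize <- function(envelopes, spec) {
  env <- envelopes$values
  if (nrow(env) != spec$n_bands) {
    .stopf("envelope matrix has %d bands but spec declares %d",
           nrow(env), spec$n_bands)
  }
  L <- envelopes$signal_length
  n_frames <- ncol(env)
  centers <- (seq_len(n_frames) - 1) * envelopes$frame_hop +
    (envelopes$fft_size + 1) / 2
  edges <- spec$band_edges
  .with_seed(spec$noise_seed, {
    out <- numeric(L)
    for (b in seq_len(spec$n_bands)) {
      carrier <- .shaped_noise(L, edges[b], edges[b + 1], spec$spread_slope,
                               spec$sample_rate)
      e <- if (n_frames > 1) {
        approx(centers, env[b, ], xout = seq_len(L), rule = 2)$y
      } else {
        rep(env[b, 1], L)
      }
      out <- out + carrier * e
    }
    out
  })
}

#' Noise-vocode a signal
#'
#' Full chain: [stft()] analysis, [design_filterbank()] band grouping,
#' [band_envelopes()] extraction, [synthesize()] with seeded noise
#' carriers; the output is trimmed to the input length and renormalized
#' to the input RMS (silence stays silence).  Deterministic given the
#' spec's \code{noise_seed}.
#'
#' @param signal Mono numeric signal at \code{spec$sample_rate}.
#' @param spec A [vocoder_spec()].
#' @param sample_rate Optional sample rate of \code{signal}; if supplied
#'   and different from the spec an error asks for resampling.
#' @return Vocoded signal, same length as the input.
#' @export
#' @examples
#' spec <- vocoder_spec(noise_seed = 7)
#' t <- seq(0, 0.25, by = 1 / spec$sample_rate)
#' x <- sin(2 * pi * 500 * t) * (1 + sin(2 * pi * 4 * t)) / 2
#' v <- vocode(x, spec)
vocode <- function(signal, spec, sample_rate = NULL) {
  if (!is.null(sample_rate) && sample_rate != spec$sample_rate) {
    .stopf("signal is sampled at %g Hz but the spec expects %g Hz; resample first",
           sample_rate, spec$sample_rate)
  }
  if (length(signal) == 0) return(numeric(0))
  fb <- design_filterbank(spec)
  env <- band_envelopes(stft(signal, spec), fb)
  out <- synthesize(env, spec)[seq_along(signal)]
  r_in <- .rms(signal)
  r_out <- .rms(out)
  if (r_in == 0 || r_out == 0) return(numeric(length(signal)))
  out * r_in / r_out
}

#' Vocode a WAV file
#'
#' @param infile,outfile Paths to mono PCM WAV files.
#' @param spec A [vocoder_spec()]; its sample rate must match the file.
#' @return The output path, invisibly.
#' @export
vocode_wav <- function(infile, outfile, spec = vocoder_spec()) {
  w <- read_wav(infile)
  out <- vocode(w$samples, spec, sample_rate = w$sample_rate)
  write_wav(out, outfile, sample_rate = w$sample_rate)
  invisible(outfile)
}
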