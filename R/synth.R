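#' Generate a multi-talker panel
#'
#' Draws `n` talkers, half with fundamental frequencies in a higher band
#' (170--250 Hz) and half in a lower band (90--140 Hz), with distinct
#' vocal-tract (formant) scale factors and speaking-rate factors.
#'
#' @param n Number of talkers (must be even).
#' @param seed Integer seed.
#' @return A data frame with columns `talker`, `group` (`"high"`/`"low"`),
#'   `f0`, `formant_scale`, `rate`, `noise_seed`.
#' @export
generate_talkers <- function(n = 10, seed = 1) {
  if (n %% 2 != 0) stop("n talkers must be even (equal high/low f0 groups)")
  with_seed(seed, {
    nh <- n / 2
    f0 <- c(runif(nh, 170, 250), runif(nh, 90, 140))
    fs <- c(runif(nh, 1.04, 1.18), runif(nh, 0.88, 1.00))
    # enforce distinct formant scales
    fs <- fs + seq_len(n) * 1e-4
    data.frame(talker = sprintf("t%02d", seq_len(n)),
               group = rep(c("high", "low"), each = nh),
               f0 = f0, formant_scale = fs,
               rate = runif(n, 0.92, 1.08),
               noise_seed = sample.int(1e6, n),
               stringsAsFactors = FALSE)
  })
}

# second-order resonator cascade (formant filter)
.resonate <- function(x, freqs, sr, bw = NULL) {
  if (is.null(bw)) bw <- 60 + 0.05 * freqs
  for (i in seq_along(freqs)) {
    r <- exp(-pi * bw[i] / sr)
    th <- 2 * pi * freqs[i] / sr
    g <- 1 - 2 * r * cos(th) + r^2
    x <- stats::filter(g * x, c(2 * r * cos(th), -r^2), method = "recursive")
  }
  as.numeric(x)
}

# band-shaped noise via FFT brick with raised-cosine 200 Hz skirts
.band_noise <- function(nsmp, lo, hi, sr) {
  x <- rnorm(nsmp)
  X <- fft(x)
  f <- (seq_len(nsmp) - 1) / nsmp * sr
  f <- pmin(f, sr - f)                      # two-sided
  w <- numeric(nsmp)
  ramp <- 200
  w[f >= lo & f <= hi] <- 1
  lo_r <- f >= lo - ramp & f < lo
  hi_r <- f > hi & f <= hi + ramp
  w[lo_r] <- 0.5 * (1 + cos(pi * (lo - f[lo_r]) / ramp))
  w[hi_r] <- 0.5 * (1 + cos(pi * (f[hi_r] - hi) / ramp))
  Re(fft(X * w, inverse = TRUE)) / nsmp
}

.voiced_source <- function(nsmp, f0, sr) {
  # sawtooth phase accumulator (approximate glottal source, -6 dB/oct)
  phase <- cumsum(rep(f0, length.out = nsmp) / sr)
  2 * (phase %% 1) - 1
}

.synth_segment <- function(rec, dur_s, talker, sr, f0) {
  nsmp <- max(8L, round(dur_s * sr))
  fsc <- talker$formant_scale
  cls <- rec$class
  if (cls %in% c("vowel", "glide", "liquid")) {
    src <- .voiced_source(nsmp, f0, sr)
    if (isTRUE(rec$diphthong) && !is.na(rec$f1e)) {
      # two-target diphthong: synthesize halves, crossfade 20 ms
      n1 <- round(nsmp * 0.55); n2 <- nsmp - n1
      a <- .resonate(src[seq_len(n1 + min(n2, round(0.02 * sr)))],
                     c(rec$f1, rec$f2, rec$f3) * fsc, sr)
      f3e <- if (is.na(rec$f3e)) rec$f3 else rec$f3e
      b <- .resonate(src[(n1 + 1):nsmp],
                     c(rec$f1e, rec$f2e, f3e) * fsc, sr)
      y <- numeric(nsmp)
      y[seq_len(n1)] <- a[seq_len(n1)]
      ov <- min(n2, round(0.02 * sr))
      w <- seq(0, 1, length.out = ov)
      y[n1 + seq_len(ov)] <- (1 - w) * a[n1 + seq_len(ov)] + w * b[seq_len(ov)]
      if (n2 > ov) y[(n1 + ov + 1):nsmp] <- b[(ov + 1):n2]
    } else {
      y <- .resonate(src, c(rec$f1, rec$f2, rec$f3) * fsc, sr)
    }
    y <- y / max(abs(y), 1e-9) * rec$amp
  } else if (cls == "nasal") {
    src <- .voiced_source(nsmp, f0, sr)
    y <- .resonate(src, c(rec$f1, rec$f2 * fsc), sr, bw = c(100, 300))
    y <- y / max(abs(y), 1e-9) * rec$amp
  } else if (cls == "fricative") {
    y <- .band_noise(nsmp, rec$noise_lo, rec$noise_hi, sr)
    y <- y / max(abs(y), 1e-9) * rec$amp
    if (isTRUE(rec$voiced)) {
      v <- .resonate(.voiced_source(nsmp, f0, sr), 500 * fsc, sr, bw = 200)
      y <- 0.55 * y + 0.45 * v / max(abs(v), 1e-9) * rec$amp
    }
  } else if (cls == "affricate") {
    ncl <- round(nsmp * 0.4)
    fr <- .band_noise(nsmp - ncl, rec$noise_lo, rec$noise_hi, sr)
    fr <- fr / max(abs(fr), 1e-9) * rec$amp
    y <- c(numeric(ncl), fr)
    if (isTRUE(rec$voiced)) {
      v <- .voiced_source(nsmp, f0, sr) * 0.12
      y <- y + v
    }
  } else {                                   # stops
    ncl <- round(nsmp * 0.55)
    nb <- max(4L, round(0.015 * sr))          # 15 ms burst
    nb <- min(nb, nsmp - ncl)
    burst <- .band_noise(nb, max(50, rec$burst_cf - 600),
                         rec$burst_cf + 600, sr)
    burst <- burst / max(abs(burst), 1e-9) * rec$amp
    tailn <- nsmp - ncl - nb
    tail_part <- if (tailn > 0) {
      if (isTRUE(rec$voiced)) numeric(tailn)
      else 0.2 * .band_noise(tailn, 500, 4000, sr)   # aspiration
    } else numeric(0)
    y <- c(numeric(ncl), burst, tail_part)
    if (isTRUE(rec$voiced)) {                 # voice bar during closure
      vb <- .resonate(.voiced_source(ncl, f0, sr), 150, sr, bw = 100)
      y[seq_len(ncl)] <- 0.15 * vb / max(abs(vb), 1e-9)
    }
  }
  y[!is.finite(y)] <- 0
  y
}

#' Synthesize one spoken token of a word
#'
#' Concatenative source-filter synthesis: sonorants are a sawtooth source at
#' the talker's fundamental frequency shaped by talker-scaled formant
#' resonators; fricatives are band-shaped noise; stops are closure silence
#' plus a burst (voiced stops carry a voice bar); affricates are closure
#' plus frication. Segments are joined with a 10 ms linear crossfade.
#' Segment durations scale sublinearly with word length so that utterances
#' fall in the configured duration range, with per-token jitter. The same
#' `(word, talker, seed)` always yields the identical waveform.
#'
#' @param word A lexicon row (or a list with elements `id` and `phonemes`).
#' @param talker A one-row talker data frame from [generate_talkers()].
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed for duration jitter and noise.
#' @param dur_range Permissible utterance duration range in ms.
#' @param inventory Phoneme inventory.
#' @return A list of class `"token_audio"` with elements `word`, `talker`,
#'   `wave` (mono samples in \[-1, 1\]), `sample_rate`, `duration_ms`, and
#'   `onsets_ms` (named vector of phoneme onset times).
#' @export
synthesize_token <- function(word, talker, sample_rate = 22050, seed = 1,
                             dur_range = c(300, 1200),
                             inventory = phoneme_inventory()) {
  ph <- if (is.character(word)) word else strsplit(word$phonemes, " ")[[1]]
  wid <- if (is.character(word)) paste(word, collapse = "") else word$id
  if (!length(ph)) stop("empty phoneme sequence")
  bad <- setdiff(ph, inventory$phoneme)
  if (length(bad)) stop("unknown phoneme symbol: ", bad[1])
  tseed <- (abs(sum(utf8ToInt(paste0(wid, talker$talker)))) * 7919 +
            talker$noise_seed + seed * 131) %% .Machine$integer.max
  with_seed(tseed, {
    L <- length(ph)
    target <- 222 * L^0.694 * talker$rate * runif(1, 0.95, 1.05)
    target <- min(max(target, dur_range[1] + 5), dur_range[2] - 10)
    w <- inventory[ph, "durw"]
    durs <- target / 1000 * w / sum(w)
    f0s <- talker$f0 * seq(1.02, 0.88, length.out = L)   # declination
    segs <- lapply(seq_len(L), function(i)
      .synth_segment(inventory[ph[i], ], durs[i], talker, sample_rate,
                     f0s[i]))
    # overlap-add with 10 ms linear crossfade
    ov <- round(0.010 * sample_rate)
    lens <- lengths(segs)
    starts <- cumsum(c(1, head(pmax(lens - ov, 1), -1)))
    total <- starts[L] + lens[L] - 1
    wave <- numeric(total)
    for (i in seq_len(L)) {
      s <- segs[[i]]
      if (i > 1 && ov > 0 && length(s) > ov)
        s[seq_len(ov)] <- s[seq_len(ov)] * seq(0, 1, length.out = ov)
      if (i < L && ov > 0 && length(s) > ov)
        s[(length(s) - ov + 1):length(s)] <-
          s[(length(s) - ov + 1):length(s)] * seq(1, 0, length.out = ov)
      idx <- starts[i] + seq_along(s) - 1
      wave[idx] <- wave[idx] + s
    }
    wave <- wave / max(abs(wave), 1e-9) * 0.9
    structure(list(word = wid, talker = talker$talker, wave = wave,
                   sample_rate = sample_rate,
                   duration_ms = 1000 * length(wave) / sample_rate,
                   onsets_ms = setNames(1000 * (starts - 1) / sample_rate, ph)),
              class = "token_audio")
  })
}

#' Minimal RIFF WAV writer/reader (mono, 16-bit PCM)
#'
#' @param wave Numeric samples in \[-1, 1\], or a `token_audio` object.
#' @param path File path.
#' @param sample_rate Sampling rate in Hz (ignored when `wave` is a
#'   `token_audio`).
#' @return `read_wav()` returns a list with `wave` and `sample_rate`.
#' @export
write_wav <- function(wave, path, sample_rate = 22050) {
  if (inherits(wave, "token_audio")) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  s <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(s)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(s)), con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  readChar(con, 8)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  readBin(con, "integer", 2, 2, endian = "little")
  sr <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 2, 2, endian = "little")
  readChar(con, 4)
  nb <- readBin(con, "integer", 1, 4, endian = "little")
  s <- readBin(con, "integer", nb / 2, 2, endian = "little")
  list(wave = s / 32767, sample_rate = sr)
}
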