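#' Trim surrounding silence from a waveform
#'
#' Removes leading and trailing samples whose short-window RMS falls below
#' the peak RMS by more than `cutoff_db`. The RMS window treats samples
#' outside the signal as zeros, so prepending exact silence shifts the trim
#' point by exactly the prepended length. Interior samples are never
#' removed.
#'
#' @param wave Numeric samples (or a `token_audio`).
#' @param cutoff_db Cutoff in dB relative to the peak short-window RMS
#'   (default -20).
#' @param sample_rate Sampling rate in Hz.
#' @param window_ms RMS window length in ms (default 25).
#' @return The trimmed numeric waveform.
#' @export
trim_silence <- function(wave, cutoff_db = -20, sample_rate = 22050,
                         window_ms = 25) {
  if (inherits(wave, "token_audio")) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  if (!length(wave)) stop("empty waveform")
  n <- length(wave)
  win <- max(1L, round(window_ms / 1000 * sample_rate))
  h <- win %/% 2L
  cs <- cumsum(c(0, wave^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + (win - h - 1L), n)
  rms <- sqrt((cs[hi + 1L] - cs[lo]) / win)      # zero-padded window
  thr <- max(rms) * 10^(cutoff_db / 20)
  keep <- which(rms >= thr & rms > 0)
  if (!length(keep) || max(rms) == 0) stop("all-silent input")
  wave[keep[1]:keep[length(keep)]]
}

erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' Build an ERB-spaced half-cosine cochlear filterbank
#'
#' Bandpass filters have half-cosine magnitude responses on an ERB-number
#' scale, with centers equally spaced between `f_min` and `f_max` and a
#' bandwidth spanning `n_low` spacings to each side, so the interior
#' summed squared response is constant. Low-pass and high-pass filters
#' carry the residual response at the band edges, making the summed squared
#' response exactly flat over the whole axis. At the defaults this yields
#' 203 + 4 + 4 = 211 filters.
#'
#' @param sample_rate Sampling rate in Hz of the signals to be filtered.
#' @param n_bandpass Number of bandpass filters.
#' @param f_min,f_max Center-frequency range in Hz (`f_max` must be below
#'   the Nyquist frequency).
#' @param n_low,n_high Number of low-/high-pass edge filters (must be
#'   equal; they double as the overlap factor of the bandpass filters).
#' @return An object of class `"filterbank"`.
#' @export
build_filterbank <- function(sample_rate = 20000, n_bandpass = 203,
                             f_min = 50, f_max = 8000,
                             n_low = 4, n_high = 4) {
  if (f_max >= sample_rate / 2)
    stop("f_max must be below the Nyquist frequency")
  if (n_low != n_high)
    stop("flat tiling requires n_low == n_high")
  e_lo <- erb_number(f_min)
  e_hi <- erb_number(f_max)
  step <- (e_hi - e_lo) / (n_bandpass + 1)
  centers_erb <- e_lo + step * seq_len(n_bandpass)
  structure(list(sample_rate = sample_rate, n_bandpass = n_bandpass,
                 f_min = f_min, f_max = f_max, n_low = n_low,
                 n_high = n_high, step = step, centers_erb = centers_erb,
                 centers_hz = (10^(centers_erb / 21.4) - 1) / 0.00437,
                 n_filters = n_bandpass + n_low + n_high,
                 cache = new.env(parent = emptyenv())),
            class = "filterbank")
}

#' @export
print.filterbank <- function(x, ...) {
  cat("ERB half-cosine filterbank:", x$n_bandpass, "bandpass +", x$n_low,
      "low-pass +", x$n_high, "high-pass =", x$n_filters, "filters,",
      x$f_min, "-", x$f_max, "Hz @", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Evaluate filterbank magnitude responses
#'
#' @param fb A `filterbank`.
#' @param freqs Frequencies in Hz.
#' @return A `length(freqs)` x `n_filters` matrix of magnitude responses.
#'   Columns are ordered low-pass, bandpass, high-pass. The summed squared
#'   response over each row is 1.
#' @export
filterbank_response <- function(fb, freqs) {
  e <- erb_number(pmax(freqs, 0))
  k <- fb$n_low
  half <- k * fb$step
  bp <- matrix(0, length(freqs), fb$n_bandpass)
  for (i in seq_len(fb$n_bandpass)) {
    d <- e - fb$centers_erb[i]
    inside <- abs(d) <= half
    bp[inside, i] <- cos(pi * d[inside] / (2 * half))
  }
  s <- rowSums(bp^2)
  deficit <- pmax(k - s, 0)
  e_mid <- (erb_number(fb$f_min) + erb_number(fb$f_max)) / 2
  lp <- sqrt(deficit * (e <= e_mid) / fb$n_low)
  hp <- sqrt(deficit * (e > e_mid) / fb$n_high)
  out <- cbind(matrix(lp, length(freqs), fb$n_low),
               bp, matrix(hp, length(freqs), fb$n_high)) / sqrt(k)
  colnames(out) <- c(sprintf("lp%02d", seq_len(fb$n_low)),
                     sprintf("bp%03d", seq_len(fb$n_bandpass)),
                     sprintf("hp%02d", seq_len(fb$n_high)))
  out
}

#' Compute a cochleagram
#'
#' Each filter is applied zero-phase in the frequency domain; the envelope
#' is the magnitude of the analytic signal of the filtered waveform,
#' power-law compressed and averaged into frames at `envelope_rate`. The
#' frame count is `ceil(duration * envelope_rate)`.
#'
#' @param wave Numeric samples (or a `token_audio`).
#' @param fb A `filterbank` (its `sample_rate` must match the waveform's).
#' @param envelope_rate Envelope frame rate in Hz.
#' @param compression Power-law compression exponent (1 = none).
#' @param sample_rate Sampling rate of `wave` in Hz.
#' @return An object of class `"cochleagram"`: a list with `mat` (frames x
#'   filters), `envelope_rate`, `n_valid` (= `nrow(mat)` before padding).
#' @export
compute_cochleagram <- function(wave, fb, envelope_rate = 200,
                                compression = 0.3,
                                sample_rate = fb$sample_rate) {
  if (inherits(wave, "token_audio")) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  if (!length(wave)) stop("empty waveform")
  if (envelope_rate > sample_rate)
    stop("envelope_rate must not exceed the sample rate")
  if (sample_rate != fb$sample_rate)
    stop("filterbank sample rate does not match the waveform")
  n <- length(wave)
  # zero-pad to a power of two; each filter's envelope is recovered from
  # the positive-frequency bins in its support alone (spectral excision),
  # inverse-transformed at a small decimated length M. Because the
  # analytic subband signal is band-limited to that support, its
  # magnitude at the M decimated time points is exact.
  nfft <- 2^ceiling(log2(max(n, 64)))
  X <- fft(c(wave, numeric(nfft - n)))
  key <- paste0("n", nfft)
  if (is.null(fb$cache[[key]])) {
    pos <- seq_len(nfft / 2 + 1)
    f <- (pos - 1) / nfft * sample_rate
    H <- filterbank_response(fb, f)
    sup <- lapply(seq_len(ncol(H)), function(j) range(which(H[, j] > 0)))
    fb$cache[[key]] <- list(H = H, sup = sup)
  }
  ca <- fb$cache[[key]]
  n_frames <- as.integer(floor((n - 1) * envelope_rate / sample_rate) + 1)
  out <- matrix(0, n_frames, fb$n_filters,
                dimnames = list(NULL, colnames(ca$H)))
  min_M <- 2^ceiling(log2(max(64, 4 * nfft * envelope_rate / sample_rate)))
  t_max <- n / sample_rate
  for (j in seq_len(fb$n_filters)) {
    k0 <- ca$sup[[j]][1]
    k1 <- ca$sup[[j]][2]
    A <- X[k0:k1] * ca$H[k0:k1, j]
    w2 <- rep(2, length(A))                    # analytic: double positives
    if (k0 == 1) w2[1] <- 1
    if (k1 == nfft / 2 + 1) w2[length(A)] <- 1
    A <- A * w2
    M <- max(min_M, 2^ceiling(log2(length(A))))
    a <- fft(c(A, complex(real = numeric(M - length(A)))), inverse = TRUE)
    tm <- (seq_len(M) - 1) * nfft / (M * sample_rate)
    keep <- tm < t_max
    env <- (Mod(a[keep]) / nfft)^compression
    fr <- floor(tm[keep] * envelope_rate) + 1
    cnt <- tabulate(fr, n_frames)
    v <- numeric(n_frames)
    rs <- rowsum(env, fr)
    idx <- as.integer(rownames(rs))
    v[idx] <- rs[, 1] / cnt[idx]
    if (any(cnt == 0))                          # tiny final frame: carry over
      for (fz in which(cnt == 0)) v[fz] <- v[max(1, fz - 1)]
    out[, j] <- v
  }
  structure(list(mat = out, envelope_rate = envelope_rate,
                 n_valid = n_frames, compression = compression,
                 sample_rate = sample_rate),
            class = "cochleagram")
}

#' Pad cochleagrams into an equal-length batch
#'
#' @param cochleagrams A list of `cochleagram` objects (or plain frame x
#'   filter matrices).
#' @param max_frames Common time dimension (default: longest item).
#' @return A list of class `"coch_batch"`: `x`, an array of dimension
#'   `(n_tokens, max_frames, n_filters)` zero-padded at the end of time;
#'   `n_valid`, integer vector of unpadded frame counts; `mask`, a logical
#'   `n_tokens` x `max_frames` validity matrix.
#' @export
pad_batch <- function(cochleagrams, max_frames = NULL) {
  mats <- lapply(cochleagrams, function(cg)
    if (inherits(cg, "cochleagram")) cg$mat else cg)
  nv <- vapply(mats, nrow, 1L)
  if (is.null(max_frames)) max_frames <- max(nv)
  over <- which(nv > max_frames)
  if (length(over))
    stop("token ", over[1], " has ", nv[over[1]],
         " frames, more than max_frames = ", max_frames)
  nf <- ncol(mats[[1]])
  x <- array(0, c(length(mats), max_frames, nf))
  for (i in seq_along(mats)) x[i, seq_len(nv[i]), ] <- mats[[i]]
  mask <- outer(nv, seq_len(max_frames), function(a, b) b <= a)
  structure(list(x = x, n_valid = nv, mask = mask), class = "coch_batch")
}

#' @rdname pad_batch
#' @param batch A `coch_batch`.
#' @return `unpad_batch()` returns the list of original matrices.
#' @export
unpad_batch <- function(batch) {
  lapply(seq_along(batch$n_valid), function(i) {
    m <- batch$x[i, seq_len(batch$n_valid[i]), , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    m
  })
}
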