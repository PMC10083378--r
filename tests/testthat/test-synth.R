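test_that("talker panels split into high and low f0 bands deterministically", {
  tk <- generate_talkers(10, seed = 1)
  expect_equal(nrow(tk), 10L)
  expect_equal(sum(tk$group == "high"), 5L)
  expect_equal(sum(tk$group == "low"), 5L)
  expect_true(all(tk$f0[tk$group == "high"] > max(tk$f0[tk$group == "low"])))
  expect_false(anyDuplicated(tk$formant_scale) > 0)
  expect_identical(generate_talkers(2, seed = 9), generate_talkers(2, seed = 9))
  expect_error(generate_talkers(3), "even")
})

test_that("token synthesis is deterministic and respects amplitude/duration bounds", {
  tk <- fix_talkers()
  lex <- fix_mini_lexicon()
  t1 <- synthesize_token(lex[3, ], tk[1, ], 20000, seed = 5)
  t2 <- synthesize_token(lex[3, ], tk[1, ], 20000, seed = 5)
  expect_identical(t1$wave, t2$wave)
  expect_lte(max(abs(t1$wave)), 1)
  for (i in c(1, 10, 20)) for (ti in c(1, 3)) {
    tok <- synthesize_token(lex[i, ], tk[ti, ], 20000, seed = 2)
    expect_gte(tok$duration_ms, 300)
    expect_lte(tok$duration_ms, 1200)
    expect_equal(length(tok$onsets_ms),
                 length(strsplit(lex$phonemes[i], " ")[[1]]))
    expect_true(all(diff(tok$onsets_ms) > 0))
  }
})

test_that("synthesis rejects empty or unknown phoneme input", {
  tk <- fix_talkers()
  expect_error(synthesize_token(character(0), tk[1, ], 20000), "empty")
  expect_error(synthesize_token(c("K", "XX"), tk[1, ], 20000), "XX")
})

test_that("tokens of one word differ by the talkers' f0 but share spectral shape", {
  tk <- generate_talkers(4, seed = 3)
  word <- c("M", "AA", "M")                     # sonorant word: clear f0
  hi <- synthesize_token(word, tk[1, ], 20000, seed = 1)
  lo <- synthesize_token(word, tk[3, ], 20000, seed = 1)
  est_f0 <- function(tok) {
    w <- tok$wave[round(length(tok$wave) * 0.4):round(length(tok$wave) * 0.6)]
    a <- acf(w, lag.max = 400, plot = FALSE)$acf[-1]
    lo_lag <- 20000 / 300                       # search 50..300 Hz
    hi_lag <- 20000 / 50
    lag <- which.max(a[ceiling(lo_lag):floor(hi_lag)]) + ceiling(lo_lag) - 1
    20000 / lag
  }
  f0h <- est_f0(hi)
  f0l <- est_f0(lo)
  expect_gt(f0h, f0l + 20)                      # band gap survives synthesis
  centroid <- function(tok) {
    s <- Mod(fft(tok$wave))[1:8000]
    f <- (0:7999) / length(tok$wave) * 20000
    sum(f * s) / sum(s)
  }
  expect_lt(abs(centroid(hi) - centroid(lo)) /
              max(centroid(hi), centroid(lo)), 0.5)
})

test_that("different phonemes are farther apart spectrally than talker variants", {
  # phonetic separability on diphone-style stimuli
  tk <- generate_talkers(4, seed = 2)
  fb <- fix_filterbank()
  phs <- c("S", "AA", "M", "K")
  spec <- list()
  for (p in phs) for (ti in 1:4) {
    tok <- synthesize_token(c(p, "AH"), tk[ti, ], 20000, seed = 1)
    cg <- compute_cochleagram(tok$wave, fb, 100, 0.3)
    n_half <- max(1, floor(nrow(cg$mat) / 2))
    spec[[paste(p, ti)]] <- colMeans(cg$mat[seq_len(n_half), , drop = FALSE])
  }
  lab <- rep(phs, each = 4)
  d <- as.matrix(dist(do.call(rbind, spec)))
  same <- d[outer(lab, lab, "==") & upper.tri(d)]
  diff_ <- d[outer(lab, lab, "!=") & upper.tri(d)]
  expect_gt(mean(diff_), mean(same))
})

test_that("WAV files round-trip through the RIFF writer", {
  tk <- fix_talkers()
  tok <- synthesize_token(c("S", "IY"), tk[1, ], 20000, seed = 1)
  path <- tempfile(fileext = ".wav")
  write_wav(tok, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 20000)
  expect_equal(back$wave, tok$wave, tolerance = 1e-3)
  unlink(path)
})
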