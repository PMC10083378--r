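test_that("syllabification follows the maximal onset principle", {
  inv <- fix_inventory()
  # 'cable' with a syllabic /L/: two units, /b/ taken as the second onset
  syl <- syllabify(c("K", "EY", "B", "L"), inv,
                   vocalic = c(inv$phoneme[inv$class == "vowel"], "L"))
  expect_length(syl, 2)
  expect_equal(syl[[1]], c("K", "EY"))
  expect_equal(syl[[2]], c("B", "L"))
  # single vowel: one syllable, no onset or coda
  expect_equal(syllabify("AA", inv), list("AA"))
  # /s t r a k t s/: onset str, coda kts
  syl2 <- syllabify(c("S", "T", "R", "AA", "K", "T", "S"), inv)
  expect_length(syl2, 1)
  expect_equal(syl2[[1]], c("S", "T", "R", "AA", "K", "T", "S"))
  # intervocalic cluster splits at the longest legal onset
  syl3 <- syllabify(c("AE", "S", "T", "R", "OW"), inv)
  expect_equal(syl3[[1]], "AE")
  expect_equal(syl3[[2]], c("S", "T", "R", "OW"))
  expect_error(syllabify(c("S", "T"), inv), "no vowel")
})

test_that("exhaustive split check: chosen onset is the longest legal one", {
  inv <- fix_inventory()
  ons <- legal_onsets(inv)
  clusters <- list(c("K", "T", "R"), c("N", "S", "T"), c("B", "L"),
                   c("R", "K", "W"))
  for (cl in clusters) {
    syl <- syllabify(c("AA", cl, "IY"), inv)
    onset2 <- head(syl[[2]], -1)
    # the onset we chose is legal (or empty)...
    if (length(onset2))
      expect_true(paste(onset2, collapse = " ") %in% ons)
    # ...and no longer legal suffix of the cluster exists
    k <- length(onset2)
    if (k < length(cl)) {
      longer <- paste(cl[(length(cl) - k):length(cl)], collapse = " ")
      expect_false(longer %in% ons)
    }
  }
})

test_that("dorsal vectors have the slot-formula length for any s_max", {
  for (s in 1:6)
    expect_equal(dorsal_length(s), 29 * (3 + 5 * s))
  expect_equal(dorsal_length(5), 812L)
})

test_that("the single-syllable slot layout matches the k00a0bL0 pattern", {
  inv <- fix_inventory()
  ch <- fix_chart()
  # /k a b L/ treated as one syllable: onset k, nucleus a, coda b l
  v <- encode_dorsal(c("K", "AA", "B", "L"), ch, s_max = 1, inv)
  expect_length(v, 29 * 8)
  blocks <- matrix(v, ncol = 29, byrow = TRUE)
  filled <- rowSums(blocks) > 0
  expect_equal(filled, c(TRUE, FALSE, FALSE,      # C C C: k 0 0
                         TRUE, FALSE,             # V V:   a 0
                         TRUE, TRUE, FALSE))      # C C C: b L 0
  expect_equal(blocks[1, ], unname(ch["K", ]))
  expect_equal(blocks[4, ], unname(ch["AA", ]))
  expect_equal(blocks[6, ], unname(ch["B", ]))
  expect_equal(blocks[7, ], unname(ch["L", ]))
})

test_that("filled slot blocks count phonemes (plus diphthong double slots)", {
  inv <- fix_inventory()
  ch <- fix_chart()
  lex <- fix_mini_lexicon()
  for (i in seq_len(nrow(lex))) {
    ph <- strsplit(lex$phonemes[i], " ")[[1]]
    v <- encode_dorsal(lex[i, ], ch, 5, inv)
    blocks <- sum(rowSums(matrix(v, ncol = 29, byrow = TRUE)) > 0)
    n_diph <- sum(inv[ph, "diphthong"])
    expect_equal(blocks, length(ph) + n_diph)
  }
})

test_that("dorsal encoding is injective over the generated lexicon", {
  lex <- fix_mini_lexicon()
  m <- build_targets(lex, "dorsal", fix_chart(), s_max = 5,
                     inventory = fix_inventory())
  expect_equal(anyDuplicated(apply(m, 1, paste, collapse = "")), 0L)
})

test_that("slot overflow fails naming the word", {
  inv <- fix_inventory()
  ch <- fix_chart()
  expect_error(encode_dorsal(c("S", "T", "R", "AA", "K", "T", "S", "T"),
                             ch, 5, inv), "exceeds three")
  expect_error(encode_dorsal(c("K", "AA", "B", "IY", "T", "UW", "S", "EY",
                               "M", "OW", "L", "IH"), ch, 2, inv),
               "syllables")
})

test_that("template filtering reaches the documented fixed points", {
  counts <- rbind(w1 = c(2, 1, 0, 3, 0),
                  w2 = c(1, 0, 2, 1, 0),
                  w3 = c(0, 2, 1, 2, 0),
                  w4 = c(3, 1, 1, 0, 1))
  colnames(counts) <- paste0("t", 1:5)
  cooc <- structure(list(counts = counts), class = "cooc_table")
  # (1,1): identity
  ts <- build_template_set(cooc, 1, 1)
  expect_equal(ts$templates, colnames(counts))
  expect_equal(ts$words_kept, rownames(counts))
  # t5 admits only w4: thresholds (2,1) remove it, 4 templates remain
  ts2 <- build_template_set(cooc, 2, 1)
  expect_equal(ts2$templates, paste0("t", 1:4))
  expect_equal(ts2$words_kept, rownames(counts))
  # monotone: raising thresholds never adds templates
  for (mw in 1:4) for (mt in 1:3) {
    a <- tryCatch(build_template_set(cooc, mw, mt)$templates,
                  error = function(e) character(0))
    b <- tryCatch(build_template_set(cooc, mw + 1, mt)$templates,
                  error = function(e) character(0))
    expect_true(all(b %in% a))
  }
  expect_error(build_template_set(cooc, 5, 1), "eliminate")
})

test_that("surviving words are attested in at least the word threshold", {
  lex <- fix_mini_lexicon()
  cooc <- generate_cooccurrence(lex, n_templates = 60, base_count = 800,
                                seed = 2)
  ts <- build_template_set(cooc, 5, 3)
  att <- ts$admissible
  expect_true(all(rowSums(att) >= 3))
  expect_true(all(colSums(att) >= 5))
})

test_that("ventral vectors are attestation indicators", {
  counts <- rbind(w1 = c(5, 0, 1, 0, 0, 2), w2 = c(0, 3, 0, 1, 4, 0))
  colnames(counts) <- paste0("t", 1:6)
  cooc <- structure(list(counts = counts), class = "cooc_table")
  ts <- build_template_set(cooc, 1, 1)
  v1 <- encode_ventral("w1", ts)
  expect_equal(v1, c(1L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(sum(v1), 3L)
  v2 <- encode_ventral("w2", ts)
  expect_equal(cosine_sim(v1, v2), 0)           # disjoint template sets
  expect_error(encode_ventral("w9", ts), "filtered")
})

test_that("fused vectors concatenate dorsal then ventral", {
  inv <- fix_inventory()
  ch <- fix_chart()
  lex <- fix_mini_lexicon()
  cooc <- generate_cooccurrence(lex, n_templates = 60, base_count = 800,
                                seed = 2)
  ts <- build_template_set(cooc, 5, 3)
  w <- lex[lex$id %in% ts$words_kept, ][1, ]
  fz <- encode_fused(w, ch, ts, 5, inv)
  expect_length(fz, 812 + length(ts$templates))
  expect_equal(fz[1:812], encode_dorsal(w, ch, 5, inv))
  expect_equal(fz[-(1:812)], encode_ventral(w, ts))
})
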