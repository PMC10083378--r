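test_that("the weighted Levenshtein ratio reproduces the worked examples", {
  expect_equal(round(lev_ratio("acted", "active"), 2), 0.73)
  expect_equal(round(lev_ratio("killed", "killing"), 2), 0.62)
  expect_equal(lev_ratio("cat", "cat"), 1)
  expect_equal(lev_ratio("abc", "abc"), 1)
  expect_error(lev_ratio("", "abc"), "nonempty")
})

test_that("lev_ratio equals the weighted-cost DP oracle on short strings", {
  set.seed(13)
  alpha <- c("a", "b", "c")
  for (rep in 1:60) {
    a <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(lev_ratio(a, b), lev_oracle(a, b))
    expect_equal(lev_ratio(a, b), lev_ratio(b, a))     # symmetry
  }
})

test_that("phoneme mode counts each phoneme as one symbol", {
  expect_equal(lev_ratio("K AE T", "K AE P", mode = "phoneme"),
               (3 + 3 - 2) / 6)
  expect_equal(lev_ratio("K AE T", "K AE T", mode = "phoneme"), 1)
  expect_error(lev_ratio("K QQ", "K", mode = "phoneme"), "QQ")
})

test_that("embeddings preserve PPMI geometry", {
  lex <- fix_mini_lexicon()
  cooc <- generate_cooccurrence(lex, n_templates = 30, base_count = 500,
                                seed = 6)
  counts <- cooc$counts
  # identical count rows embed with cosine 1
  counts2 <- counts
  counts2[2, ] <- counts2[1, ]
  emb2 <- build_embeddings(structure(list(counts = counts2),
                                     class = "cooc_table"), dims = 10)
  expect_equal(cosine_sim(emb2[1, ], emb2[2, ]), 1, tolerance = 1e-8)
  # full-rank embedding reproduces PPMI cosines exactly
  n <- sum(counts)
  pmi <- log((counts / n) / outer(rowSums(counts) / n, colSums(counts) / n))
  ppmi <- pmax(pmi, 0)
  ppmi[!is.finite(ppmi)] <- 0
  rank <- qr(ppmi)$rank
  emb <- build_embeddings(cooc, dims = rank)
  for (pair in list(c(1, 5), c(2, 9), c(10, 20)))
    expect_equal(cosine_sim(emb[pair[1], ], emb[pair[2], ]),
                 cosine_sim(ppmi[pair[1], ], ppmi[pair[2], ]),
                 tolerance = 1e-8)
  expect_error(build_embeddings(cooc, dims = nrow(counts) + 5), "rank")
})

test_that("embeddings are more similar within a POS class than across", {
  lex <- fix_mini_lexicon()
  for (s in 1:3) {
    cooc <- generate_cooccurrence(lex, n_templates = 60, base_count = 800,
                                  seed = s)
    emb <- build_embeddings(cooc, dims = 16)
    cs <- emb / sqrt(rowSums(emb^2))
    cs <- cs %*% t(cs)
    same <- outer(lex$pos9, lex$pos9, "==") & upper.tri(cs)
    diff_ <- (!outer(lex$pos9, lex$pos9, "==")) & upper.tri(cs)
    expect_gt(mean(cs[same]), mean(cs[diff_]))
  }
})

test_that("error profiles collect exactly the misidentified tokens", {
  lex <- fix_mini_lexicon()
  cooc <- generate_cooccurrence(lex, n_templates = 60, base_count = 800,
                                seed = 2)
  emb <- build_embeddings(cooc, dims = 8)
  targets <- build_targets(lex, "dorsal", fix_chart(), s_max = 5,
                           inventory = fix_inventory())
  words <- lex$id
  # perfect predictions: no errors
  p0 <- error_profile(targets[words, ], words, lex, targets, emb)
  expect_equal(p0$status, "no errors")
  expect_equal(p0$n_errors, 0L)
  # swap two targets: exactly those two tokens come out as errors
  preds <- targets[words, ]
  preds[1, ] <- targets[words[2], ]
  preds[2, ] <- targets[words[1], ]
  p1 <- error_profile(preds, words, lex, targets, emb)
  expect_equal(p1$status, "ok")
  expect_setequal(p1$errors$true[1:2], words[1:2])
  expect_setequal(p1$errors$predicted[1:2], words[2:1])
  expect_true(all(p1$errors$phon_sim >= 0 & p1$errors$phon_sim <= 1))
  expect_gte(p1$mean_phon_sim, min(p1$errors$phon_sim))
  expect_lte(p1$mean_phon_sim, max(p1$errors$phon_sim))
})
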