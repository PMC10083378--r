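test_that("selectivity counting matches the exhaustive oracles", {
  set.seed(8)
  for (rep in 1:3) {
    resp <- matrix(runif(12 * 2), 12, 2)
    lab <- rep(c("A", "B", "C"), each = 4)
    for (delta in c(0.05, 0.3)) {
      expect_equal(selectivity_index(resp, lab, delta,
                                     competitor = "per_class"),
                   si_oracle_perclass(resp, lab, delta))
      expect_equal(selectivity_index(resp, lab, delta,
                                     competitor = "global_max"),
                   si_oracle(resp, lab, delta))
    }
  }
})

test_that("a perfectly selective unit scores 1 and others 0", {
  lab <- rep(c("p", "q", "r"), each = 4)
  resp <- cbind(unit1 = ifelse(lab == "p", 1, 0))
  si <- selectivity_index(resp, lab, delta = 0.3)
  expect_equal(si["p", 1], 1)
  expect_equal(si["q", 1], 0)
  expect_equal(si["r", 1], 0)
  # constant unit: margin never reached
  si0 <- selectivity_index(cbind(rep(0.7, 12)), lab, delta = 0.3)
  expect_true(all(si0 == 0))
})

test_that("selectivity never increases with the margin threshold", {
  set.seed(9)
  resp <- matrix(runif(20 * 3), 20, 3)
  lab <- rep(letters[1:5], each = 4)
  deltas <- c(0, 0.1, 0.2, 0.3, 0.5)
  mats <- lapply(deltas, function(d) selectivity_index(resp, lab, d))
  for (i in seq_along(deltas)[-1])
    expect_true(all(mats[[i]] <= mats[[i - 1]] + 1e-12))
  expect_true(all(mats[[1]] >= 0 & mats[[1]] <= 1))
})

test_that("unit responses average the requested window frames", {
  traj <- matrix(rep(1:10, 2), 10, 2)              # two identical units
  # 10 frames at 200 Hz span 0-45 ms, all inside [0, 100)
  expect_equal(unit_response(traj, 0, 100, frame_rate = 200), c(5.5, 5.5))
  # single-frame window
  expect_equal(unit_response(traj, 20, 5, frame_rate = 200), c(5, 5))
  # 0-100 ms at 200 Hz: mean over 20 frames
  traj2 <- matrix(seq_len(40), 40, 1)
  expect_equal(unit_response(traj2, 0, 100, frame_rate = 200),
               mean(1:20))
  expect_error(unit_response(traj, 100, 100, frame_rate = 200,
                             n_valid = 10), "outside")
})

test_that("item dendrograms follow Ward geometry", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  hc <- cluster_items(m)
  expect_equal(hc$height[1], 0)                  # identical rows merge at 0
  expect_equal(sort(cutree(hc, 2)[c("a", "b")]), c(a = 1, b = 1))
  # merge order equals the naive ESS oracle on 5 items
  set.seed(11)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  got <- hclust_partitions(cluster_items(X))
  want <- ward_oracle_partitions(X)
  for (s in seq_along(want))
    expect_true(same_partition(got[[s]], want[[s]]))
  expect_true(all(diff(cluster_items(X)$height) >= 0))
})

test_that("cophenetic correlation behaves like a tree distance correlation", {
  set.seed(12)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  hc <- hclust(dist(X), method = "ward.D2")
  expect_equal(cophenetic_r(hc, hc), 1)
  # 4-leaf hand computation
  Y1 <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), 4, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  Y2 <- matrix(c(0, 0, 10, 0, 1, 0, 11, 0), 4, 2, byrow = TRUE,
               dimnames = list(c("a", "c", "b", "d"), NULL))
  h1 <- hclust(dist(Y1), method = "ward.D2")
  h2 <- hclust(dist(Y2), method = "ward.D2")
  m1 <- as.matrix(cophenetic(h1))
  m2 <- as.matrix(cophenetic(h2))[rownames(m1), rownames(m1)]
  want <- cor(m1[upper.tri(m1)], m2[upper.tri(m2)])
  expect_equal(cophenetic_r(h1, h2), want)
  # distance-preserving relabeling gives 1
  expect_equal(cophenetic_r(h1, h1), 1)
  h3 <- hclust(dist(matrix(rnorm(6), 3, 2,
                           dimnames = list(c("x", "y", "z"), NULL))))
  expect_error(cophenetic_r(h1, h3), "leaf sets")
})

test_that("reference hierarchies nest sonority classes and POS groups", {
  refs <- reference_trees(fix_inventory(), affix_table())
  expect_length(refs$phoneme$order, 39)
  expect_length(refs$morpheme$order, 20)
  cp <- as.matrix(cophenetic(refs$phoneme))
  inv <- fix_inventory()
  vow <- inv$phoneme[inv$class == "vowel"]
  stop_ <- inv$phoneme[inv$class == "voiceless_stop"]
  # vowels sit in a common subtree excluding obstruents
  expect_lt(max(cp[vow, vow]), min(cp[vow, stop_]))
  cm <- as.matrix(cophenetic(refs$morpheme))
  # plural -s and noun-forming -ment share the noun subtree; -ing does not
  expect_lt(cm["-s", "-ment"], cm["-s", "-ing"])
})

test_that("dendrograms serialize to Newick with all leaves", {
  refs <- reference_trees(fix_inventory(), affix_table())
  path <- tempfile(fileext = ".nwk")
  write_newick(refs$morpheme, path)
  txt <- readLines(path)
  for (a in affix_table()$affix)
    expect_true(grepl(gsub("-", "", a), paste(txt, collapse = "")) ||
                grepl(a, paste(txt, collapse = ""), fixed = TRUE))
  unlink(path)
})

test_that("morpheme selectivity requires every affix to be attested", {
  toy <- fix_toy_net()
  lex <- fix_mini_lexicon()
  lex2 <- lex[!(lex$affixes == "-ing"), ]
  expect_error(msi_matrix(toy$net, lex2$id, lex2), "-ing")
})

test_that("diphone sets cover all phonemes with known onsets", {
  tk <- generate_talkers(2, seed = 5)
  fb <- fix_filterbank()
  inv <- fix_inventory()
  dip <- make_diphones(inv, tk, fb, envelope_rate = 100, seed = 1)
  expect_equal(nrow(dip$meta), 39 * 2 * 2 * 2)   # 2 frames x CV/VC x talkers
  cnt <- table(dip$meta$target)
  expect_true(all(cnt >= 2 * nrow(tk)))
  expect_setequal(names(cnt), inv$phoneme)
  expect_true(all(dip$meta$onset_ms >= 0 &
                  dip$meta$onset_ms < dip$meta$duration_ms))
  expect_length(dip$cochleagrams, nrow(dip$meta))
})
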