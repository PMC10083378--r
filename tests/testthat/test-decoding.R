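test_that("pos9 derivation follows root class plus affix transformation", {
  w <- function(affixes, pos4 = "noun")
    list(affixes = affixes, pos4 = pos4)
  expect_equal(pos9_class(w("")), "singular_noun")
  expect_equal(pos9_class(w("-s")), "plural_noun")
  expect_equal(pos9_class(w("-ing")), "gerund_verb")
  expect_equal(pos9_class(w("-er")), "comparative_adjective")
  expect_equal(pos9_class(w("-ly")), "adverb")
  expect_equal(pos9_class(w("un-,-er")), "comparative_adjective")
  expect_error(pos9_class(list(affixes = "-zz", pos4 = "noun")), "unknown")
  # -s attaches to nouns; forcing a verb root is inconsistent
  expect_error(pos9_class(w("-s"), root_pos4 = "verb"), "inconsistent")
})

test_that("AMI is 1 for identical partitions and ~0 for random ones", {
  lab <- rep(c("a", "b", "c"), each = 10)
  expect_equal(ami_score(lab, lab), 1)
  set.seed(1)
  shuffles <- replicate(100, ami_score(lab, sample(lab)))
  expect_lt(abs(mean(shuffles)), 0.02)
})

test_that("AMI equals the exhaustive permutation oracle on 6-point toys", {
  set.seed(3)
  toys <- list(
    list(a = c(1, 1, 2, 2, 3, 3), b = c(1, 1, 2, 3, 3, 3)),
    list(a = c(1, 1, 1, 2, 2, 2), b = c(2, 2, 1, 1, 2, 1)),
    list(a = c(1, 2, 1, 2, 1, 2), b = c(1, 1, 2, 2, 3, 3)))
  for (t in toys)
    expect_equal(ami_score(t$a, t$b), ami_oracle(t$a, t$b),
                 tolerance = 1e-10)
})

test_that("AMI is symmetric and invariant to label renaming", {
  set.seed(4)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(ami_score(a, b), ami_score(b, a), tolerance = 1e-12)
  ren <- c("x", "z", "y")[a]
  expect_equal(ami_score(a, b), ami_score(ren, b), tolerance = 1e-12)
})

test_that("clustering one-hot copies of the labels recovers them perfectly", {
  lab <- rep(c("p", "q", "r"), each = 8)
  feats <- model.matrix(~ 0 + factor(lab)) + matrix(rnorm(72, 0, 1e-3),
                                                    24, 3)
  r <- cluster_and_score(feats, lab)
  expect_equal(r$ami, 1, tolerance = 1e-8)
  expect_equal(r$k, 3)
  expect_error(cluster_and_score(feats, lab, k = 1), "at least 2")
  expect_error(cluster_and_score(feats[1:3, ], lab[1:3], k = 3), "fewer")
})

test_that("Ward clustering follows the naive minimum-ESS-increase oracle", {
  set.seed(5)
  for (rep in 1:3) {
    X <- matrix(rnorm(10), 5, 2)
    hc <- hclust(dist(X), method = "ward.D2")
    got <- hclust_partitions(hc)
    want <- ward_oracle_partitions(X)
    for (s in seq_along(want))
      expect_true(same_partition(got[[s]], want[[s]]))
  }
})

test_that("feature matrices are standardized, strided, and time-major", {
  toy <- fix_toy_net()
  lab <- letters[toy$wid]
  fs <- build_feature_matrix(toy$net, lab, time_stride = 1,
                             weights = "final")
  T <- dim(toy$x)[2]
  H <- toy$net$config$hidden
  expect_equal(ncol(fs$features), T * H)
  expect_equal(nrow(fs$features), length(lab))
  sds <- apply(fs$features, 2, sd)
  expect_true(all(abs(colMeans(fs$features)) < 1e-8))
  expect_true(all(abs(sds - 1) < 1e-6 | sds == 0))
  fs2 <- build_feature_matrix(toy$net, lab, time_stride = 2,
                              weights = "final")
  expect_equal(ncol(fs2$features), length(seq(1, T, 2)) * H)
  expect_error(build_feature_matrix(toy$net, lab, time_stride = T + 1),
               "stride")
  # features from a well-trained toy net decode its word identity
  expect_gt(cluster_and_score(fs, lab, k = 8)$ami, 0.5)
})

test_that("the cluster-count sweep reports a profile around the true k", {
  lab <- rep(c("p", "q", "r", "s"), each = 6)
  feats <- model.matrix(~ 0 + factor(lab)) +
    matrix(rnorm(96, 0, 1e-3), 24, 4)
  prof <- ami_profile(feats, lab, span = 2)
  expect_equal(prof$k, 2:6)
  expect_equal(prof$ami[prof$k == 4], 1, tolerance = 1e-8)
})
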