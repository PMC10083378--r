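#' Nine-way part-of-speech class of a word
#'
#' Recomputes the 9-way class (singular/plural noun, adjective,
#' comparative adjective, base/past/gerund/present verb, adverb) from the
#' root's 4-way class and the word's affix chain, validating that each
#' affix attaches to the part of speech produced so far.
#'
#' @param word A lexicon row (fields `pos4` of the root via `root_pos4` or
#'   computed from `affixes`), or a list with `root_pos4` and `affixes`.
#' @param root_pos4 The root's 4-way class; by default recovered by
#'   stripping the word's affixes.
#' @param affixes Affix table.
#' @return One of the nine class labels.
#' @export
pos9_class <- function(word, root_pos4 = NULL, affixes = affix_table()) {
  chain <- if (nzchar(word$affixes)) strsplit(word$affixes, ",")[[1]]
           else character(0)
  if (is.null(root_pos4)) {
    # invert: the first affix's pos_in is the root's class; roots keep pos4
    root_pos4 <- if (length(chain))
      affixes$pos_in[match(chain[1], affixes$affix)] else word$pos4
  }
  cur4 <- root_pos4
  cur9 <- pos4_to_pos9(cur4)
  for (a in chain) {
    i <- match(a, affixes$affix)
    if (is.na(i)) stop("unknown affix: ", a)
    if (affixes$pos_in[i] != cur4)
      stop("inconsistent affix chain: ", a, " cannot attach to ", cur4)
    cur4 <- affixes$pos_out4[i]
    cur9 <- affixes$pos_out9[i]
  }
  unname(cur9)
}

#' Extract a labeled, standardized hidden-feature matrix
#'
#' Per token, the hidden trajectory (clamped over padding) is subsampled
#' by `time_stride`, flattened time-major into one long vector, and the
#' resulting tokens x features matrix is columnwise standardized to zero
#' mean and unit variance. Zero-variance columns are set to zero rather
#' than dropped, preserving index alignment.
#'
#' @param object A `stream_net`.
#' @param x Input batch (defaults to the stored one).
#' @param labels Per-token class labels (length = number of tokens).
#' @param time_stride Keep every `time_stride`-th frame.
#' @param weights `"best"` (default) or `"final"`.
#' @return A list of class `"feature_set"`: `features` (tokens x
#'   features), `labels`, `time_stride`, `n_constant` (count of
#'   zero-variance columns).
#' @export
build_feature_matrix <- function(object, labels, x = NULL, time_stride = 1,
                                 weights = "best") {
  traj <- predict(object, newdata = x, type = "hidden", weights = weights)
  n_t <- dim(traj)[2]
  if (time_stride > n_t) stop("time_stride exceeds the number of frames")
  keep <- seq(1, n_t, by = time_stride)
  traj <- traj[, keep, , drop = FALSE]
  # flatten time-major: frame 1 units, frame 2 units, ...
  feat <- matrix(aperm(traj, c(3, 2, 1)), nrow = dim(traj)[1], byrow = TRUE)
  mu <- colMeans(feat)
  sdv <- apply(feat, 2, sd)
  zero <- sdv == 0 | !is.finite(sdv)
  sdv[zero] <- 1
  feat <- sweep(sweep(feat, 2, mu), 2, sdv, "/")
  feat[, zero] <- 0
  stopifnot(length(labels) == nrow(feat))
  structure(list(features = feat, labels = as.character(labels),
                 time_stride = time_stride, n_constant = sum(zero)),
            class = "feature_set")
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information adjusted for chance under the permutation
#' (hypergeometric) model and normalized by the arithmetic mean of the two
#' entropies: random label assignments score about 0, identical
#' partitions score 1. Symmetric and invariant to label renaming.
#'
#' @param a,b Two label vectors of equal length.
#' @return A single number (<= 1).
#' @export
ami_score <- function(a, b) {
  stopifnot(length(a) == length(b))
  ct <- table(a, b)
  n <- sum(ct)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  pij <- ct / n
  nz <- ct > 0
  mi <- sum(pij[nz] * log(pij[nz] / (outer(ai, bj) / n^2)[nz]))
  hu <- -sum(ifelse(ai > 0, ai / n * log(ai / n), 0))
  hv <- -sum(ifelse(bj > 0, bj / n * log(bj / n), 0))
  if (max(hu, hv) == 0) return(1)          # both trivial partitions agree
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n)
    hi <- min(ai[i], bj[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      lp <- lfactorial(ai[i]) + lfactorial(n - ai[i]) + lfactorial(bj[j]) +
        lfactorial(n - bj[j]) - lfactorial(n) - lfactorial(nij) -
        lfactorial(ai[i] - nij) - lfactorial(bj[j] - nij) -
        lfactorial(n - ai[i] - bj[j] + nij)
      emi <- emi + nij / n * log(n * nij / (ai[i] * bj[j])) * exp(lp)
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  unname((mi - emi) / denom)
}

#' Cluster hidden features and score decoding accuracy
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) of the feature rows, cut at `k` clusters (by default the true
#' number of classes), scored against the true labels with adjusted
#' mutual information.
#'
#' @param features A `feature_set` from [build_feature_matrix()], or a
#'   plain matrix plus `labels`.
#' @param labels True class labels (taken from the `feature_set` if
#'   omitted).
#' @param k Number of clusters (>= 2; fewer than the number of rows).
#' @return A list: `ami`, `clusters` (integer assignment), `k`.
#' @export
cluster_and_score <- function(features, labels = NULL, k = NULL) {
  if (inherits(features, "feature_set")) {
    if (is.null(labels)) labels <- features$labels
    features <- features$features
  }
  if (is.null(k)) k <- length(unique(labels))
  if (k < 2) stop("k must be at least 2")
  if (nrow(features) <= k) stop("fewer tokens than clusters")
  hc <- hclust(dist(features), method = "ward.D2")
  cl <- cutree(hc, k = k)
  list(ami = ami_score(cl, labels), clusters = cl, k = k)
}

#' Sweep the cluster count around the true class count
#'
#' @inheritParams cluster_and_score
#' @param span Half-width of the sweep (k in `true_k - span` ...
#'   `true_k + span`, clipped at 2).
#' @return A data frame with columns `k` and `ami`.
#' @export
ami_profile <- function(features, labels = NULL, span = 2) {
  if (inherits(features, "feature_set") && is.null(labels))
    labels <- features$labels
  k0 <- length(unique(labels))
  ks <- unique(pmax(2, (k0 - span):(k0 + span)))
  data.frame(k = ks, ami = vapply(ks, function(k)
    cluster_and_score(features, labels, k)$ami, 1.0))
}
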