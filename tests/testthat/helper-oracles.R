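# Independent oracles used by the unit and acceptance tests.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) for (k in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = k)
  out
}

mi_of <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  p <- ct / n
  px <- rowSums(ct) / n
  py <- colSums(ct) / n
  nz <- ct > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

entropy_of <- function(a) {
  p <- table(a) / length(a)
  -sum(p * log(p))
}

# AMI by exhaustive permutation: the expected MI under the fixed-margin
# null is the average MI over all relabelings of the points
ami_oracle <- function(a, b) {
  n <- length(a)
  emi <- mean(vapply(perms(n), function(p) mi_of(a, b[p]), 1.0))
  den <- (entropy_of(a) + entropy_of(b)) / 2 - emi
  (mi_of(a, b) - emi) / den
}

# naive Ward agglomeration on raw coordinates: at each step merge the
# pair of clusters with the smallest increase in within-cluster sum of
# squares; returns the partition after each merge
ward_oracle_partitions <- function(X) {
  cl <- as.list(seq_len(nrow(X)))
  parts <- list()
  while (length(cl) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (j <= i) next
      a <- X[cl[[i]], , drop = FALSE]
      b <- X[cl[[j]], , drop = FALSE]
      d <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
        sum((colMeans(a) - colMeans(b))^2)
      if (d < best[1]) best <- c(d, i, j)
    }
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
    parts[[length(parts) + 1]] <- lapply(cl, sort)
  }
  parts
}

# partition sequence of an hclust, same shape as the oracle's
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  lapply((n - 1):1, function(k) {
    ct <- cutree(hc, k = k)
    unname(lapply(split(seq_len(n), ct), sort))
  })
}

same_partition <- function(p, q) {
  key <- function(part) sort(vapply(part, paste, "", collapse = ","))
  identical(key(p), key(q))
}

# weighted edit-distance similarity oracle via utils::adist
lev_oracle <- function(a, b) {
  d <- utils::adist(a, b, costs = list(insertions = 1, deletions = 1,
                                       substitutions = 2))[1, 1]
  (nchar(a) + nchar(b) - d) / (nchar(a) + nchar(b))
}

# brute-force per-class selectivity counting: for each target token, the
# fraction of non-target classes whose maximum it beats by delta
si_oracle_perclass <- function(responses, labels, delta) {
  items <- sort(unique(labels))
  out <- matrix(0, length(items), ncol(responses),
                dimnames = list(items, colnames(responses)))
  for (p in items) for (h in seq_len(ncol(responses))) {
    tgt <- which(labels == p)
    other <- setdiff(items, p)
    tot <- 0
    for (t in tgt) {
      beaten <- 0
      for (q in other) {
        qmax <- -Inf
        for (s in which(labels == q)) qmax <- max(qmax, responses[s, h])
        if (responses[t, h] >= qmax + delta) beaten <- beaten + 1
      }
      tot <- tot + beaten / length(other)
    }
    out[p, h] <- tot / length(tgt)
  }
  out
}

# brute-force global-max selectivity counting
si_oracle <- function(responses, labels, delta) {
  items <- sort(unique(labels))
  out <- matrix(0, length(items), ncol(responses),
                dimnames = list(items, colnames(responses)))
  for (p in items) for (h in seq_len(ncol(responses))) {
    cnt <- 0
    tgt <- which(labels == p)
    for (t in tgt) {
      margin_ok <- TRUE
      for (s in which(labels != p))
        if (responses[t, h] < responses[s, h] + delta) margin_ok <- FALSE
      if (margin_ok) cnt <- cnt + 1
    }
    out[p, h] <- cnt / length(tgt)
  }
  out
}
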