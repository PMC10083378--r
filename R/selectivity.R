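#' Synthesize diphone probe stimuli
#'
#' For every phoneme in the inventory, consonant--vowel and
#' vowel--consonant diphones are synthesized against a small set of frame
#' phonemes (vowel targets are framed by consonants and vice versa), for
#' every talker, and converted to cochleagrams. The target phoneme's onset
#' time is known exactly from synthesis.
#'
#' @param inventory Phoneme inventory.
#' @param talkers Talker panel.
#' @param fb Filterbank for cochleagram conversion.
#' @param envelope_rate,compression Cochleagram parameters.
#' @param frame_vowels,frame_consonants Frame phonemes for consonant and
#'   vowel targets respectively.
#' @param seed Integer seed.
#' @return A list of class `"diphone_set"`: `meta` (data frame with
#'   `target`, `context` (`"CV"`/`"VC"`), `frame`, `talker`, `onset_ms`,
#'   `duration_ms`) and `cochleagrams` (list, row-aligned with `meta`).
#' @export
make_diphones <- function(inventory = phoneme_inventory(), talkers, fb,
                          envelope_rate = 200, compression = 0.3,
                          frame_vowels = c("AA", "IY"),
                          frame_consonants = c("T", "S"), seed = 1) {
  rows <- list()
  cgs <- list()
  k <- 0L
  for (p in inventory$phoneme) {
    is_v <- inventory[p, "class"] == "vowel"
    frames <- if (is_v) frame_consonants else frame_vowels
    for (fr in frames) {
      pairs <- if (is_v) list(CV = c(fr, p), VC = c(p, fr))
               else list(CV = c(p, fr), VC = c(fr, p))
      for (ctx in names(pairs)) {
        ph <- pairs[[ctx]]
        for (ti in seq_len(nrow(talkers))) {
          tok <- synthesize_token(ph, talkers[ti, ],
                                  sample_rate = fb$sample_rate, seed = seed,
                                  inventory = inventory)
          cg <- compute_cochleagram(tok, fb, envelope_rate, compression)
          k <- k + 1L
          rows[[k]] <- data.frame(
            target = p, context = ctx, frame = fr,
            talker = talkers$talker[ti],
            onset_ms = unname(tok$onsets_ms[match(p, names(tok$onsets_ms))]),
            duration_ms = tok$duration_ms, stringsAsFactors = FALSE)
          cgs[[k]] <- cg
        }
      }
    }
  }
  structure(list(meta = do.call(rbind, rows), cochleagrams = cgs),
            class = "diphone_set")
}

#' Mean per-unit response in a time window
#'
#' @param trajectory A frames x units activation matrix (one token's
#'   hidden trajectory).
#' @param onset_ms Window start relative to token onset, in ms.
#' @param window_ms Window length in ms.
#' @param frame_rate Frame rate of the trajectory in Hz.
#' @param n_valid Number of valid (unpadded) frames.
#' @return A numeric vector, the mean activation per unit over frames in
#'   `[onset, onset + window)`.
#' @export
unit_response <- function(trajectory, onset_ms, window_ms = 100,
                          frame_rate = 200, n_valid = nrow(trajectory)) {
  t0 <- 1000 * (seq_len(nrow(trajectory)) - 1) / frame_rate
  ix <- which(t0 >= onset_ms & t0 < onset_ms + window_ms)
  ix <- ix[ix <= n_valid]
  if (!length(ix))
    stop("response window lies outside the valid frames")
  colMeans(trajectory[ix, , drop = FALSE])
}

#' Selectivity index from a response table
#'
#' The counting core shared by [psi_matrix()] and [msi_matrix()]: how
#' often tokens bearing an item drive a unit at least `delta` activation
#' units above the item's competitors, normalized to \[0, 1\] by the
#' target token count. Two competitor readings are implemented. The
#' default `per_class` rule counts, for each target token, the fraction
#' of non-target classes whose strongest token it beats by `delta` — the
#' class-wise comparison of the selectivity-index lineage this follows.
#' The stricter `global_max` rule requires beating the single strongest
#' non-target token of any class; with many probe tokens per class that
#' margin is rarely attainable and the matrix degenerates, which is why
#' it is not the default. Values never increase as `delta` grows.
#'
#' @param responses Tokens x units response matrix.
#' @param labels Item label per token.
#' @param delta Margin in activation units.
#' @param items Item order for the rows of the result.
#' @param competitor `"per_class"` (default) or `"global_max"`.
#' @return An items x units matrix in \[0, 1\].
#' @export
selectivity_index <- function(responses, labels, delta = 0.3,
                              items = sort(unique(labels)),
                              competitor = c("per_class", "global_max")) {
  competitor <- match.arg(competitor)
  responses <- as.matrix(responses)
  labels <- as.character(labels)
  H <- ncol(responses)
  out <- matrix(0, length(items), H,
                dimnames = list(items, colnames(responses)))
  for (p in items) {
    tgt <- labels == p
    if (!any(tgt)) stop("no tokens bearing item ", p)
    if (competitor == "global_max") {
      comp <- apply(responses[!tgt, , drop = FALSE], 2, max)
      hits <- sweep(responses[tgt, , drop = FALSE], 2, comp + delta) >= 0
      out[p, ] <- colMeans(hits)
    } else {
      other <- setdiff(items, p)
      acc <- matrix(0, sum(tgt), H)
      for (q in other) {
        comp <- apply(responses[labels == q, , drop = FALSE], 2, max)
        acc <- acc + (sweep(responses[tgt, , drop = FALSE], 2,
                            comp + delta) >= 0)
      }
      out[p, ] <- colMeans(acc / length(other))
    }
  }
  out
}

#' Phonemic selectivity index matrix
#'
#' Probes a trained network with diphone stimuli and scores each hidden
#' unit's selectivity for each of the 39 phonemes from its mean response
#' in a 0--100 ms window after target-phoneme onset.
#'
#' @param object A `stream_net`.
#' @param diphones A `diphone_set` from [make_diphones()].
#' @param window_ms Response window after phoneme onset, in ms.
#' @param delta Margin in activation units.
#' @param weights `"best"` (default) or `"final"`.
#' @param competitor Competitor rule, see [selectivity_index()].
#' @return A 39 x hidden-units `SelectivityMatrix`.
#' @export
psi_matrix <- function(object, diphones, window_ms = 100, delta = 0.3,
                       weights = "best",
                       competitor = c("per_class", "global_max")) {
  batch <- pad_batch(diphones$cochleagrams)
  traj <- predict(object, newdata = batch, type = "hidden",
                  weights = weights)
  rate <- diphones$cochleagrams[[1]]$envelope_rate
  resp <- t(vapply(seq_len(nrow(diphones$meta)), function(i) {
    m <- traj[i, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    unit_response(m, diphones$meta$onset_ms[i], window_ms, rate,
                  n_valid = batch$n_valid[i])
  }, numeric(dim(traj)[3])))
  selectivity_index(resp, diphones$meta$target, delta,
                    competitor = match.arg(competitor))
}

#' Morphemic selectivity index matrix
#'
#' Scores hidden-unit selectivity for each affix from the mean activation
#' of every root-plus-one-affix token over the full time window — all
#' frames of the padded batch, where frames beyond a token's length
#' repeat its final state under the masking layer's clamp semantics, so
#' the whole-word representation is weighted accordingly.
#'
#' @param object A `stream_net`.
#' @param batch Input batch of all tokens (defaults to the stored one).
#' @param token_words Word id per token.
#' @param lexicon Lexicon data frame.
#' @param affixes Affix table (all 20 affixes must be attested among
#'   one-affix words).
#' @param delta Margin in activation units.
#' @param weights,competitor See [psi_matrix()].
#' @return A 20 x hidden-units `SelectivityMatrix`.
#' @export
msi_matrix <- function(object, token_words, lexicon, batch = NULL,
                       affixes = affix_table(), delta = 0.3,
                       weights = "best",
                       competitor = c("per_class", "global_max")) {
  one <- lexicon[lexicon$n_affixes == 1, ]
  miss <- setdiff(affixes$affix, one$affixes)
  if (length(miss))
    stop("affix not attested in any one-affix word: ",
         paste(miss, collapse = ", "))
  ix <- which(token_words %in% one$id)
  traj <- predict(object, newdata = batch, type = "hidden",
                  weights = weights)
  resp <- t(vapply(ix, function(i) {
    m <- traj[i, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    colMeans(m)
  }, numeric(dim(traj)[3])))
  lab <- one$affixes[match(token_words[ix], one$id)]
  selectivity_index(resp, lab, delta, items = affixes$affix,
                    competitor = match.arg(competitor))
}

#' Ward dendrogram over selectivity items
#'
#' @param m An items x units selectivity matrix.
#' @return An `hclust` object (Euclidean distance, Ward linkage).
#' @export
cluster_items <- function(m) {
  if (nrow(m) < 2) stop("need at least two items to cluster")
  hclust(dist(m), method = "ward.D2")
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation between the upper triangles of the two trees'
#' cophenetic distance matrices, after aligning leaves by label.
#'
#' @param d1,d2 `hclust` objects over the same leaf set.
#' @return A number in \[-1, 1\].
#' @export
cophenetic_r <- function(d1, d2) {
  c1 <- as.matrix(cophenetic(d1))
  c2 <- as.matrix(cophenetic(d2))
  if (!setequal(rownames(c1), rownames(c2)))
    stop("dendrograms have different leaf sets")
  ord <- rownames(c1)
  c2 <- c2[ord, ord]
  ut <- upper.tri(c1)
  cor(c1[ut], c2[ut])
}

#' Reference phoneme and morpheme hierarchies
#'
#' Fixture dendrograms for cophenetic comparison: phonemes nested by
#' sonority class (vowels > glides > liquids > nasals > voiced fricatives
#' > voiceless fricatives = voiced stops > voiceless stops), and affixes
#' grouped by the part of speech of the words they create.
#'
#' @param inventory Phoneme inventory.
#' @param affixes Affix table.
#' @return A list with `hclust` elements `phoneme` (39 leaves) and
#'   `morpheme` (20 leaves).
#' @export
reference_trees <- function(inventory = phoneme_inventory(),
                            affixes = affix_table()) {
  n <- nrow(inventory)
  dp <- matrix(0, n, n, dimnames = list(inventory$phoneme, inventory$phoneme))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    same_cls <- inventory$class[i] == inventory$class[j]
    dp[i, j] <- abs(inventory$sonority[i] - inventory$sonority[j]) +
      (!same_cls) * 0.5 + 0.01 * abs(i - j) / n
  }
  ph_tree <- hclust(as.dist(dp), method = "ward.D2")
  m <- nrow(affixes)
  dm <- matrix(0, m, m, dimnames = list(affixes$affix, affixes$affix))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    dm[i, j] <- if (affixes$pos_out4[i] == affixes$pos_out4[j]) 0.1 else 1
    dm[i, j] <- dm[i, j] + 0.001 * abs(i - j) / m
  }
  list(phoneme = ph_tree, morpheme = hclust(as.dist(dm), method = "ward.D2"))
}

#' Serialize a dendrogram as Newick
#'
#' @param tree An `hclust`.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}
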