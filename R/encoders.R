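#' Syllabify a phoneme sequence
#'
#' One syllable per vocalic symbol; intervocalic consonants are assigned to
#' the following syllable's onset up to the longest legal onset (maximal
#' onset principle), the remainder to the preceding coda. Word-initial
#' consonants are all onset, word-final consonants all coda.
#'
#' @param phonemes Character vector of phoneme symbols.
#' @param inventory Phoneme inventory.
#' @param vocalic Symbols that may be syllable nuclei (default: the
#'   inventory's vowels; supply e.g. `c(vowels, "L")` to treat a final /L/
#'   as syllabic).
#' @param onsets Legal onset clusters (space-separated strings).
#' @return A list of character vectors, one per syllable.
#' @export
syllabify <- function(phonemes, inventory = phoneme_inventory(),
                      vocalic = NULL, onsets = legal_onsets(inventory)) {
  if (!length(phonemes)) stop("empty phoneme sequence")
  if (is.null(vocalic))
    vocalic <- inventory$phoneme[inventory$class == "vowel"]
  nuc <- which(phonemes %in% vocalic)
  if (!length(nuc)) stop("no vowel: cannot syllabify")
  n_syl <- length(nuc)
  syl <- vector("list", n_syl)
  # initial onset
  syl[[1]] <- phonemes[seq_len(nuc[1])]
  for (i in seq_len(n_syl - 1)) {
    clus <- if (nuc[i + 1] - nuc[i] > 1)
      phonemes[(nuc[i] + 1):(nuc[i + 1] - 1)] else character(0)
    # longest legal suffix of the cluster becomes the next onset
    take <- 0L
    for (k in seq_along(clus)) {
      cand <- paste(clus[(length(clus) - k + 1):length(clus)], collapse = " ")
      if (cand %in% onsets) take <- k
    }
    coda <- if (length(clus) > take) clus[seq_len(length(clus) - take)]
            else character(0)
    onset <- if (take > 0) clus[(length(clus) - take + 1):length(clus)]
             else character(0)
    syl[[i]] <- c(syl[[i]], coda)
    syl[[i + 1]] <- c(onset, phonemes[nuc[i + 1]])
  }
  if (nuc[n_syl] < length(phonemes))
    syl[[n_syl]] <- c(syl[[n_syl]], phonemes[(nuc[n_syl] + 1):length(phonemes)])
  syl
}

#' Length of a dorsal slot vector
#'
#' The slot template is an initial CCC onset cluster plus `s_max` VVCCC
#' syllable blocks, each slot holding one `n_features`-component vector:
#' `n_features * (3 + 5 * s_max)` components (812 at the defaults).
#'
#' @param s_max Maximum number of syllables.
#' @param n_features Feature vector length.
#' @export
dorsal_length <- function(s_max = 5, n_features = 29)
  n_features * (3 + 5 * s_max)

#' Encode a word as a dorsal (articulatory slot) target vector
#'
#' Places each phoneme's binary feature vector into a fixed slot grid:
#' three initial-onset consonant slots, then per syllable two vowel slots
#' and three consonant slots. The consonant slots of syllable *i* hold all
#' consonants between nucleus *i* and nucleus *i+1* (coda plus following
#' onset), left-aligned; the final block's consonant slots hold the final
#' coda. Monophthongs fill the first vowel slot only; diphthongs fill both.
#' Unfilled slots are zero vectors, so the vector carries no temporal cues
#' beyond slot identity.
#'
#' @param word A lexicon row, or a character vector of phonemes.
#' @param chart Feature chart from [feature_chart()].
#' @param s_max Maximum syllable count of the slot grid.
#' @param inventory Phoneme inventory.
#' @param vocalic Optional override of nucleus symbols (see [syllabify()]).
#' @return An integer vector of length `dorsal_length(s_max, ncol(chart))`.
#' @export
encode_dorsal <- function(word, chart = feature_chart(), s_max = 5,
                          inventory = phoneme_inventory(), vocalic = NULL) {
  ph <- if (is.character(word)) word else strsplit(word$phonemes, " ")[[1]]
  wname <- if (is.character(word)) paste(ph, collapse = " ") else word$id
  syl <- syllabify(ph, inventory = inventory, vocalic = vocalic)
  if (length(syl) > s_max)
    stop("word ", wname, " has ", length(syl), " syllables; s_max = ", s_max)
  if (is.null(vocalic))
    vocalic <- inventory$phoneme[inventory$class == "vowel"]
  nf <- ncol(chart)
  out <- integer(dorsal_length(s_max, nf))
  put <- function(slot, p) {
    if (!p %in% rownames(chart)) stop("phoneme ", p, " missing from chart")
    out[(slot - 1L) * nf + seq_len(nf)] <<- chart[p, ]
  }
  n_syl <- length(syl)
  nuclei <- lapply(syl, function(s) s[s %in% vocalic])
  onset1 <- syl[[1]][seq_len(match(TRUE, syl[[1]] %in% vocalic) - 1L)]
  if (length(onset1) > 3)
    stop("word ", wname, ": initial onset exceeds three consonants")
  for (k in seq_along(onset1)) put(k, onset1[k])
  for (i in seq_len(n_syl)) {
    nuc <- nuclei[[i]]
    if (length(nuc) > 2)
      stop("word ", wname, ": more than two vowels in syllable ", i)
    if (length(nuc) != 1)
      stop("word ", wname, ": syllable ", i, " lacks a single nucleus")
    vslot <- 3L + (i - 1L) * 5L
    put(vslot + 1L, nuc)
    dip <- isTRUE(inventory[nuc, "diphthong"]) ||
      (nuc %in% rownames(chart) && "diphthong" %in% colnames(chart) &&
       chart[nuc, "diphthong"] == 1)
    if (dip) put(vslot + 2L, nuc)
    # consonants after nucleus i, before nucleus i+1 (coda + next onset)
    ni <- match(nuc, syl[[i]])
    clus <- if (ni < length(syl[[i]]))
      syl[[i]][(ni + 1L):length(syl[[i]])] else character(0)
    if (i < n_syl) {
      nxt <- syl[[i + 1L]]
      nni <- match(TRUE, nxt %in% vocalic)
      if (nni > 1L) clus <- c(clus, nxt[seq_len(nni - 1L)])
    }
    if (length(clus) > 3)
      stop("word ", wname, ": consonant cluster after syllable ", i,
           " exceeds three slots")
    for (k in seq_along(clus)) put(vslot + 2L + k, clus[k])
  }
  out
}

#' Filter the template set for ventral encoding
#'
#' Iterates to a fixed point: templates admitting fewer than
#' `min_words_per_template` (surviving) words are dropped, and words
#' attested in fewer than `min_templates_per_word` surviving templates are
#' flagged and no longer count toward template admission.
#'
#' @param cooc A `cooc_table`.
#' @param min_words_per_template,min_templates_per_word Thresholds (>= 1).
#' @return A list of class `"template_set"`: `templates` (surviving ids),
#'   `admissible` (binary word x template attestation matrix over kept
#'   words), `words_kept`, `words_flagged`.
#' @export
build_template_set <- function(cooc, min_words_per_template = 160,
                               min_templates_per_word = 20) {
  stopifnot(min_words_per_template >= 1, min_templates_per_word >= 1)
  att <- (cooc$counts > 0) * 1L
  keep_t <- rep(TRUE, ncol(att))
  keep_w <- rep(TRUE, nrow(att))
  repeat {
    nt <- keep_t & colSums(att[keep_w, , drop = FALSE]) >= min_words_per_template
    nw <- keep_w & rowSums(att[, nt, drop = FALSE]) >= min_templates_per_word
    if (identical(nt, keep_t) && identical(nw, keep_w)) break
    keep_t <- nt
    keep_w <- nw
  }
  if (!any(keep_t)) stop("thresholds eliminate all templates")
  structure(list(templates = colnames(att)[keep_t],
                 admissible = att[keep_w, keep_t, drop = FALSE],
                 words_kept = rownames(att)[keep_w],
                 words_flagged = rownames(att)[!keep_w]),
            class = "template_set")
}

#' Encode a word as a ventral (co-occurrence indicator) target vector
#'
#' The binary attestation indicator of the word over the surviving
#' templates. Identical for every spoken token of the word.
#'
#' @param word A lexicon row, a word id, or anything with an `id` element.
#' @param template_set A `template_set` from [build_template_set()].
#' @return An integer 0/1 vector of length `length(template_set$templates)`.
#' @export
encode_ventral <- function(word, template_set) {
  id <- if (is.character(word)) word else word$id
  if (!id %in% template_set$words_kept)
    stop("word ", id, " was filtered out of the template set")
  as.integer(template_set$admissible[id, ])
}

#' Encode a word as a fused (dorsal + ventral) target vector
#'
#' @inheritParams encode_dorsal
#' @inheritParams encode_ventral
#' @return Concatenation of the dorsal and ventral vectors, dorsal first.
#' @export
encode_fused <- function(word, chart = feature_chart(), template_set,
                         s_max = 5, inventory = phoneme_inventory()) {
  c(encode_dorsal(word, chart, s_max, inventory),
    encode_ventral(word, template_set))
}

#' Build the full target matrix for a lexicon
#'
#' @param lexicon Lexicon data frame.
#' @param type One of `"dorsal"`, `"ventral"`, `"fused"`.
#' @param chart Feature chart.
#' @param template_set Required for ventral/fused targets.
#' @param s_max Maximum syllable count.
#' @param inventory Phoneme inventory.
#' @return A words x dimensions matrix with word ids as row names.
#' @export
build_targets <- function(lexicon, type = c("dorsal", "ventral", "fused"),
                          chart = feature_chart(), template_set = NULL,
                          s_max = 5, inventory = phoneme_inventory()) {
  type <- match.arg(type)
  rows <- lapply(seq_len(nrow(lexicon)), function(i) {
    w <- lexicon[i, ]
    switch(type,
           dorsal = encode_dorsal(w, chart, s_max, inventory),
           ventral = encode_ventral(w, template_set),
           fused = encode_fused(w, chart, template_set, s_max, inventory))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- lexicon$id
  m
}
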