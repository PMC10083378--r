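#' The 20-affix table
#'
#' Fifteen suffixes and five prefixes, each with its phonological form, the
#' part of speech it attaches to (`pos_in`, 4-way), and the 9-way part of
#' speech of the word it creates (`pos_out9`, with its 4-way projection
#' `pos_out4`). The spellings and forms are the package's own; the inventory
#' mirrors the productive English affixes (plural *-s*, *-ing*, *-ed*,
#' *-er*, *-est*, *-ly*, *-ment*, *un-*, *re-*, ...).
#'
#' @return A data frame with 20 rows and columns `affix`, `kind`
#'   (`prefix`/`suffix`), `phonemes`, `pos_in`, `pos_out9`, `pos_out4`.
#' @export
affix_table <- function() {
  s <- function(a, ph, pin, p9, p4) data.frame(
    affix = a, kind = "suffix", phonemes = ph, pos_in = pin,
    pos_out9 = p9, pos_out4 = p4, stringsAsFactors = FALSE)
  p <- function(a, ph, pin, p9, p4) data.frame(
    affix = a, kind = "prefix", phonemes = ph, pos_in = pin,
    pos_out9 = p9, pos_out4 = p4, stringsAsFactors = FALSE)
  rbind(
    s("-s",    "Z",        "noun",      "plural_noun",           "noun"),
    s("-es",   "AH Z",     "verb",      "present_verb",          "verb"),
    s("-ed",   "AH D",     "verb",      "past_verb",             "verb"),
    s("-ing",  "IH NG",    "verb",      "gerund_verb",           "verb"),
    s("-er",   "ER",       "adjective", "comparative_adjective", "adjective"),
    s("-est",  "AH S T",   "adjective", "comparative_adjective", "adjective"),
    s("-ly",   "L IY",     "adjective", "adverb",                "adverb"),
    s("-ment", "M AH N T", "verb",      "singular_noun",         "noun"),
    s("-ness", "N AH S",   "adjective", "singular_noun",         "noun"),
    s("-or",   "AH R",     "verb",      "singular_noun",         "noun"),
    s("-tion", "SH AH N",  "verb",      "singular_noun",         "noun"),
    s("-ful",  "F UH L",   "noun",      "adjective",             "adjective"),
    s("-less", "L AH S",   "noun",      "adjective",             "adjective"),
    s("-y",    "IY",       "noun",      "adjective",             "adjective"),
    s("-al",   "AH L",     "noun",      "adjective",             "adjective"),
    p("un-",   "AH N",     "adjective", "adjective",             "adjective"),
    p("re-",   "R IY",     "verb",      "base_verb",             "verb"),
    p("dis-",  "D IH S",   "verb",      "base_verb",             "verb"),
    p("pre-",  "P R IY",   "verb",      "base_verb",             "verb"),
    p("non-",  "N AA N",   "noun",      "singular_noun",         "noun")
  )
}

pos9_classes <- function() {
  c("singular_noun", "plural_noun", "adjective", "comparative_adjective",
    "base_verb", "past_verb", "gerund_verb", "present_verb", "adverb")
}

pos4_to_pos9 <- function(pos4) {
  c(noun = "singular_noun", verb = "base_verb", adjective = "adjective",
    adverb = "adverb")[pos4]
}

# crude phoneme -> spelling map for pseudo-orthography
.orth_map <- c(
  IY = "ee", IH = "i", EH = "e", AE = "a", AA = "o", AO = "aw", UH = "oo",
  UW = "u", AH = "u", ER = "ur", EY = "ay", AY = "ie", AW = "ow", OY = "oy",
  OW = "oe", W = "w", Y = "y", L = "l", R = "r", M = "m", N = "n", NG = "ng",
  F = "f", V = "v", TH = "th", DH = "dh", S = "s", Z = "z", SH = "sh",
  ZH = "zh", HH = "h", CH = "ch", JH = "j", P = "p", B = "b", T = "t",
  D = "d", K = "k", G = "g")

phonemes_to_orth <- function(ph) paste(.orth_map[ph], collapse = "")

# single random root: stratified onset class, (C)(C)V(C)(C) (+ optional
# second syllable CV(C))
.sample_root <- function(onset_cls, inventory, force = NULL) {
  vows <- inventory$phoneme[inventory$class == "vowel"]
  cons <- inventory$phoneme[inventory$class != "vowel"]
  codas1 <- setdiff(cons, c("HH", "W", "Y"))
  codas2 <- c("N T", "N D", "S T", "S K", "K S", "T S", "L T", "L D", "R T",
              "R D", "N S", "M P", "NG K", "F T", "P T", "K T", "L S",
              "R N", "R M", "L Z", "R Z", "N Z")
  ons <- legal_onsets(inventory)
  pick_onset <- function(cls) {
    if (cls == "vowel") return(character(0))
    cands <- cons[vapply(cons, function(x)
      onset_class(x, inventory) == cls && x != "NG", TRUE)]
    c1 <- sample(cands, 1)
    # occasionally extend to a legal cluster
    ext <- ons[startsWith(ons, paste0(c1, " "))]
    if (length(ext) && runif(1) < 0.25) strsplit(sample(ext, 1), " ")[[1]]
    else c1
  }
  onset <- pick_onset(onset_cls)
  nuc <- if (!is.null(force) && force %in% vows) force else sample(vows, 1)
  ncoda <- sample(0:2, 1, prob = c(0.35, 0.45, 0.20))
  coda <- if (ncoda == 0) character(0)
          else if (ncoda == 1) sample(codas1, 1)
          else strsplit(sample(codas2, 1), " ")[[1]]
  ph <- c(onset, nuc, coda)
  if (runif(1) < 0.35) {            # optional second syllable: C V (C)
    on2 <- sample(setdiff(cons, c("NG")), 1)
    nuc2 <- sample(vows, 1)
    coda2 <- if (runif(1) < 0.4) sample(codas1, 1) else character(0)
    ph <- c(ph, on2, nuc2, coda2)
  }
  if (!is.null(force) && !force %in% ph) {
    # place a forced consonant legally: NG only in coda, others as onset
    vpos <- match(TRUE, ph %in% vows)
    if (force == "NG") ph <- append(ph, "NG", after = vpos)
    else if (!force %in% vows) ph <- c(force, ph[vpos:length(ph)])
  }
  if (length(ph) < 2) ph <- c(ph, sample(codas1, 1))
  ph
}

#' Generate a morphologically structured lexicon
#'
#' Samples phonotactically legal roots (stratified over the seven onset
#' classes, with coverage of the full phoneme inventory enforced), derives
#' words by attaching one affix (and a small fraction with a prefix +
#' suffix pair), applies a form-length filter, and returns the lexicon
#' table. Deterministic given `seed`.
#'
#' @param inventory Phoneme inventory, see [phoneme_inventory()].
#' @param n_roots Number of monomorphemic roots.
#' @param affixes Affix table, see [affix_table()].
#' @param n_one_affix Number of one-affix derived words (default scales with
#'   `n_roots` as roughly 690/260; every affix is attested at least once
#'   when `n_one_affix >= nrow(affixes)`).
#' @param n_two_affix Number of prefix+suffix words (default about 3\% of
#'   the lexicon).
#' @param min_len,max_len Form length constraint in phonemes.
#' @param seed Integer seed.
#' @return A data frame with one row per word: `id`, `orthography`,
#'   `phonemes` (space-separated), `syllables` (`.`-separated syllable
#'   blocks), `root`, `affixes` (comma-separated, `""` for roots),
#'   `n_affixes`, `pos4`, `pos9`, `onset_class`.
#' @export
generate_lexicon <- function(inventory = phoneme_inventory(),
                             n_roots = 252,
                             affixes = affix_table(),
                             n_one_affix = round(n_roots * 690 / 260),
                             n_two_affix = round(n_roots * 50 / 260),
                             min_len = 2, max_len = 10,
                             seed = 1) {
  if (min_len > max_len || max_len < 2)
    stop("impossible length constraints: no legal root fits [",
         min_len, ", ", max_len, "]")
  if (n_roots < 4)
    stop("n_roots must cover the four parts of speech")
  with_seed(seed, {
    cls7 <- onset_classes()
    # fixed class proportions (shuffled), so every class has a workable
    # number of members at any lexicon size
    quota <- setNames(pmax(1, round(c(0.40, 0.30, 0.22, 0.08) * n_roots)),
                      c("noun", "verb", "adjective", "adverb"))
    while (sum(quota) > n_roots) quota[which.max(quota)] <-
      quota[which.max(quota)] - 1L
    while (sum(quota) < n_roots) quota[which.min(quota)] <-
      quota[which.min(quota)] + 1L
    pos4 <- sample(rep(names(quota), quota))
    roots <- vector("list", n_roots)
    seen <- character(0)
    for (i in seq_len(n_roots)) {
      for (try in 1:200) {
        ph <- .sample_root(cls7[(i - 1L) %% 7L + 1L], inventory)
        key <- paste(ph, collapse = " ")
        if (!key %in% seen && length(ph) >= min_len && length(ph) <= max_len) break
      }
      seen <- c(seen, key)
      roots[[i]] <- ph
    }
    # coverage repair: rebuild roots (from the end) around missing
    # phonemes, iterating since a rebuild may orphan another phoneme
    ri <- n_roots
    for (pass in 1:10) {
      missing <- setdiff(inventory$phoneme, unique(unlist(roots)))
      if (!length(missing) || ri < 1L) break
      for (mp in missing) {
        if (ri < 1L) break
        for (try in 1:200) {
          cls <- cls7[(ri - 1L) %% 7L + 1L]
          if (mp != "NG" && inventory[mp, "class"] != "vowel")
            cls <- onset_class(mp, inventory)
          ph <- .sample_root(cls, inventory, force = mp)
          key <- paste(ph, collapse = " ")
          if (mp %in% ph && !key %in% seen &&
              length(ph) >= min_len && length(ph) <= max_len) break
        }
        seen[ri] <- key
        roots[[ri]] <- ph
        ri <- ri - 1L
      }
    }

    word <- function(id, ph, root_id, affs, pos4w, pos9w) {
      syl <- syllabify(ph, inventory = inventory)
      data.frame(id = id, orthography = NA_character_,
                 phonemes = paste(ph, collapse = " "),
                 syllables = paste(vapply(syl, paste, "", collapse = " "),
                                   collapse = " . "),
                 root = root_id,
                 affixes = paste(affs, collapse = ","),
                 n_affixes = length(affs), pos4 = pos4w, pos9 = pos9w,
                 onset_class = onset_class(ph, inventory),
                 stringsAsFactors = FALSE)
    }
    out <- vector("list", n_roots + n_one_affix + n_two_affix)
    for (i in seq_len(n_roots))
      out[[i]] <- word(sprintf("w%04d", i), roots[[i]], sprintf("w%04d", i),
                       character(0), pos4[i], pos4_to_pos9(pos4[i]))
    apply_affix <- function(ph, a) {
      aph <- strsplit(affixes$phonemes[a], " ")[[1]]
      if (affixes$kind[a] == "prefix") c(aph, ph) else c(ph, aph)
    }
    k <- n_roots
    used <- character(0)
    alen <- lengths(strsplit(affixes$phonemes, " "))
    for (j in seq_len(n_one_affix)) {
      a <- (j - 1L) %% nrow(affixes) + 1L
      # only roots whose derived form survives the length filter
      elig <- which(pos4 == affixes$pos_in[a] &
                    lengths(roots) + alen[a] <= max_len &
                    lengths(roots) + alen[a] >= min_len)
      if (!length(elig)) next
      for (try in 1:100) {
        r <- sample(elig, 1)
        if (!paste(r, a) %in% used) break
      }
      used <- c(used, paste(r, a))
      k <- k + 1L
      out[[k]] <- word(sprintf("w%04d", k), apply_affix(roots[[r]], a),
                       sprintf("w%04d", r), affixes$affix[a],
                       affixes$pos_out4[a], affixes$pos_out9[a])
    }
    pre <- which(affixes$kind == "prefix")
    for (j in seq_len(n_two_affix)) {
      for (try in 1:200) {
        p <- sample(pre, 1)
        elig <- which(pos4 == affixes$pos_in[p])
        if (!length(elig)) next
        r <- sample(elig, 1)
        # prefixes preserve pos4, so any suffix taking that pos4 applies
        sfx <- which(affixes$kind == "suffix" &
                     affixes$pos_in == affixes$pos_out4[p])
        if (!length(sfx)) next
        s2 <- sample(sfx, 1)
        key <- paste(r, p, s2)
        if (!key %in% used) break
      }
      used <- c(used, key)
      k <- k + 1L
      out[[k]] <- word(sprintf("w%04d", k),
                       apply_affix(apply_affix(roots[[r]], p), s2),
                       sprintf("w%04d", r),
                       c(affixes$affix[p], affixes$affix[s2]),
                       affixes$pos_out4[s2], affixes$pos_out9[s2])
    }
    lex <- do.call(rbind, out[seq_len(k)])
    # form length filter + uniqueness
    len <- lengths(strsplit(lex$phonemes, " "))
    lex <- lex[len >= min_len & len <= max_len, , drop = FALSE]
    lex <- lex[!duplicated(lex$phonemes), , drop = FALSE]
    if (!nrow(lex)) stop("length constraints eliminated the entire lexicon")
    lex$orthography <- vapply(strsplit(lex$phonemes, " "), phonemes_to_orth, "")
    rownames(lex) <- lex$id
    lex
  })
}

#' Write / read a lexicon as TSV
#'
#' @param lexicon A lexicon data frame from [generate_lexicon()].
#' @param path File path.
#' @return `read_lexicon()` returns the lexicon data frame.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  lex$n_affixes <- as.integer(lex$n_affixes)
  lex$affixes[is.na(lex$affixes)] <- ""
  rownames(lex) <- lex$id
  lex
}
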