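#' Generate a POS-structured word-by-template co-occurrence table
#'
#' Emulates trigram-template co-occurrence statistics: each template is a
#' three-word context with one open slot that admits a single grammatical
#' class. A template is assigned a 4-way part-of-speech slot, and within
#' that class a preference distribution over the 9-way subclasses drawn
#' from a symmetric Dirichlet with concentration `pos_affinity` (lower
#' values give more POS-selective templates). Word occurrence totals follow
#' a Zipf law; each word's total is spread over the templates compatible
#' with its 4-way class, weighted by the templates' preference for the
#' word's 9-way class. Words of the same 9-way class therefore have more
#' similar template profiles than words of different classes.
#'
#' @param lexicon Lexicon from [generate_lexicon()].
#' @param n_templates Number of templates (at least 9).
#' @param pos_affinity Dirichlet concentration (> 0) controlling template
#'   POS selectivity.
#' @param zipf_exponent Zipf exponent for word totals.
#' @param base_count Count assigned to the most frequent word.
#' @param min_total Floor on per-word totals (keeps rare words attested in
#'   enough templates to survive filtering).
#' @param seed Integer seed.
#' @return A list of class `"cooc_table"` with `counts` (word x template
#'   integer matrix), `templates` (data frame: `template`, `pos4`), and the
#'   generating parameters.
#' @export
generate_cooccurrence <- function(lexicon, n_templates = 1400,
                                  pos_affinity = 0.25, zipf_exponent = 1.0,
                                  base_count = 3000, min_total = 40,
                                  seed = 1) {
  if (!nrow(lexicon)) stop("empty lexicon")
  if (pos_affinity <= 0) stop("pos_affinity must be > 0")
  if (n_templates < length(pos9_classes()))
    stop("n_templates must be at least the number of pos9 classes")
  p9 <- pos9_classes()
  p9_of_p4 <- list(noun = c("singular_noun", "plural_noun"),
                   verb = c("base_verb", "past_verb", "gerund_verb",
                            "present_verb"),
                   adjective = c("adjective", "comparative_adjective"),
                   adverb = "adverb")
  with_seed(seed, {
    pos4_prop <- table(factor(lexicon$pos4, names(p9_of_p4)))
    # guarantee every 4-way class a floor of templates, rest proportional
    m <- ceiling(n_templates / 20)
    floor_t <- rep(names(p9_of_p4), m)
    tpos4 <- c(floor_t,
               sample(names(p9_of_p4), n_templates - length(floor_t),
                      replace = TRUE, prob = pmax(as.numeric(pos4_prop), 1)))
    # template preference over its pos4's subclasses: Dirichlet draws with
    # the peak cycled over the subclasses, so every 9-way class has
    # templates that favor it
    pref <- matrix(0, n_templates, length(p9), dimnames = list(NULL, p9))
    cyc <- integer(length(p9_of_p4))
    names(cyc) <- names(p9_of_p4)
    for (t in seq_len(n_templates)) {
      sub <- p9_of_p4[[tpos4[t]]]
      cyc[tpos4[t]] <- cyc[tpos4[t]] %% length(sub) + 1L
      des <- cyc[tpos4[t]]
      g <- stats::rgamma(length(sub), shape = pos_affinity)
      if (sum(g) <= 0) {                        # degenerate concentration
        g <- rep(.Machine$double.xmin, length(sub))
        g[des] <- 1
      }
      mx <- which.max(g)
      g[c(des, mx)] <- g[c(mx, des)]
      pref[t, sub] <- g / sum(g)
    }
    ranks <- sample(nrow(lexicon))
    totals <- pmax(min_total, round(base_count * ranks^(-zipf_exponent)))
    counts <- matrix(0L, nrow(lexicon), n_templates,
                     dimnames = list(lexicon$id,
                                     sprintf("tpl%04d", seq_len(n_templates))))
    for (i in seq_len(nrow(lexicon))) {
      j <- which(tpos4 == lexicon$pos4[i])
      w <- pref[j, lexicon$pos9[i]] + 1e-9
      counts[i, j] <- as.integer(stats::rmultinom(1, totals[i], w))
    }
    structure(list(counts = counts,
                   templates = data.frame(template = colnames(counts),
                                          pos4 = tpos4,
                                          stringsAsFactors = FALSE),
                   pos_affinity = pos_affinity,
                   zipf_exponent = zipf_exponent, seed = seed),
              class = "cooc_table")
  })
}

#' Write / read a co-occurrence table as sparse triplet CSV
#'
#' @param cooc A `cooc_table` from [generate_cooccurrence()].
#' @param path File path.
#' @return `read_cooccurrence()` returns a `cooc_table` (without the
#'   generating parameters).
#' @export
write_cooccurrence <- function(cooc, path) {
  idx <- which(cooc$counts > 0, arr.ind = TRUE)
  df <- data.frame(word_id = rownames(cooc$counts)[idx[, 1]],
                   template_id = colnames(cooc$counts)[idx[, 2]],
                   count = cooc$counts[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  words <- sort(unique(df$word_id))
  tpls <- sort(unique(df$template_id))
  m <- matrix(0L, length(words), length(tpls), dimnames = list(words, tpls))
  m[cbind(match(df$word_id, words), match(df$template_id, tpls))] <-
    as.integer(df$count)
  structure(list(counts = m,
                 templates = data.frame(template = tpls,
                                        pos4 = NA_character_,
                                        stringsAsFactors = FALSE)),
            class = "cooc_table")
}
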