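#' Weighted Levenshtein similarity ratio
#'
#' The normalized similarity `(|a| + |b| - d) / (|a| + |b|)`, where `d` is
#' the minimum-cost edit distance with insertion/deletion cost 1 and
#' substitution cost 2. Ranges from 0 (no similarity) to 1 (identical);
#' e.g. `lev_ratio("acted", "active")` is 0.73 to two decimals. In
#' `"phoneme"` mode the inputs are space-separated phoneme strings, mapped
#' internally to a one-character-per-phoneme alphabet so that each phoneme
#' counts as one symbol.
#'
#' @param a,b Nonempty strings (orthographic), or space-separated phoneme
#'   strings in `"phoneme"` mode.
#' @param mode `"orthographic"` (default) or `"phoneme"`.
#' @param inventory Phoneme inventory (for `"phoneme"` mode).
#' @return A number in \[0, 1\].
#' @export
lev_ratio <- function(a, b, mode = c("orthographic", "phoneme"),
                      inventory = phoneme_inventory()) {
  mode <- match.arg(mode)
  if (mode == "phoneme") {
    enc <- function(s) {
      ph <- strsplit(s, " +")[[1]]
      bad <- setdiff(ph, inventory$phoneme)
      if (length(bad)) stop("unknown phoneme symbol: ", bad[1])
      paste(inventory[ph, "char"], collapse = "")
    }
    a <- enc(a)
    b <- enc(b)
  }
  if (!nzchar(a) || !nzchar(b)) stop("lev_ratio requires nonempty strings")
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa)
  lb <- length(sb)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1)
    cur[1] <- i
    for (j in seq_len(lb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + if (sa[i] == sb[j]) 0 else 2)
    }
    prev <- cur
  }
  (la + lb - prev[lb + 1]) / (la + lb)
}

#' Distributional word embeddings from the co-occurrence table
#'
#' Positive pointwise mutual information transform of the word x template
#' counts followed by truncated singular value decomposition; the
#' embedding is `U[, 1:dims] %*% diag(d[1:dims])`, which at full rank
#' preserves the pairwise cosines of the PPMI rows exactly.
#'
#' @param cooc A `cooc_table` (or a plain counts matrix).
#' @param dims Embedding dimensionality (must not exceed the PPMI rank).
#' @param seed Unused source of randomness kept for interface symmetry;
#'   the decomposition is deterministic.
#' @return A words x dims matrix with word ids as row names.
#' @export
build_embeddings <- function(cooc, dims = 50, seed = 1) {
  counts <- if (inherits(cooc, "cooc_table")) cooc$counts else cooc
  n <- sum(counts)
  pw <- rowSums(counts) / n
  pt <- colSums(counts) / n
  pmi <- log((counts / n) / outer(pw, pt))
  ppmi <- pmax(pmi, 0)
  ppmi[!is.finite(ppmi)] <- 0
  sv <- svd(ppmi)
  rank <- sum(sv$d > max(dim(ppmi)) * .Machine$double.eps * sv$d[1])
  if (dims > rank)
    stop("dims (", dims, ") exceeds the PPMI matrix rank (", rank, ")")
  emb <- sv$u[, seq_len(dims), drop = FALSE] %*% diag(sv$d[seq_len(dims)],
                                                      dims)
  rownames(emb) <- rownames(counts)
  zero <- rowSums(emb^2) == 0
  if (any(zero))
    stop("zero embedding for word(s): ",
         paste(rownames(emb)[zero], collapse = ", "))
  emb
}

#' Characterize a network's identification errors
#'
#' Collects every token whose lexicon-competitive identification was
#' wrong, and scores each error pair for phonological similarity (weighted
#' Levenshtein ratio on phoneme strings) and semantic similarity (cosine
#' of the distributional embeddings). Both similarities are computed on
#' the identical error set.
#'
#' @param predictions Tokens x dim prediction matrix (or a `stream_net`,
#'   in which case predictions use its stored batch).
#' @param token_words True word id per token.
#' @param lexicon Lexicon data frame.
#' @param targets Lexicon target matrix.
#' @param embeddings Embedding matrix from [build_embeddings()].
#' @param weights Which weights when `predictions` is a model.
#' @return A list of class `"error_profile"`: `status` (`"ok"` or
#'   `"no errors"`), `errors` (data frame: token, true, predicted,
#'   phon_sim, sem_sim), `mean_phon_sim`, `mean_sem_sim`, `n_errors`.
#' @export
error_profile <- function(predictions, token_words, lexicon, targets,
                          embeddings, weights = "final") {
  if (inherits(predictions, "stream_net"))
    predictions <- predict(predictions, weights = weights)
  rep_ <- accuracy_report(predictions, token_words, targets)
  pt <- rep_$per_token
  err <- pt[!pt$correct, , drop = FALSE]
  if (!nrow(err)) {
    return(structure(list(status = "no errors",
                          errors = data.frame(), n_errors = 0L,
                          mean_phon_sim = NA_real_,
                          mean_sem_sim = NA_real_),
                     class = "error_profile"))
  }
  phon <- vapply(seq_len(nrow(err)), function(i)
    lev_ratio(lexicon[err$true[i], "phonemes"],
              lexicon[err$predicted[i], "phonemes"], mode = "phoneme"), 1.0)
  sem <- vapply(seq_len(nrow(err)), function(i)
    cosine_sim(embeddings[err$true[i], ], embeddings[err$predicted[i], ]),
    1.0)
  errors <- data.frame(token = err$token, true = err$true,
                       predicted = err$predicted, phon_sim = phon,
                       sem_sim = sem)
  structure(list(status = "ok", errors = errors, n_errors = nrow(errors),
                 mean_phon_sim = mean(phon), mean_sem_sim = mean(sem)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  if (x$status == "no errors") cat("No identification errors.\n")
  else cat(sprintf(
    "%d identification errors: mean phonological similarity %.3f, mean semantic similarity %.3f\n",
    x$n_errors, x$mean_phon_sim, x$mean_sem_sim))
  invisible(x)
}
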