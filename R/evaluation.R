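#' Cosine similarity
#'
#' `dot(a, b) / (||a|| ||b||)`; lies in \[0, 1\] for componentwise
#' nonnegative inputs. Zero vectors are an error.
#'
#' @param a,b Numeric vectors of equal length.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Identify a word by nearest-cosine lookup over the lexicon
#'
#' The predicted word is the lexicon entry whose target vector has the
#' highest cosine similarity to the prediction. A token is identified
#' correctly only when the true word's cosine strictly exceeds every other
#' word's; ties count as errors and are flagged.
#'
#' @param prediction Numeric prediction vector.
#' @param targets Lexicon target matrix (words x dimensions, word ids as
#'   row names).
#' @param true_word Optional true word id.
#' @return A list: `predicted`, `cosines` (named vector), `tie`, and — when
#'   `true_word` is given — `correct` and `cosine_true`.
#' @export
identify_word <- function(prediction, targets, true_word = NULL) {
  if (!nrow(targets)) stop("empty lexicon")
  nt <- sqrt(rowSums(targets^2))
  np <- sqrt(sum(prediction^2))
  if (np == 0) stop("cosine similarity undefined for zero vectors")
  cs <- as.numeric(targets %*% prediction) / (nt * np)
  names(cs) <- rownames(targets)
  top <- max(cs)
  tie <- sum(cs >= top - 1e-12) > 1
  pred <- names(cs)[which.max(cs)]
  out <- list(predicted = pred, cosines = cs, tie = tie)
  if (!is.null(true_word)) {
    out$correct <- !tie && identical(pred, true_word)
    out$cosine_true <- unname(cs[true_word])
  }
  out
}

#' Accuracy report for a fitted network
#'
#' Computes, per token, the cosine similarity of the final-step prediction
#' to the true target and the lexicon-competitive identification outcome,
#' aggregated over the training set, the validation set, and both
#' combined. Mean cosine and identification accuracy are distinct
#' quantities and both are reported.
#'
#' @param object A `stream_net` (or a precomputed tokens x dim prediction
#'   matrix).
#' @param token_words Character vector of true word ids, one per token.
#' @param targets Lexicon target matrix (rownames = word ids).
#' @param x Input batch for prediction (defaults to the stored batch).
#' @param train_idx,val_idx Token index vectors (default: the fit's split).
#' @param weights Which weights to use, `"final"` or `"best"`.
#' @return A list of class `"accuracy_report"`: `summary` (data frame with
#'   rows train/validation/combined: `n_tokens`, `mean_cosine`,
#'   `n_correct`, `accuracy`) and `per_token`.
#' @export
accuracy_report <- function(object, token_words, targets, x = NULL,
                            train_idx = NULL, val_idx = NULL,
                            weights = "final") {
  if (inherits(object, "stream_net")) {
    if (is.null(train_idx)) train_idx <- object$train_idx
    if (is.null(val_idx)) val_idx <- object$val_idx
    preds <- predict(object, newdata = x, weights = weights)
  } else preds <- object
  stopifnot(nrow(preds) == length(token_words))
  n <- length(token_words)
  res <- lapply(seq_len(n), function(i)
    identify_word(preds[i, ], targets, token_words[i]))
  per_token <- data.frame(
    token = seq_len(n), true = token_words,
    predicted = vapply(res, `[[`, "", "predicted"),
    correct = vapply(res, `[[`, TRUE, "correct"),
    tie = vapply(res, `[[`, TRUE, "tie"),
    cosine_true = vapply(res, `[[`, 1.0, "cosine_true"),
    subset = ifelse(seq_len(n) %in% val_idx, "validation",
                    ifelse(seq_len(n) %in% train_idx, "train", "other")))
  agg <- function(ix, label) data.frame(
    subset = label, n_tokens = length(ix),
    mean_cosine = mean(per_token$cosine_true[ix]),
    n_correct = sum(per_token$correct[ix]),
    accuracy = mean(per_token$correct[ix]))
  summ <- rbind(
    if (length(train_idx)) agg(train_idx, "train"),
    if (length(val_idx)) agg(val_idx, "validation"),
    agg(seq_len(n), "combined"))
  structure(list(summary = summ, per_token = per_token),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
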