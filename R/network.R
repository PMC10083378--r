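#' Closed-form LSTM + dense parameter count
#'
#' `4 * (hidden * (input + hidden) + hidden) + (hidden * output + output)`.
#'
#' @param input,hidden,output Layer sizes.
#' @export
lstm_param_count <- function(input, hidden, output)
  4 * (hidden * (input + hidden) + hidden) + (hidden * output + output)

#' Split tokens into training and validation sets by talker
#'
#' Holds out every token of one talker (the same talker for all words), so
#' validation measures generalization to an unheard voice. With 10 talkers
#' this is a nine-to-one split. A per-word random holdout is available as
#' an alternative.
#'
#' @param tokens A data frame with columns `word` and `talker` (one row per
#'   token).
#' @param holdout `"same_talker"` (default) or `"per_word"`.
#' @param seed Integer seed selecting the held-out talker.
#' @return A list with integer index vectors `train` and `val`, and
#'   `holdout_talker` (for the default scheme).
#' @export
split_train_val <- function(tokens, holdout = c("same_talker", "per_word"),
                            seed = 1) {
  holdout <- match.arg(holdout)
  talkers <- unique(tokens$talker)
  if (length(talkers) < 2) stop("need at least two talkers to split")
  with_seed(seed, {
    if (holdout == "same_talker") {
      ht <- sample(talkers, 1)
      val <- which(tokens$talker == ht)
      list(train = setdiff(seq_len(nrow(tokens)), val), val = val,
           holdout_talker = ht)
    } else {
      val <- unlist(lapply(split(seq_len(nrow(tokens)), tokens$word),
                           function(ix) ix[sample.int(length(ix), 1)]))
      val <- sort(unname(val))
      list(train = setdiff(seq_len(nrow(tokens)), val), val = val,
           holdout_talker = NA_character_)
    }
  })
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

.orthogonal <- function(n) {
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}

# Glorot input/dense kernels, orthogonal recurrent blocks (one per gate),
# zero biases with a unit forget-gate bias
init_lstm_weights <- function(input, hidden, output, seed = 1) {
  with_seed(seed, {
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1           # forget-gate bias
    list(Wx = .glorot(4 * hidden, input),
         Wh = do.call(rbind, lapply(1:4, function(g) .orthogonal(hidden))),
         b = b,
         Wd = .glorot(output, hidden),
         bd = numeric(output))
  })
}

.as_input_cube <- function(x) {
  # accepts a coch_batch or a (tokens, time, filters) array; returns
  # list(cube = (F, N, T) array, n_valid)
  if (inherits(x, "coch_batch")) {
    list(cube = aperm(x$x, c(3, 1, 2)), n_valid = as.integer(x$n_valid))
  } else if (is.array(x) && length(dim(x)) == 3) {
    list(cube = aperm(x, c(3, 1, 2)), n_valid = rep(dim(x)[2], dim(x)[1]))
  } else stop("x must be a coch_batch or a (tokens, time, filters) array")
}

#' Fit a masked LSTM word-mapping network
#'
#' The model of the dual-stream experiments: a masking layer (padded
#' cochleagram frames clamp the recurrent state), a fully recurrent LSTM
#' hidden layer, and a dense sigmoid output layer read out at each token's
#' final valid frame. Trained by Adam on mean squared error. Training and
#' validation mean cosine similarity are checkpointed every
#' `checkpoint_interval` epochs, and the weights of the best validation
#' checkpoint are retained alongside the final weights.
#'
#' @param x Input batch: a `coch_batch` from [pad_batch()] or an array of
#'   dimension `(tokens, time, filters)`.
#' @param y Target matrix, one row per token.
#' @param hidden Number of LSTM units.
#' @param epochs Full passes over the training set.
#' @param batch_size Minibatch size.
#' @param lr Constant Adam learning rate.
#' @param checkpoint_interval Epochs between metric checkpoints (must
#'   divide `epochs`).
#' @param validation Integer indices of validation tokens (e.g. from
#'   [split_train_val()]); the rest are trained on. `NULL` trains on all.
#' @param seed Integer seed (weight initialization and batch shuffling).
#' @param keep_data Store the input batch in the fit (needed by
#'   [fitted.stream_net()] and [residuals.stream_net()]).
#' @param verbose Print checkpoint metrics.
#' @return An object of class `"stream_net"`: weights, `best_weights`,
#'   `best_epoch`, `history` (data frame: epoch, loss, train_cosine,
#'   val_cosine), `config`, index vectors, and (optionally) the data.
#' @export
stream_net <- function(x, y, hidden = 512, epochs = 10000, batch_size = 100,
                       lr = 1e-4, checkpoint_interval = 100,
                       validation = NULL, seed = 1, keep_data = TRUE,
                       verbose = FALSE) {
  inp <- .as_input_cube(x)
  y <- as.matrix(y)
  stopifnot(nrow(y) == dim(inp$cube)[2])
  if (epochs %% checkpoint_interval != 0)
    stop("checkpoint_interval must divide epochs")
  n <- nrow(y)
  val <- if (is.null(validation)) integer(0) else as.integer(validation)
  train <- setdiff(seq_len(n), val)
  W0 <- init_lstm_weights(dim(inp$cube)[1], hidden, ncol(y), seed)
  fit <- cpp_lstm_train(W0, inp$cube, inp$n_valid, t(y),
                        train - 1L, val - 1L,
                        as.integer(epochs), as.integer(batch_size), lr,
                        as.integer(checkpoint_interval), as.integer(seed),
                        verbose)
  hist <- as.data.frame(fit$history)
  names(hist) <- c("epoch", "loss", "train_cosine", "val_cosine")
  structure(list(weights = fit$weights, best_weights = fit$best_weights,
                 best_epoch = fit$best_epoch, history = hist,
                 config = list(input = dim(inp$cube)[1], hidden = hidden,
                               output = ncol(y), epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               checkpoint_interval = checkpoint_interval,
                               seed = seed),
                 train_idx = train, val_idx = val,
                 data = if (keep_data) list(x = x, y = y) else NULL,
                 call = match.call()),
            class = "stream_net")
}

#' Predict from a fitted stream network
#'
#' @param object A `stream_net`.
#' @param newdata A `coch_batch` or `(tokens, time, filters)` array;
#'   defaults to the stored training batch.
#' @param type `"response"` for the dense sigmoid output at each token's
#'   final valid frame; `"hidden"` for the full hidden-state trajectory
#'   (clamped over padded frames), an array `(tokens, time, hidden)`.
#' @param weights `"final"` or `"best"` (best validation checkpoint).
#' @param ... Unused.
#' @return A tokens x output matrix, or the hidden trajectory array.
#' @export
predict.stream_net <- function(object, newdata = NULL,
                               type = c("response", "hidden"),
                               weights = c("final", "best"), ...) {
  type <- match.arg(type)
  weights <- match.arg(weights)
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("no stored data; supply newdata")
    newdata <- object$data$x
  }
  inp <- .as_input_cube(newdata)
  if (any(inp$n_valid < 1)) stop("all-padded input token")
  W <- if (weights == "best") object$best_weights else object$weights
  out <- cpp_lstm_forward(W, inp$cube, inp$n_valid, type == "hidden")
  if (type == "response") t(out$prediction)
  else aperm(out$hidden, c(2, 3, 1))            # (tokens, time, hidden)
}

#' @export
fitted.stream_net <- function(object, ...) predict(object)

#' @export
residuals.stream_net <- function(object, ...) {
  if (is.null(object$data)) stop("no stored data")
  object$data$y - fitted(object)
}

#' @export
coef.stream_net <- function(object, ...) object$weights

#' @export
print.stream_net <- function(x, ...) {
  cfg <- x$config
  cat("Masked LSTM word-mapping network\n")
  cat(sprintf("  %d cochlear channels -> %d LSTM units -> %d sigmoid outputs\n",
              cfg$input, cfg$hidden, cfg$output))
  cat(sprintf("  %s parameters, %d epochs (lr %g, batch %d), seed %d\n",
              format(lstm_param_count(cfg$input, cfg$hidden, cfg$output),
                     big.mark = ","),
              cfg$epochs, cfg$lr, cfg$batch_size, cfg$seed))
  h <- tail(x$history, 1)
  if (nrow(h))
    cat(sprintf("  final: loss %.5f, train cosine %.3f, val cosine %.3f (best epoch %d)\n",
                h$loss, h$train_cosine, h$val_cosine, x$best_epoch))
  invisible(x)
}

#' @export
summary.stream_net <- function(object, ...) {
  print(object)
  cat("\nCheckpoint history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.stream_net <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_cosine, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "mean cosine similarity", ...)
  if (any(is.finite(h$val_cosine)))
    graphics::lines(h$epoch, h$val_cosine, lty = 2)
  graphics::legend("bottomright", legend = c("train", "validation"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a fitted network
#'
#' Round-trips through RDS with bit-identical weights, so reloaded models
#' give identical predictions.
#'
#' @param object A `stream_net`.
#' @param path File path.
#' @export
save_stream_net <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_stream_net
#' @export
load_stream_net <- function(path) readRDS(path)
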