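# Shared fixtures, built once per test run.
.fixtures <- new.env()

fix_inventory <- function() {
  if (is.null(.fixtures$inv)) .fixtures$inv <- phoneme_inventory()
  .fixtures$inv
}

fix_chart <- function() {
  if (is.null(.fixtures$chart)) .fixtures$chart <- feature_chart(fix_inventory())
  .fixtures$chart
}

fix_mini_lexicon <- function(seed = 1) {
  key <- paste0("lex", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_lexicon(fix_inventory(), n_roots = 24,
                                         n_one_affix = 22, n_two_affix = 2,
                                         seed = seed)
  .fixtures[[key]]
}

fix_filterbank <- function() {
  if (is.null(.fixtures$fb)) .fixtures$fb <- build_filterbank(20000)
  .fixtures$fb
}

fix_talkers <- function(n = 4, seed = 1) {
  generate_talkers(n, seed = seed)
}

# a tiny trained network on a synthetic separable task (fast, shared)
fix_toy_net <- function() {
  if (is.null(.fixtures$toy)) {
    set.seed(42)
    n_proto <- 8; T <- 20; F <- 12; O <- 40
    proto <- array(runif(n_proto * T * F, 0, 0.6), c(n_proto, T, F))
    wid <- rep(seq_len(n_proto), 3)
    x <- array(0, c(length(wid), T, F))
    for (i in seq_along(wid))
      x[i, , ] <- proto[wid[i], , ] + array(rnorm(T * F, 0, 0.02), c(T, F))
    y <- matrix(0, length(wid), O)
    for (i in seq_along(wid)) {
      set.seed(wid[i]); y[i, sample(O, 8)] <- 1
    }
    net <- stream_net(x, y, hidden = 16, epochs = 300, batch_size = 8,
                      lr = 1e-2, checkpoint_interval = 50, seed = 2)
    .fixtures$toy <- list(net = net, x = x, y = y, wid = wid,
                          proto = proto)
  }
  .fixtures$toy
}
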