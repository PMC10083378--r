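#' Study configuration profiles
#'
#' Bundles every tunable parameter of the pipeline. The `"paper"` profile
#' carries the full-scale settings (252 roots, 20 affixes, 10 talkers, 211
#' filters, 200 Hz envelope, 512 hidden units, 10,000 epochs, batch 100,
#' learning rate 1e-4, template thresholds 160/20). The `"mini"` profile
#' is a desk-scale configuration preserving the study's structure: 24
#' roots + 24 derived words (about 48 words, every affix attested), 4
#' talkers, 100 Hz envelope, 64 hidden units, 300 epochs; because a mini
#' run takes thousands of optimizer steps rather than the full schedule's
#' hundreds of thousands, it uses batch 4 and a 3e-3 Adam rate, calibrated
#' in pilot runs so the fixed epoch budget trains to convergence.
#'
#' @param profile `"mini"` or `"paper"`.
#' @param ... Named overrides of individual fields.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(profile = c("mini", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    n_roots = 252, n_one_affix = round(252 * 690 / 260),
    n_two_affix = round(252 * 50 / 260),
    min_len = 2, max_len = 10,
    n_talkers = 10,
    sample_rate = 20000, dur_range = c(300, 1200),
    n_bandpass = 203, f_min = 50, f_max = 8000, n_low = 4, n_high = 4,
    envelope_rate = 200, compression = 0.3, trim_cutoff_db = -20,
    s_max = 5,
    n_templates = 1400, pos_affinity = 0.25, zipf_exponent = 1.0,
    base_count = 3000, min_total = 40,
    min_words_per_template = 160, min_templates_per_word = 20,
    hidden = 512, epochs = 10000, batch_size = 100, lr = 1e-4,
    checkpoint_interval = 100,
    delta = 0.3, psi_window_ms = 100, time_stride = 1,
    embedding_dims = 50, n_iterations = 10)
  if (profile == "mini") {
    cfg[c("n_roots", "n_one_affix", "n_two_affix", "n_talkers",
          "envelope_rate", "hidden", "epochs", "batch_size", "lr",
          "checkpoint_interval", "n_templates", "min_words_per_template",
          "min_templates_per_word", "time_stride", "embedding_dims",
          "n_iterations", "base_count")] <-
      list(24, 22, 2, 4, 100, 64, 300, 4, 3e-3, 50, 60, 3, 3, 2, 16, 3, 800)
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

#' Run the full dual-stream study
#'
#' Executes the pipeline end to end for one iteration: corpus generation
#' (lexicon, talkers, audio, co-occurrence), cochleagram conversion,
#' target encoding, talker-holdout split, training of the dorsal, ventral
#' and fused networks on identical input, and the downstream analyses
#' (accuracy, onset/POS decoding by clustering with AMI, PSI/MSI
#' selectivity with cophenetic comparison to reference hierarchies, and
#' error characterization). Every stage derives its seed from `seed`.
#'
#' @param config A `study_config`.
#' @param seed Integer master seed for the iteration.
#' @param stages Character vector of analysis stages to run after
#'   training: any of `"evaluate"`, `"decode"`, `"selectivity"`,
#'   `"errors"`.
#' @param verbose Print progress.
#' @return An object of class `"stream_study"`; see [study_report()].
#' @export
run_study <- function(config = study_config("mini"), seed = 1,
                      stages = c("evaluate", "decode", "selectivity",
                                 "errors"),
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  inv <- phoneme_inventory()
  chart <- feature_chart(inv)
  affx <- affix_table()
  say("synth: lexicon, talkers, audio")
  lex <- generate_lexicon(inv, n_roots = config$n_roots, affixes = affx,
                          n_one_affix = config$n_one_affix,
                          n_two_affix = config$n_two_affix,
                          min_len = config$min_len, max_len = config$max_len,
                          seed = seed)
  talkers <- generate_talkers(config$n_talkers, seed = seed + 1L)
  fb <- build_filterbank(config$sample_rate, config$n_bandpass,
                         config$f_min, config$f_max, config$n_low,
                         config$n_high)
  tokens <- expand.grid(word = lex$id, talker = talkers$talker,
                        stringsAsFactors = FALSE)
  say("cochlea: ", nrow(tokens), " tokens")
  cgs <- vector("list", nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    tok <- synthesize_token(lex[tokens$word[i], ],
                            talkers[match(tokens$talker[i], talkers$talker), ],
                            sample_rate = config$sample_rate,
                            seed = seed + 2L, dur_range = config$dur_range,
                            inventory = inv)
    w <- trim_silence(tok$wave, config$trim_cutoff_db, config$sample_rate)
    cgs[[i]] <- compute_cochleagram(w, fb, config$envelope_rate,
                                    config$compression)
  }
  batch <- pad_batch(cgs)
  say("encode: targets")
  cooc <- generate_cooccurrence(lex, n_templates = config$n_templates,
                                pos_affinity = config$pos_affinity,
                                zipf_exponent = config$zipf_exponent,
                                base_count = config$base_count,
                                min_total = config$min_total,
                                seed = seed + 3L)
  tset <- build_template_set(cooc, config$min_words_per_template,
                             config$min_templates_per_word)
  if (length(tset$words_flagged)) {
    keep <- tokens$word %in% tset$words_kept
    tokens <- tokens[keep, , drop = FALSE]
    batch <- pad_batch(cgs[keep])
    lex <- lex[lex$id %in% tset$words_kept, , drop = FALSE]
  }
  targets <- list(
    dorsal = build_targets(lex, "dorsal", chart, s_max = config$s_max,
                           inventory = inv),
    ventral = build_targets(lex, "ventral", template_set = tset),
    fused = build_targets(lex, "fused", chart, tset, config$s_max, inv))
  ytok <- lapply(targets, function(m) m[tokens$word, , drop = FALSE])
  split <- split_train_val(tokens, seed = seed + 4L)
  nets <- list()
  for (nm in names(targets)) {
    say("train: ", nm, " network (", ncol(ytok[[nm]]), " outputs)")
    nets[[nm]] <- stream_net(batch, ytok[[nm]], hidden = config$hidden,
                             epochs = config$epochs,
                             batch_size = config$batch_size, lr = config$lr,
                             checkpoint_interval = config$checkpoint_interval,
                             validation = split$val, seed = seed + 5L,
                             verbose = verbose)
  }
  study <- list(config = config, seed = seed, lexicon = lex,
                talkers = talkers, tokens = tokens, filterbank = fb,
                batch = batch, cooc = cooc, template_set = tset,
                targets = targets, split = split, networks = nets)
  if ("evaluate" %in% stages) {
    say("evaluate")
    study$accuracy <- lapply(names(nets), function(nm)
      accuracy_report(nets[[nm]], tokens$word, targets[[nm]]))
    names(study$accuracy) <- names(nets)
  }
  if ("decode" %in% stages) {
    say("decode")
    lab7 <- lex[tokens$word, "onset_class"]
    lab9 <- lex[tokens$word, "pos9"]
    # decoding probes the trained model of the iteration (final weights);
    # only the selectivity analysis selects the best validation epoch
    study$decoding <- do.call(rbind, lapply(names(nets), function(nm) {
      f7 <- build_feature_matrix(nets[[nm]], lab7,
                                 time_stride = config$time_stride,
                                 weights = "final")
      f9 <- build_feature_matrix(nets[[nm]], lab9,
                                 time_stride = config$time_stride,
                                 weights = "final")
      data.frame(network = nm,
                 task = c("onset7", "pos9"),
                 k = c(length(unique(lab7)), length(unique(lab9))),
                 ami = c(cluster_and_score(f7)$ami,
                         cluster_and_score(f9)$ami))
    }))
  }
  if ("selectivity" %in% stages) {
    say("selectivity")
    dip <- make_diphones(inv, talkers, fb, config$envelope_rate,
                         config$compression, seed = seed + 6L)
    refs <- reference_trees(inv, affx)
    study$selectivity <- list(diphone_meta = dip$meta, reference = refs)
    for (nm in names(nets)) {
      psi <- psi_matrix(nets[[nm]], dip, config$psi_window_ms, config$delta)
      msi <- msi_matrix(nets[[nm]], tokens$word, lex, affixes = affx,
                        delta = config$delta)
      study$selectivity[[nm]] <- list(
        psi = psi, msi = msi,
        psi_cophenetic = cophenetic_r(cluster_items(psi), refs$phoneme),
        msi_cophenetic = cophenetic_r(cluster_items(msi), refs$morpheme))
    }
  }
  if ("errors" %in% stages) {
    say("errors")
    emb <- build_embeddings(cooc, dims = config$embedding_dims)
    emb <- emb[rownames(emb) %in% lex$id, , drop = FALSE]
    study$embeddings <- emb
    study$errors <- lapply(names(nets), function(nm)
      error_profile(nets[[nm]], tokens$word, lex, targets[[nm]], emb))
    names(study$errors) <- names(nets)
  }
  structure(study, class = "stream_study")
}

#' Summarize a study into the report tables
#'
#' @param study A `stream_study` from [run_study()].
#' @return A list: `accuracy` (per network: train/validation/combined mean
#'   cosine and identification counts), `decoding` (network x task AMI),
#'   `selectivity` (cophenetic correlations to the reference hierarchies),
#'   `errors` (mean phonological/semantic similarity per network), and
#'   `dissociation` (`"supported"`/`"not supported"`, from the AMI
#'   ordering).
#' @export
study_report <- function(study) {
  out <- list(profile = study$config$profile, seed = study$seed,
              n_words = nrow(study$lexicon),
              n_tokens = nrow(study$tokens))
  if (!is.null(study$accuracy))
    out$accuracy <- do.call(rbind, lapply(names(study$accuracy), function(nm)
      cbind(network = nm, study$accuracy[[nm]]$summary)))
  if (!is.null(study$decoding)) {
    out$decoding <- study$decoding
    am <- function(net, task)
      study$decoding$ami[study$decoding$network == net &
                         study$decoding$task == task]
    out$dissociation <- if (am("dorsal", "onset7") > am("ventral", "onset7") &&
                            am("ventral", "pos9") > am("dorsal", "pos9"))
      "supported" else "not supported"
  }
  if (!is.null(study$selectivity)) {
    nets <- intersect(names(study$networks), names(study$selectivity))
    out$selectivity <- data.frame(
      network = nets,
      psi_cophenetic = vapply(nets, function(nm)
        study$selectivity[[nm]]$psi_cophenetic, 1.0),
      msi_cophenetic = vapply(nets, function(nm)
        study$selectivity[[nm]]$msi_cophenetic, 1.0))
  }
  if (!is.null(study$errors))
    out$errors <- data.frame(
      network = names(study$errors),
      n_errors = vapply(study$errors, `[[`, 1L, "n_errors"),
      mean_phon_sim = vapply(study$errors, `[[`, 1.0, "mean_phon_sim"),
      mean_sem_sim = vapply(study$errors, `[[`, 1.0, "mean_sem_sim"))
  out
}

#' @export
print.stream_study <- function(x, ...) {
  rep_ <- study_report(x)
  cat(sprintf("Dual-stream study (%s profile, seed %d): %d words, %d tokens\n",
              rep_$profile, rep_$seed, rep_$n_words, rep_$n_tokens))
  if (!is.null(rep_$accuracy)) {
    cat("\nIdentification accuracy:\n")
    print(rep_$accuracy, row.names = FALSE)
  }
  if (!is.null(rep_$decoding)) {
    cat("\nDecoding (AMI):\n")
    print(rep_$decoding, row.names = FALSE)
    cat("Double dissociation:", rep_$dissociation, "\n")
  }
  if (!is.null(rep_$selectivity)) {
    cat("\nSelectivity (cophenetic r to reference hierarchies):\n")
    print(rep_$selectivity, row.names = FALSE)
  }
  if (!is.null(rep_$errors)) {
    cat("\nError profile:\n")
    print(rep_$errors, row.names = FALSE)
  }
  invisible(x)
}
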