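#' Generator hyperparameters
#'
#' Desk-scale defaults: 2 LSTM layers of 256 hidden units, Adam with learning
#' rate 5e-3, minibatches of 16 sequences.  All are configuration, not
#' constants of the method.
#'
#' @param layers Number of stacked LSTM layers.
#' @param hidden Hidden units per layer.
#' @param lr Adam learning rate for pretraining.
#' @param batch_size Sequences per minibatch.
#' @param max_length Sampling length cap (tokens).
#' @param validation_fraction Held-out fraction for the per-epoch validation
#'   loss during pretraining.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(layers = 2L, hidden = 256L, lr = 5e-3,
                             batch_size = 16L, max_length = 100L,
                             validation_fraction = 0.1) {
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 lr = lr, batch_size = as.integer(batch_size),
                 max_length = as.integer(max_length),
                 validation_fraction = validation_fraction),
            class = "generator_config")
}

#' Pretrain the SMILES language model
#'
#' Trains a character-level LSTM to model a corpus of (canonical) SMILES by
#' next-token prediction, the pretraining stage of transfer-learning de novo
#' design.  A held-out split tracks generalisation per epoch.
#'
#' @param corpus Character vector of canonical SMILES (>= 10).
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialisation, the train/validation
#'   split and minibatch shuffling.
#' @param config A [generator_config()].
#' @return A `generator_model`: list with `vocab`, `params`, `config`,
#'   `history` (tibble `epoch`, `train_loss`, `val_loss`), `corpus_size`.
#' @export
pretrain <- function(corpus, epochs = 20L, seed = 1L,
                     config = generator_config()) {
  stopifnot(length(corpus) >= 10, epochs >= 1)
  set.seed(seed)
  vocab <- build_vocabulary(corpus)
  seqs <- encode_smiles(vocab, corpus)
  n_val <- max(1L, floor(config$validation_fraction * length(seqs)))
  val_idx <- sample(length(seqs), n_val)
  train <- seqs[-val_idx]
  val <- seqs[val_idx]
  params <- lstm_init(length(vocab$tokens), hidden = config$hidden,
                      layers = config$layers)
  state <- adam_init(params)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    res <- lstm_epoch(params, state, train, vocab$pad, config$batch_size,
                      config$lr)
    params <- res$params; state <- res$state
    vl <- lstm_nll(params, val, vocab$pad)
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = res$loss,
                                    val_loss = vl)
  }
  model <- list(vocab = vocab, params = params, config = config,
                history = do.call(rbind, history),
                corpus_size = length(corpus))
  class(model) <- "generator_model"
  model
}

#' @export
print.generator_model <- function(x, ...) {
  cat("<generator_model: ", x$params$n_layers, "x", x$params$hidden,
      " LSTM, vocab ", length(x$vocab$tokens), ", ",
      nrow(x$history), " pretraining epochs",
      if (!is.null(x$finetune_history)) paste0(" + ", nrow(x$finetune_history),
                                               " fine-tuning epochs"),
      ">\n", sep = "")
  invisible(x)
}

#' Fine-tune the model on a focused set (transfer learning)
#'
#' Continues training on a small set of template actives to bias sampling
#' toward their chemotype.  With `epochs = 0` the model is returned unchanged.
#'
#' @param model A [pretrain()] result.
#' @param focused Character vector of SMILES; every token must be covered by
#'   the model vocabulary.
#' @param epochs Fine-tuning epochs.
#' @param seed Integer seed.
#' @param lr Learning rate (default one third of the pretraining rate; the
#'   focused set is small and easily overfit past the point of invalid
#'   syntax).
#' @return The updated `generator_model`, with `finetune_history` (tibble
#'   `epoch`, `train_loss`, `focused_ll`) recording the mean per-token
#'   log-likelihood of the focused set before and after each epoch.
#' @export
fine_tune <- function(model, focused, epochs = 10L, seed = 1L,
                      lr = model$config$lr / 3) {
  stopifnot(inherits(model, "generator_model"), length(focused) >= 1,
            epochs >= 0)
  seqs <- encode_smiles(model$vocab, focused)
  if (epochs == 0) return(model)
  set.seed(seed)
  params <- model$params
  state <- adam_init(params)
  ll0 <- -lstm_nll(params, seqs, model$vocab$pad)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    res <- lstm_epoch(params, state, seqs, model$vocab$pad,
                      min(model$config$batch_size, length(seqs)), lr)
    params <- res$params; state <- res$state
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = res$loss,
                                    focused_ll = -lstm_nll(params, seqs,
                                                           model$vocab$pad))
  }
  model$params <- params
  model$finetune_history <- do.call(rbind, history)
  model$focused_ll_before <- ll0
  model$focused_ll_after <- history[[epochs]]$focused_ll
  model
}

#' Mean per-token log-likelihood of SMILES under the model
#'
#' @param model A `generator_model`.
#' @param smiles Character vector.
#' @return A single number (natural-log units per token).
#' @export
log_likelihood <- function(model, smiles) {
  -lstm_nll(model$params, encode_smiles(model$vocab, smiles), model$vocab$pad)
}

#' Sample SMILES strings from the model
#'
#' Ancestral sampling with a temperature-scaled softmax.  Returns exactly `n`
#' strings; syntactic validity is assessed downstream by
#' [evaluate_generation()], not here.
#'
#' @param model A `generator_model`.
#' @param n Number of samples.
#' @param temperature Softmax temperature (> 0); low values approach greedy
#'   argmax decoding.
#' @param seed Integer seed; a fixed seed reproduces the sample list exactly.
#' @param max_length Token cap per sample (default from the model config).
#' @return Character vector of length `n`.
#' @export
sample_smiles <- function(model, n, temperature = 1.0, seed = 1L,
                          max_length = model$config$max_length) {
  stopifnot(inherits(model, "generator_model"), n >= 1, temperature > 0)
  set.seed(seed)
  ids <- lstm_sample_ids(model$params, n, temperature, max_length,
                         model$vocab$begin, model$vocab$end, model$vocab$pad)
  decode_smiles(model$vocab, lapply(seq_len(n), function(j) ids[, j]))
}

#' Save / load a generator model
#'
#' The checkpoint is a single-file archive holding the vocabulary, weights,
#' configuration and training history, plus a checksum of the weights; a
#' reloaded model produces bit-identical samples under the same seed.
#'
#' @param model A `generator_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `generator_model` (load).
#' @export
save_generator <- function(model, path) {
  model$weights_hash <- digest_params(model$params)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "generator_model")) stop("not a generator checkpoint")
  if (!identical(model$weights_hash, digest_params(model$params))) {
    stop("checkpoint weight hash mismatch: file corrupted")
  }
  model
}

digest_params <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  leaves <- param_leaves(params)
  writeBin(unlist(lapply(leaves, as.numeric)), f)
  unname(tools::md5sum(f))
}
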