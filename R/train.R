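# Training loops: language-model pretraining over a BPTT token stream,
# optional task-corpus LM fine-tuning with discriminative rates, and the
# staged QSAR fine-tune with gradual unfreezing.

#' Build the language-model token stream from a corpus
#'
#' Tokenizes and numericalizes every SMILES and concatenates the results
#' into one contiguous zero-based index stream, each molecule wrapped in
#' `<bos>`/`<eos>` delimiters by default.
#'
#' @param smiles Character vector of SMILES strings.
#' @param vocab A `smiles_vocab`.
#' @param add_bos_eos Wrap each SMILES with delimiters?
#' @return Integer vector of zero-based token indices.
#' @export
lm_stream <- function(smiles, vocab, add_bos_eos = TRUE) {
  unlist(lapply(smiles, function(s) {
    numericalize(tokenize_smiles(s), vocab, add_bos_eos = add_bos_eos)$indices
  }), use.names = FALSE)
}

# Arrange a stream into a batch-major matrix: B parallel substreams of
# equal length (trailing remainder dropped, as is conventional for BPTT).
stream_batches <- function(stream, batch_size) {
  n_per <- length(stream) %/% batch_size
  if (n_per < 2L) {
    stop("stream too short for the requested batch size", call. = FALSE)
  }
  matrix(stream[seq_len(n_per * batch_size)], nrow = n_per, ncol = batch_size)
}

# Per-parameter learning rates for one optimizer step: the discriminative
# ladder scaled by the relative one-cycle factor.
step_lrs <- function(groups, disc, cyc_factor) {
  lrs <- list()
  for (gi in seq_along(groups)) {
    for (nm in groups[[gi]]) lrs[[nm]] <- disc[gi] * cyc_factor
  }
  lrs
}

# Shared LM optimization loop. `disc` is the bottom-to-top discriminative
# ladder (a constant vector for plain pretraining); `trainable` names the
# updatable parameters.
lm_fit <- function(model, stream, epochs, bptt, batch_size, disc,
                   trainable, one_cycle = TRUE, pct_start = 0.3,
                   div_factor = 25, final_div = 1e4, clip = 0.4, wd = 0.01,
                   ar_alpha = 2, tar_beta = 1, seed = 0L,
                   log_file = NULL) {
  groups <- layer_groups(model)
  M <- stream_batches(stream, batch_size)
  n_per <- nrow(M)
  windows <- ceiling((n_per - 1L) / bptt)
  params <- model$params
  epoch_loss <- numeric(epochs)
  lr_log <- numeric(0)
  lr_max_top <- disc[length(disc)]
  opt <- NULL
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      spec <- one_cycle_spec(lr_max_top, total_steps = windows,
                             pct_start = pct_start, div_factor = div_factor,
                             final_div = final_div)
      if (is.null(opt)) opt <- adam_init(params)
      state <- NULL
      tot_loss <- 0
      tot_tok <- 0
      step <- 0L
      for (w in seq_len(windows)) {
        t0 <- (w - 1L) * bptt + 1L
        t1 <- min(t0 + bptt - 1L, n_per - 1L)
        ids <- M[t0:t1, , drop = FALSE]     # T x B: rows are timesteps
        targets <- M[(t0 + 1L):(t1 + 1L), , drop = FALSE]
        model_tmp <- model
        model_tmp$params <- params
        res <- mspm_forward_backward(model_tmp, ids, targets, state = state,
                                     train = TRUE, ar_alpha = ar_alpha,
                                     tar_beta = tar_beta)
        state <- res$state  # carried across windows, gradients truncated
        cyc <- if (one_cycle) one_cycle_lr(step, spec) / lr_max_top else 1
        mom <- if (one_cycle) one_cycle_mom(step, spec) else 0.9
        lrs <- step_lrs(groups, disc, cyc)
        lr_log <- c(lr_log, disc[length(disc)] * cyc)
        params <- adam_step(params, res$grads, opt, lrs, trainable,
                            beta1 = mom, clip = clip, wd = wd)
        step <- step + 1L
        ntok <- length(ids)
        tot_loss <- tot_loss + res$loss * ntok
        tot_tok <- tot_tok + ntok
      }
      epoch_loss[ep] <- tot_loss / tot_tok
      if (!is.null(log_file)) {
        log_jsonl(log_file, list(phase = "lm", epoch = ep,
                                 loss = epoch_loss[ep]))
      }
    }
  })
  model$params <- params
  list(model = model, loss_log = epoch_loss, lr_log = lr_log)
}

#' Pretrain the SMILES language model
#'
#' Minimizes next-token cross-entropy over contiguous backpropagation-
#' through-time windows of the concatenated, delimiter-joined corpus
#' stream. Each epoch runs one cycle of the one-cycle policy at the same
#' peak rate (set `one_cycle = FALSE` for a strictly constant rate).
#'
#' @param model An `mft_model` of kind `"mspm"`.
#' @param stream Zero-based token stream from [lm_stream()].
#' @param epochs Training epochs (default 10).
#' @param bptt Backpropagation-through-time window length (default 70).
#' @param batch_size Number of parallel substreams (default 32).
#' @param lr_max Peak learning rate.
#' @param one_cycle Use the one-cycle schedule within each epoch?
#' @param clip Global gradient-norm clip (0 or `NULL` disables).
#' @param seed Integer RNG seed (dropout masks, scheduling reproducible).
#' @param log_file Optional JSONL log path.
#' @return List with `model`, per-epoch `loss_log` (nats/token) and the
#'   per-step `lr_log`.
#' @export
train_mspm <- function(model, stream, epochs = 10L, bptt = 70L,
                       batch_size = 32L, lr_max = 3e-3, one_cycle = TRUE,
                       clip = 0.4, wd = 0.01, ar_alpha = 2, tar_beta = 1,
                       seed = 0L, log_file = NULL) {
  stopifnot(inherits(model, "mft_model"), model$kind == "mspm")
  if (length(stream) == 0L) stop("empty corpus stream", call. = FALSE)
  groups <- layer_groups(model)
  disc <- rep(lr_max, length(groups))  # no discriminative scaling here
  lm_fit(model, stream, epochs, bptt, batch_size, disc,
         trainable = unlist(groups), one_cycle = one_cycle, clip = clip,
         wd = wd, ar_alpha = ar_alpha, tar_beta = tar_beta,
         seed = seed, log_file = log_file)
}

#' Fine-tune the general language model on a task corpus
#'
#' Optional stage: adapts the pretrained language model to the target
#' dataset's chemical space using the one-cycle policy and discriminative
#' fine-tuning (rate ratio `decay` between adjacent layer groups, top group
#' at `base_lr`). Skipping this stage and fine-tuning the QSAR model
#' directly from the general model is a fully supported path.
#'
#' @param model Pretrained `mft_model` of kind `"mspm"` (vocabulary already
#'   aligned, e.g. via [transfer_encoder()]).
#' @param stream Task-corpus token stream.
#' @param epochs Fine-tuning epochs.
#' @param base_lr Learning rate of the top group.
#' @param decay Discriminative decay (default 2.6).
#' @inheritParams train_mspm
#' @return List with `model`, `loss_log`, `lr_log`.
#' @export
finetune_task_mspm <- function(model, stream, epochs = 4L, base_lr = 3e-3,
                               decay = 2.6, bptt = 70L, batch_size = 32L,
                               clip = 0.4, wd = 0.01, ar_alpha = 2,
                               tar_beta = 1, seed = 0L, log_file = NULL) {
  stopifnot(inherits(model, "mft_model"), model$kind == "mspm")
  if (length(stream) == 0L) stop("empty corpus stream", call. = FALSE)
  groups <- layer_groups(model)
  disc <- discriminative_lrs(base_lr, length(groups), decay)
  lm_fit(model, stream, epochs, bptt, batch_size, disc,
         trainable = unlist(groups), seed = seed, clip = clip, wd = wd,
         ar_alpha = ar_alpha, tar_beta = tar_beta, log_file = log_file)
}

#' Held-out language-model loss (nats per token)
#'
#' Evaluates next-token cross-entropy of a language model over a stream in
#' eval mode (dropout off, deterministic).
#'
#' @param model An `mft_model` of kind `"mspm"`.
#' @param stream Zero-based token stream.
#' @param bptt,batch_size Evaluation window shape.
#' @return Mean cross-entropy in nats/token.
#' @export
evaluate_mspm <- function(model, stream, bptt = 70L, batch_size = 16L) {
  stopifnot(model$kind == "mspm")
  bs <- min(batch_size, max(1L, length(stream) %/% 2L))
  M <- stream_batches(stream, bs)
  n_per <- nrow(M)
  state <- NULL
  tot <- 0; ntok <- 0
  for (t0 in seq(1L, n_per - 1L, by = bptt)) {
    t1 <- min(t0 + bptt - 1L, n_per - 1L)
    ids <- M[t0:t1, , drop = FALSE]
    targets <- M[(t0 + 1L):(t1 + 1L), , drop = FALSE]
    res <- mspm_forward_backward(model, ids, targets, state = state,
                                 train = FALSE, compute_grads = FALSE)
    state <- res$state
    tot <- tot + res$loss * length(ids)
    ntok <- ntok + length(ids)
  }
  tot / ntok
}

# Numericalize a set of SMILES into a right-padded T x B id matrix.
pad_batch <- function(seqs) {
  TT <- max(lengths(seqs))
  B <- length(seqs)
  ids <- matrix(PAD_INDEX, TT, B)
  for (b in seq_len(B)) ids[seq_along(seqs[[b]]), b] <- seqs[[b]]
  ids
}

numericalize_set <- function(smiles, vocab, add_bos_eos = TRUE) {
  lapply(smiles, function(s) {
    numericalize(tokenize_smiles(s), vocab, add_bos_eos = add_bos_eos)$indices
  })
}

#' Fine-tune a QSAR/QSPR model with gradual unfreezing
#'
#' Executes the stages of `plan` in order. Within each stage only the
#' stage's unfrozen top layer groups receive optimizer updates; rates
#' follow the one-cycle policy scaled by the discriminative ladder
#' (`plan$lr_decay_factor` between adjacent groups). Loss is mean squared
#' error for regression (labels standardized internally; predictions are
#' returned on the original scale) and cross-entropy for classification.
#'
#' @param model An `mft_model` of kind `"qsar"` (pretrained encoder
#'   transferred via [transfer_encoder()], or freshly initialized for
#'   from-scratch training).
#' @param dataset Molecule-record data.frame; training inputs are the
#'   `raw_smiles` (augmented variants train on their own renderings).
#' @param plan A [stage_plan()]; its final stage must unfreeze all groups
#'   unless `allow_partial = TRUE`.
#' @param task `"regression"` or `"classification"`.
#' @param vocab Vocabulary; defaults to the one stored in the model.
#' @param batch_size Minibatch size (128 by convention; use 64 for very
#'   large sets).
#' @param clip Global gradient-norm clip.
#' @param seed Integer RNG seed.
#' @param allow_partial Permit a plan that never unfreezes every group.
#' @param log_file Optional JSONL log path.
#' @return List with `model`, `loss_log` (stage x epoch data.frame) and
#'   `lr_log` (per-step data.frame: stage, step, lr per group).
#' @export
finetune_qsar <- function(model, dataset, plan, task = c("regression",
                                                         "classification"),
                          vocab = model$vocab, batch_size = 128L,
                          clip = 0.4, wd = 0.01, seed = 0L,
                          allow_partial = FALSE, log_file = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(model, "mft_model"), model$kind == "qsar",
            inherits(plan, "stage_plan"))
  groups <- layer_groups(model)
  n_groups <- length(groups)
  stages <- plan$stages
  if (any(stages$unfrozen_groups > n_groups)) {
    stop("plan unfreezes more groups than the model has", call. = FALSE)
  }
  if (!allow_partial && stages$unfrozen_groups[nrow(stages)] != n_groups) {
    stop("final stage must unfreeze all layer groups", call. = FALSE)
  }
  labels <- if (task == "regression") dataset$label else dataset$class_id
  if (anyNA(labels)) stop("dataset labels are incomplete", call. = FALSE)
  if (task == "regression") {
    mu <- mean(labels); sdev <- stats::sd(labels)
    if (!is.finite(sdev) || sdev == 0) sdev <- 1
    model$norm <- list(mean = mu, sd = sdev)
    labels <- (labels - mu) / sdev
  } else {
    model$norm <- NULL
    if (max(labels) + 1L > model$head$output_dim) {
      stop("class id exceeds the model's output dimension", call. = FALSE)
    }
  }
  seqs <- numericalize_set(dataset$raw_smiles, vocab)
  n <- length(seqs)
  params <- model$params
  bnstate <- model$bn
  loss_rows <- list()
  lr_rows <- list()
  with_seed(seed, {
    for (si in seq_len(nrow(stages))) {
      k <- stages$unfrozen_groups[si]
      base_lr <- stages$base_lr[si]
      epochs <- stages$epochs[si]
      disc_all <- numeric(n_groups)
      active <- (n_groups - k + 1L):n_groups
      disc_all[active] <- discriminative_lrs(base_lr, k, plan$lr_decay_factor)
      trainable <- unlist(groups[active])
      steps_per_epoch <- ceiling(n / batch_size)
      spec <- one_cycle_spec(base_lr, total_steps = epochs * steps_per_epoch)
      opt <- adam_init(params)
      step <- 0L
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0; ep_n <- 0
        for (b0 in seq(1L, n, by = batch_size)) {
          sel <- ord[b0:min(b0 + batch_size - 1L, n)]
          ids <- pad_batch(seqs[sel])
          model_tmp <- model
          model_tmp$params <- params
          model_tmp$bn <- bnstate
          res <- qsar_forward_backward(model_tmp, ids, labels = labels[sel],
                                       train = TRUE, task = task)
          bnstate <- res$bn
          cyc <- one_cycle_lr(step, spec) / base_lr
          mom <- one_cycle_mom(step, spec)
          lrs <- step_lrs(groups, disc_all, cyc)
          lr_rows[[length(lr_rows) + 1L]] <-
            c(stage = si, step = step, disc_all * cyc)
          params <- adam_step(params, res$grads, opt, lrs, trainable,
                              beta1 = mom, clip = clip, wd = wd)
          step <- step + 1L
          ep_loss <- ep_loss + res$loss * length(sel)
          ep_n <- ep_n + length(sel)
        }
        loss_rows[[length(loss_rows) + 1L]] <-
          data.frame(stage = si, epoch = ep, loss = ep_loss / ep_n)
        if (!is.null(log_file)) {
          log_jsonl(log_file, list(phase = "qsar", stage = si, epoch = ep,
                                   loss = ep_loss / ep_n))
        }
      }
    }
  })
  model$params <- params
  model$bn <- bnstate
  lr_log <- as.data.frame(do.call(rbind, lr_rows))
  names(lr_log) <- c("stage", "step", paste0("group", seq_len(n_groups)))
  list(model = model, loss_log = do.call(rbind, loss_rows), lr_log = lr_log)
}

#' Predict with a fine-tuned QSAR model
#'
#' Eval-mode forward pass (no dropout; deterministic). Regression
#' predictions are returned on the original label scale; classification
#' returns a matrix of class probabilities.
#'
#' @param model Trained `mft_model` of kind `"qsar"`.
#' @param smiles Character vector of SMILES.
#' @param task `"regression"` or `"classification"`.
#' @param vocab Vocabulary; defaults to the model's.
#' @param batch_size Inference batch size.
#' @return Numeric vector (regression) or `n x classes` probability matrix.
#' @export
predict_qsar <- function(model, smiles, task = c("regression",
                                                 "classification"),
                         vocab = model$vocab, batch_size = 64L) {
  task <- match.arg(task)
  stopifnot(model$kind == "qsar")
  seqs <- numericalize_set(smiles, vocab)
  n <- length(seqs)
  out <- vector("list", ceiling(n / batch_size))
  j <- 0L
  for (b0 in seq(1L, n, by = batch_size)) {
    sel <- b0:min(b0 + batch_size - 1L, n)
    ids <- pad_batch(seqs[sel])
    res <- qsar_forward_backward(model, ids, train = FALSE, task = task)
    j <- j + 1L
    out[[j]] <- res$pred
  }
  if (task == "regression") {
    pred <- unlist(out)
    if (!is.null(model$norm)) pred <- pred * model$norm$sd + model$norm$mean
    pred
  } else {
    do.call(rbind, out)
  }
}

# Append one JSON line to a structured log.
log_jsonl <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
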