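# Paired transfer-learning experiment on synthetic data: for each seed,
# fine-tune a QSAR model from a pretrained language model and train an
# identically configured, identically initialized model from scratch, with
# shared splits and stage plan, and compare validation error.

#' Tiny encoder configuration for desk-scale experiments
#'
#' A 32-wide embedding, 64 hidden units, three LSTM layers and lightly
#' scaled dropouts: large enough to learn SMILES statistics on synthetic
#' corpora, small enough to train in seconds on a CPU.
#'
#' @param dropout_mult Multiplier on the standard dropout family.
#' @return An [encoder_config()].
#' @export
tiny_encoder_config <- function(dropout_mult = 0.25) {
  encoder_config(embedding_dim = 32L, hidden_dim = 64L, n_layers = 3L,
                 dropout_mult = dropout_mult)
}

#' Paired pretrained-vs-scratch transfer benchmark on synthetic data
#'
#' Generates a synthetic pretraining corpus and a disjoint labelled task
#' dataset (canonical-SMILES set difference enforced, so pretraining can
#' never leak task molecules). For every seed and training-set size: (i)
#' pretrain a tiny language model, transfer its encoder into a QSAR model
#' and fine-tune on the task training set; (ii) fine-tune an identically
#' initialized QSAR model from scratch. Both arms share the seed's split,
#' architecture and stage plan; the recorded metric is validation RMSE
#' (regression) or AUROC (classification) on canonical SMILES.
#'
#' @param pretrain_n Pretraining corpus size (distinct molecules).
#' @param task_n Vector of task training-set sizes.
#' @param seeds Integer vector of paired-experiment seeds.
#' @param task `"regression"` or `"classification"`.
#' @param enc Encoder configuration shared by both arms.
#' @param plan Stage plan shared by both arms.
#' @param n_valid Validation-set size.
#' @param pretrain_epochs,bptt,lm_batch_size,lm_lr Language-model
#'   pretraining settings.
#' @param batch_size QSAR fine-tuning batch size.
#' @param base_seed Seed for corpus and dataset generation (kept separate
#'   from the per-arm training seeds).
#' @param share_pretrained Pretrain one language model (seeded by
#'   `base_seed`) and reuse it across all seeds instead of pretraining per
#'   seed. The paired arms still vary by seed (splits, initialization,
#'   batching); sharing only removes redundant language-model runs, at the
#'   price of not sampling language-model initialization variance.
#' @param progress Print one line per completed arm?
#' @return A data.frame with one row per (seed, task_n, arm) and the
#'   summary attribute `"summary"` (per-task_n means and pretrained-arm win
#'   counts).
#' @export
transfer_benchmark <- function(pretrain_n = 20000L, task_n = c(100L, 500L),
                               seeds = 1:10,
                               task = c("regression", "classification"),
                               enc = tiny_encoder_config(),
                               plan = desk_stage_plan(),
                               n_valid = 200L,
                               pretrain_epochs = 8L, bptt = 70L,
                               lm_batch_size = 128L, lm_lr = 3e-3,
                               batch_size = 32L, base_seed = 20L,
                               share_pretrained = FALSE,
                               progress = FALSE) {
  task <- match.arg(task)
  corpus <- generate_corpus(synth_spec(n_molecules = pretrain_n,
                                       seed = base_seed))
  pool_n <- max(task_n) + n_valid
  task_spec <- synth_spec(n_molecules = ceiling(pool_n * 1.5) + 50L,
                          seed = base_seed + 1L)
  pool <- if (task == "regression") {
    generate_regression_dataset(task_spec)
  } else {
    generate_classification_dataset(task_spec)
  }
  pool <- pool[!(pool$canonical_smiles %in% corpus$canonical_smiles), ,
               drop = FALSE]
  if (nrow(pool) < pool_n) {
    stop("generation error: task pool too small after enforcing ",
         "disjointness from the pretraining corpus", call. = FALSE)
  }
  pool <- pool[seq_len(pool_n), , drop = FALSE]
  valid_idx <- (pool_n - n_valid + 1L):pool_n
  valid <- pool[valid_idx, , drop = FALSE]
  train_pool <- pool[-valid_idx, , drop = FALSE]

  vocab <- build_vocab(lapply(c(corpus$canonical_smiles,
                                pool$canonical_smiles), tokenize_smiles))
  stream <- lm_stream(corpus$canonical_smiles, vocab)

  rows <- list()
  shared_lm <- if (share_pretrained) {
    lm <- build_mspm(vocab, config = enc, seed = base_seed)
    train_mspm(lm, stream, epochs = pretrain_epochs, bptt = bptt,
               batch_size = lm_batch_size, lr_max = lm_lr, seed = base_seed)
  }
  for (seed in seeds) {
    lm_fit_res <- if (share_pretrained) {
      shared_lm
    } else {
      lm <- build_mspm(vocab, config = enc, seed = seed)
      train_mspm(lm, stream, epochs = pretrain_epochs,
                 bptt = bptt, batch_size = lm_batch_size,
                 lr_max = lm_lr, seed = seed)
    }
    for (nt in task_n) {
      sel <- with_seed(seed + 7919L * nt, sample.int(nrow(train_pool), nt))
      train <- train_pool[sel, , drop = FALSE]
      for (arm in c("pretrained", "scratch")) {
        qsar <- build_qsar(vocab, enc = enc,
                           head = classifier_config(
                             output_dim = if (task == "regression") 1L else 2L),
                           seed = seed)
        if (arm == "pretrained") {
          qsar <- transfer_encoder(lm_fit_res$model, qsar,
                                   source_vocab = vocab,
                                   target_vocab = vocab)
        }
        fit <- finetune_qsar(qsar, train, plan, task = task, vocab = vocab,
                             batch_size = batch_size, seed = seed)
        pred <- predict_qsar(fit$model, valid$canonical_smiles, task = task)
        value <- if (task == "regression") {
          rmse(valid$label, pred)
        } else {
          auroc(valid$class_id, pred[, 2L])
        }
        rows[[length(rows) + 1L]] <-
          data.frame(seed = seed, task_n = nt, arm = arm,
                     metric = if (task == "regression") "RMSE" else "AUROC",
                     value = value)
        if (progress) {
          message(sprintf("seed %d n %d %s: %.4f", seed, nt, arm, value))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- summarize_transfer_benchmark(out)
  out
}

#' Summarize a paired transfer benchmark
#'
#' @param results Data.frame from [transfer_benchmark()].
#' @return Data.frame per task size: mean metric of each arm, number of
#'   seeds where the pretrained arm is at least as good as scratch, and the
#'   seed count. "At least as good" means lower-or-equal RMSE, or
#'   higher-or-equal AUROC.
#' @export
summarize_transfer_benchmark <- function(results) {
  higher_better <- results$metric[1] == "AUROC"
  out <- lapply(split(results, results$task_n), function(df) {
    wide <- merge(df[df$arm == "pretrained", c("seed", "value")],
                  df[df$arm == "scratch", c("seed", "value")],
                  by = "seed", suffixes = c("_pretrained", "_scratch"))
    wins <- if (higher_better) {
      sum(wide$value_pretrained >= wide$value_scratch)
    } else {
      sum(wide$value_pretrained <= wide$value_scratch)
    }
    data.frame(task_n = df$task_n[1],
               mean_pretrained = mean(wide$value_pretrained),
               mean_scratch = mean(wide$value_scratch),
               wins_pretrained = wins,
               n_seeds = nrow(wide))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
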