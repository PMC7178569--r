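test_that("one-cycle schedule hits its endpoints and rejects out-of-range steps", {
  spec <- one_cycle_spec(lr_max = 0.01, total_steps = 100L)
  expect_equal(one_cycle_lr(0, spec), 0.01 / 25, tolerance = 1e-15)
  expect_equal(one_cycle_lr(30, spec), 0.01, tolerance = 1e-15)
  expect_equal(one_cycle_lr(100, spec), 0.01 / (25 * 1e4), tolerance = 1e-15)
  # momentum counter-cycles
  expect_equal(one_cycle_mom(0, spec), 0.95, tolerance = 1e-15)
  expect_equal(one_cycle_mom(30, spec), 0.85, tolerance = 1e-15)
  expect_equal(one_cycle_mom(100, spec), 0.95, tolerance = 1e-15)
  # continuity near the peak
  expect_lt(abs(one_cycle_lr(30.01, spec) - one_cycle_lr(29.99, spec)), 1e-5)
  expect_error(one_cycle_lr(101, spec), "out of range")
  expect_error(one_cycle_lr(-1, spec), "out of range")
})

test_that("discriminative rates follow the geometric ladder", {
  lrs <- discriminative_lrs(3e-2, 4L, 2.6)
  expect_equal(lrs, c(3e-2 / 2.6^3, 3e-2 / 2.6^2, 3e-2 / 2.6, 3e-2),
               tolerance = 1e-12)
  expect_equal(lrs[1], 1.707e-3, tolerance = 1e-3)
  ratios <- lrs[-1] / lrs[-length(lrs)]
  expect_equal(ratios, rep(2.6, 3), tolerance = 1e-12)
  expect_equal(discriminative_lrs(0.5, 3L, 1), rep(0.5, 3L),
               tolerance = 1e-15)
})

test_that("the default stage plan carries the published rates and epochs", {
  plan <- default_stage_plan()
  expect_identical(plan$stages$unfrozen_groups, 1:4)
  expect_equal(plan$stages$base_lr, c(3e-2, 5e-3, 5e-4, 5e-5),
               tolerance = 1e-15)
  expect_identical(plan$stages$epochs, c(4L, 4L, 4L, 6L))
  expect_equal(plan$lr_decay_factor, 2.6, tolerance = 1e-15)
  expect_error(stage_plan(c(1L, 3L, 2L), rep(1e-3, 3), rep(1L, 3)),
               "strictly more")
})

test_that("layer groups partition the parameters bottom-to-top", {
  vocab <- fixture_vocab()
  model <- build_qsar(vocab, test_encoder(), classifier_config(output_dim = 1L),
                      seed = 1L)
  groups <- layer_groups(model)
  expect_length(groups, 4L)
  all_names <- unlist(groups)
  expect_setequal(all_names, names(model$params))
  expect_identical(anyDuplicated(all_names), 0L)
  expect_true("emb" %in% groups[[1]])
  expect_true("lstm_Wh_2" %in% groups[[2]])
  expect_true("lstm_Wh_3" %in% groups[[3]])
  expect_true(all(c("head_W1", "head_W2") %in% groups[[4]]))

  lm <- build_mspm(vocab, test_encoder(), seed = 1L)
  expect_true("dec_b" %in% layer_groups(lm)[[4]])
})

test_that("language-model training starts at the uniform baseline and is reproducible", {
  corp <- fixture_corpus()
  vocab <- build_vocab(lapply(corp$canonical_smiles, tokenize_smiles))
  stream <- lm_stream(corp$canonical_smiles, vocab)
  model <- build_mspm(vocab, test_encoder(0.1, 12L, 16L, 2L), seed = 2L)

  init_loss <- evaluate_mspm(model, stream, bptt = 30L, batch_size = 8L)
  expect_lt(abs(init_loss - log(vocab_size(vocab))) / log(vocab_size(vocab)),
            0.05)

  a <- train_mspm(model, stream, epochs = 2L, bptt = 30L, batch_size = 8L,
                  lr_max = 3e-3, seed = 5L)
  b <- train_mspm(model, stream, epochs = 2L, bptt = 30L, batch_size = 8L,
                  lr_max = 3e-3, seed = 5L)
  expect_identical(a$loss_log, b$loss_log)
  expect_identical(a$model$params, b$model$params)
  expect_lt(tail(a$loss_log, 1), init_loss)
  expect_error(train_mspm(model, integer(0)), "empty corpus")
})

test_that("frozen layer groups are bit-invariant through a training stage", {
  corp <- fixture_corpus()
  ds <- generate_regression_dataset(synth_spec(n_molecules = 40L, seed = 44L))
  vocab <- build_vocab(lapply(ds$canonical_smiles, tokenize_smiles))
  model <- build_qsar(vocab, test_encoder(0.1),
                      classifier_config(output_dim = 1L), seed = 3L)
  groups <- layer_groups(model)

  head_only <- stage_plan(1L, 5e-3, 2L)
  fit <- finetune_qsar(model, ds, head_only, task = "regression",
                       vocab = vocab, batch_size = 16L, seed = 1L,
                       allow_partial = TRUE)
  for (nm in unlist(groups[1:3])) {
    expect_identical(fit$model$params[[nm]], model$params[[nm]], info = nm)
  }
  expect_false(identical(fit$model$params$head_W1, model$params$head_W1))

  full <- stage_plan(4L, 5e-3, 2L)
  fit2 <- finetune_qsar(model, ds, full, task = "regression", vocab = vocab,
                        batch_size = 16L, seed = 1L)
  for (gi in seq_along(groups)) {
    changed <- any(vapply(groups[[gi]], function(nm) {
      !identical(fit2$model$params[[nm]], model$params[[nm]])
    }, TRUE))
    expect_true(changed, info = paste("group", gi))
  }
})

test_that("logged learning rates match the schedule formula exactly", {
  ds <- generate_regression_dataset(synth_spec(n_molecules = 30L, seed = 45L))
  vocab <- build_vocab(lapply(ds$canonical_smiles, tokenize_smiles))
  model <- build_qsar(vocab, test_encoder(0),
                      classifier_config(output_dim = 1L), seed = 3L)
  plan <- stage_plan(c(2L, 4L), c(4e-3, 1e-3), c(2L, 1L),
                     lr_decay_factor = 2.6)
  fit <- finetune_qsar(model, ds, plan, task = "regression", vocab = vocab,
                       batch_size = 8L, seed = 2L)
  lr_log <- fit$lr_log
  steps_per_epoch <- ceiling(30L / 8L)
  for (si in 1:2) {
    k <- plan$stages$unfrozen_groups[si]
    base <- plan$stages$base_lr[si]
    total <- plan$stages$epochs[si] * steps_per_epoch
    spec <- one_cycle_spec(base, total_steps = total)
    disc <- numeric(4L)
    disc[(4L - k + 1L):4L] <- discriminative_lrs(base, k, 2.6)
    rows <- lr_log[lr_log$stage == si, ]
    for (r in seq_len(nrow(rows))) {
      expected <- disc * one_cycle_lr(rows$step[r], spec) / base
      got <- as.numeric(rows[r, paste0("group", 1:4)])
      for (g in 1:4) {
        if (expected[g] == 0) {
          expect_identical(got[g], 0)
        } else {
          expect_lt(abs(got[g] - expected[g]) / expected[g], 1e-12)
        }
      }
    }
  }
})

test_that("staged fine-tuning is seed-reproducible end to end", {
  ds <- generate_regression_dataset(synth_spec(n_molecules = 30L, seed = 46L))
  vocab <- build_vocab(lapply(ds$canonical_smiles, tokenize_smiles))
  model <- build_qsar(vocab, test_encoder(0.2),
                      classifier_config(output_dim = 1L), seed = 3L)
  plan <- stage_plan(c(1L, 4L), c(5e-3, 1e-3), c(1L, 1L))
  a <- finetune_qsar(model, ds, plan, task = "regression", vocab = vocab,
                     batch_size = 8L, seed = 9L)
  b <- finetune_qsar(model, ds, plan, task = "regression", vocab = vocab,
                     batch_size = 8L, seed = 9L)
  expect_identical(a$loss_log, b$loss_log)
  expect_identical(a$model$params, b$model$params)
  pa <- predict_qsar(a$model, ds$canonical_smiles[1:5], task = "regression")
  pb <- predict_qsar(b$model, ds$canonical_smiles[1:5], task = "regression")
  expect_identical(pa, pb)
})

test_that("task-corpus LM fine-tuning lowers held-out task perplexity", {
  general_corp <- generate_corpus(synth_spec(n_molecules = 300L, seed = 51L,
                                             ring_prob = 0.15))
  task_spec <- synth_spec(n_molecules = 200L, seed = 52L, ring_prob = 0.9,
                          atom_alphabet = c("C", "N", "O"))
  task_corp <- generate_corpus(task_spec)
  vocab <- build_vocab(lapply(c(general_corp$canonical_smiles,
                                task_corp$canonical_smiles),
                              tokenize_smiles))
  gen_stream <- lm_stream(general_corp$canonical_smiles, vocab)
  model <- build_mspm(vocab, test_encoder(0.1, 16L, 24L), seed = 4L)
  gen_fit <- train_mspm(model, gen_stream, epochs = 4L, bptt = 40L,
                        batch_size = 16L, lr_max = 5e-3, seed = 4L)

  task_train <- task_corp$canonical_smiles[1:150]
  task_held <- task_corp$canonical_smiles[151:200]
  held_stream <- lm_stream(task_held, vocab)
  before <- evaluate_mspm(gen_fit$model, held_stream, bptt = 40L,
                          batch_size = 8L)
  ft <- finetune_task_mspm(gen_fit$model, lm_stream(task_train, vocab),
                           epochs = 4L, base_lr = 3e-3, bptt = 40L,
                           batch_size = 16L, seed = 5L)
  after <- evaluate_mspm(ft$model, held_stream, bptt = 40L, batch_size = 8L)
  expect_lte(after, before)
  # encoder shapes unchanged by fine-tuning
  for (nm in names(ft$model$params)) {
    expect_identical(dim(ft$model$params[[nm]]),
                     dim(gen_fit$model$params[[nm]]), info = nm)
  }
})

test_that("the paired benchmark table is structured by its design", {
  res <- transfer_benchmark(pretrain_n = 150L, task_n = 40L, seeds = 1:2,
                            enc = test_encoder(0.1, 12L, 16L, 2L),
                            plan = stage_plan(c(1L, 4L), c(5e-3, 1e-3),
                                              c(1L, 1L)),
                            n_valid = 30L, pretrain_epochs = 1L,
                            lm_batch_size = 8L, bptt = 30L,
                            base_seed = 60L)
  expect_identical(nrow(res), 4L)  # seeds x arms
  expect_setequal(unique(res$arm), c("pretrained", "scratch"))
  smry <- attr(res, "summary")
  expect_identical(smry$n_seeds, 2L)
  expect_true(smry$wins_pretrained >= 0 && smry$wins_pretrained <= 2)
})
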