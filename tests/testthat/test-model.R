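test_that("default encoder configuration matches the published architecture", {
  enc <- encoder_config()
  expect_identical(enc$embedding_dim, 400L)
  expect_identical(enc$hidden_dim, 1152L)
  expect_identical(enc$n_layers, 3L)
  head <- classifier_config()
  expect_identical(head$hidden_dim, 50L)
  expect_identical(head$output_dim, 1L)
  # pooled head input is 3 x embedding width (1200 at default)
  shapes <- expected_param_shapes("qsar", 100L, enc, head)
  expect_identical(shapes$head_W1[1], 1200L)
})

test_that("every parameter shape is a pure function of the configuration", {
  enc <- test_encoder(n_layers = 3L)
  head <- classifier_config(hidden_dim = 5L, output_dim = 2L)
  V <- 21L
  shapes <- expected_param_shapes("qsar", V, enc, head)
  model <- build_qsar(V, enc, head, seed = 1L)
  expect_setequal(names(model$params), names(shapes))
  for (nm in names(shapes)) {
    have <- if (is.matrix(model$params[[nm]])) dim(model$params[[nm]])
            else length(model$params[[nm]])
    expect_identical(as.integer(have), as.integer(shapes[[nm]]),
                     info = nm)
  }
  # language model: tied decoder reuses the embedding
  lm <- build_mspm(V, enc, seed = 1L)
  expect_false("dec_W" %in% names(lm$params))
  expect_identical(dim(lm$params$emb), c(V, enc$embedding_dim))
  expect_length(lm$params$dec_b, V)
  # inner LSTM shapes follow the declared widths
  expect_identical(dim(lm$params$lstm_Wx_1),
                   c(enc$embedding_dim, 4L * enc$hidden_dim))
  expect_identical(dim(lm$params$lstm_Wx_3),
                   c(enc$hidden_dim, 4L * enc$embedding_dim))
})

test_that("misconfigured models raise configuration errors", {
  expect_error(encoder_config(dropouts = list(embedding = 1.2, input = 0,
                                              weight = 0, hidden = 0,
                                              output = 0)),
               "configuration error")
  expect_error(encoder_config(dropouts = list(embedding = 0.1)),
               "configuration error")
  expect_error(build_mspm(4L, test_encoder()), "configuration error")
})

test_that("builds are deterministic and eval-mode forwards reproducible", {
  vocab <- fixture_vocab()
  a <- build_mspm(vocab, test_encoder(0), seed = 7L)
  b <- build_mspm(vocab, test_encoder(0), seed = 7L)
  expect_identical(a$params, b$params)
  ids <- matrix(with_seed(1L, sample(0:(vocab_size(vocab) - 1L), 24L,
                                     replace = TRUE)), 8L, 3L)
  tgt <- matrix(with_seed(2L, sample(0:(vocab_size(vocab) - 1L), 24L,
                                     replace = TRUE)), 8L, 3L)
  la <- mspm_forward_backward(a, ids, tgt, compute_grads = FALSE)$loss
  lb <- mspm_forward_backward(b, ids, tgt, compute_grads = FALSE)$loss
  expect_identical(la, lb)
  c_ <- build_mspm(vocab, test_encoder(0), seed = 8L)
  expect_false(identical(a$params$emb, c_$params$emb))
})

test_that("a freshly initialized language model scores near the uniform baseline", {
  vocab <- fixture_vocab()
  model <- build_mspm(vocab, test_encoder(0), seed = 3L)
  stream <- lm_stream(FIXTURE_SMILES[1:15], vocab)
  loss <- evaluate_mspm(model, stream, bptt = 20L, batch_size = 4L)
  expect_lt(abs(loss - log(vocab_size(vocab))) / log(vocab_size(vocab)), 0.05)
})

test_that("concat pooling collapses constants and ignores padding", {
  B <- 3L; E <- 4L; TT <- 5L
  h <- matrix(stats::rnorm(B * E), B, E)
  out <- do.call(rbind, replicate(TT, h, simplify = FALSE))
  mask <- matrix(TRUE, TT, B)
  pool <- concat_pool(out, mask)
  expect_equal(pool$pooled, cbind(h, h, h), tolerance = 1e-15)

  single <- concat_pool(out[1:B, , drop = FALSE], matrix(TRUE, 1L, B))
  expect_equal(single$pooled, cbind(h, h, h), tolerance = 1e-15)

  # appending pad positions never changes the pooled vector
  out2 <- rbind(out, matrix(99, 2L * B, E))
  mask2 <- rbind(mask, matrix(FALSE, 2L, B))
  expect_equal(concat_pool(out2, mask2)$pooled, pool$pooled,
               tolerance = 1e-15)

  expect_error(concat_pool(out, matrix(FALSE, TT, B)), "padding")
})

test_that("encoder transfer copies weights exactly and maps vocabularies", {
  enc <- test_encoder(0)
  sv <- build_vocab(list(c("C", "O", "N", "=", "(", ")")))
  tv <- build_vocab(list(c("C", "O", "S", "Br")))
  src <- build_mspm(sv, enc, seed = 1L)
  tgt <- build_qsar(tv, enc, classifier_config(output_dim = 1L), seed = 9L)
  head_before <- tgt$params$head_W1
  out <- transfer_encoder(src, tgt, sv, tv)
  for (l in 1:3) {
    expect_identical(out$params[[paste0("lstm_Wh_", l)]],
                     src$params[[paste0("lstm_Wh_", l)]])
  }
  # shared token rows copied to their target indices
  for (tok in c("C", "O", "<bos>")) {
    expect_identical(out$params$emb[tv$index[[tok]] + 1L, ],
                     src$params$emb[sv$index[[tok]] + 1L, ])
  }
  # target-only token rows get the mean source embedding row
  expect_equal(out$params$emb[tv$index[["S"]] + 1L, ],
               colMeans(src$params$emb), tolerance = 1e-15)
  # the task head is untouched (freshly initialized)
  expect_identical(out$params$head_W1, head_before)

  # identical vocabularies: embedding copied element-wise
  tgt2 <- transfer_encoder(src, build_qsar(sv, enc,
                                           classifier_config(output_dim = 1L),
                                           seed = 2L), sv, sv)
  expect_identical(tgt2$params$emb, src$params$emb)

  bad <- build_qsar(tv, test_encoder(0, hidden_dim = 9L),
                    classifier_config(output_dim = 1L), seed = 1L)
  expect_error(transfer_encoder(src, bad, sv, tv), "transfer error")
})

test_that("a transferred encoder is forward-identical to its source", {
  enc <- test_encoder(0)
  sv <- fixture_vocab()
  src <- build_mspm(sv, enc, seed = 4L)
  tgt <- transfer_encoder(src, build_qsar(sv, enc,
                                          classifier_config(output_dim = 1L),
                                          seed = 30L), sv, sv)
  ids <- matrix(with_seed(5L, sample(0:(vocab_size(sv) - 1L), 40L,
                                     replace = TRUE)), 10L, 4L)
  o1 <- encoder_forward(src$params, enc, ids)$out
  o2 <- encoder_forward(tgt$params, enc, ids)$out
  expect_identical(o1, o2)
})

test_that("checkpoints round-trip exactly and validate their shape audit", {
  vocab <- fixture_vocab()
  model <- build_qsar(vocab, test_encoder(0.2),
                      classifier_config(output_dim = 2L), seed = 11L)
  model$norm <- list(mean = 1.5, sd = 2.25)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(back$vocab$tokens, vocab$tokens)
  expect_equal(back$norm, model$norm, tolerance = 1e-15)
  expect_equal(back$bn, model$bn, tolerance = 1e-15)
  expect_identical(back$head$output_dim, 2L)

  # corrupt one tensor's payload: audit must fail
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$params$head_b2$data <-
    jsonlite::base64_enc(writeBin(1.0, raw(), size = 8L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "shape audit")

  lm <- build_mspm(vocab, test_encoder(0), seed = 1L)
  lm_path <- withr::local_tempfile(fileext = ".json")
  save_model(lm, lm_path)
  lm2 <- load_model(lm_path)
  expect_identical(lm2$params, lm$params)
  expect_null(lm2$head)
})

test_that("regression and classification heads emit the declared output sizes", {
  vocab <- fixture_vocab()
  reg <- build_qsar(vocab, test_encoder(0), classifier_config(output_dim = 1L),
                    seed = 1L)
  cls <- build_qsar(vocab, test_encoder(0), classifier_config(output_dim = 3L),
                    seed = 1L)
  seqs <- numericalize_set(c("CCO", "c1ccccc1"), vocab)
  ids <- pad_batch(seqs)
  pr <- qsar_forward_backward(reg, ids, task = "regression")$pred
  expect_length(pr, 2L)
  expect_true(is.numeric(pr))
  pc <- qsar_forward_backward(cls, ids, task = "classification")$pred
  expect_identical(dim(pc), c(2L, 3L))
  expect_equal(rowSums(pc), c(1, 1), tolerance = 1e-12)
})
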