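# Model builders: the SMILES language model (embedding + AWD-LSTM encoder +
# tied softmax decoder) and the QSAR/QSPR model (same encoder + concat-pool
# classifier/regressor head), plus cross-stage weight transfer and
# checkpoint IO.

#' AWD-LSTM encoder configuration
#'
#' Shape and regularization of the encoder shared by the language model and
#' the QSAR models. Defaults follow the standard configuration for SMILES
#' modelling: a 400-wide embedding, three LSTM layers with 1152 hidden
#' units, and the ULMFiT dropout family (dropout on the embedding matrix
#' rows, the embedded inputs, the recurrent weight matrices, the
#' between-layer hidden states, and the final output).
#'
#' @param embedding_dim Embedding width; also the output width of the last
#'   LSTM layer.
#' @param hidden_dim Hidden units of the inner LSTM layers.
#' @param n_layers Number of LSTM layers.
#' @param dropouts Named list with elements `embedding`, `input`, `weight`,
#'   `hidden`, `output`, all in `[0, 1)`.
#' @param dropout_mult Single multiplier applied to all five dropout rates
#'   (convenient when fine-tuning).
#' @param pad_index Index of the padding token (0).
#' @param tie_weights Tie the softmax decoder weights to the embedding?
#' @return An `encoder_config`.
#' @export
encoder_config <- function(embedding_dim = 400L, hidden_dim = 1152L,
                           n_layers = 3L,
                           dropouts = list(embedding = 0.1, input = 0.25,
                                           weight = 0.5, hidden = 0.15,
                                           output = 0.1),
                           dropout_mult = 1,
                           pad_index = 0L, tie_weights = TRUE) {
  stopifnot(embedding_dim >= 1L, hidden_dim >= 1L, n_layers >= 1L)
  need <- c("embedding", "input", "weight", "hidden", "output")
  if (!all(need %in% names(dropouts))) {
    stop("configuration error: `dropouts` must name ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dropouts <- lapply(dropouts[need], function(p) p * dropout_mult)
  if (any(unlist(dropouts) < 0) || any(unlist(dropouts) >= 1)) {
    stop("configuration error: dropouts must lie in [0, 1)", call. = FALSE)
  }
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 dropouts = dropouts,
                 pad_index = as.integer(pad_index),
                 tie_weights = isTRUE(tie_weights)),
            class = "encoder_config")
}

#' QSAR head configuration
#'
#' The classifier/regressor head consumes the concatenation of max pooling,
#' mean pooling and the last-time-step state of the encoder output
#' (`3 * embedding_dim` wide) through two feed-forward layers with a ReLU
#' between them, each preceded by batch normalization and dropout (the
#' standard pooled-classifier layout).
#'
#' @param hidden_dim Width of the intermediate head layer.
#' @param output_dim 1 for regression; the number of classes otherwise.
#' @param head_dropouts Dropout rates applied before each head layer.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(hidden_dim = 50L, output_dim = 1L,
                              head_dropouts = c(0.2, 0.1)) {
  stopifnot(hidden_dim >= 1L, output_dim >= 1L, length(head_dropouts) == 2L,
            all(head_dropouts >= 0), all(head_dropouts < 1))
  structure(list(hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 head_dropouts = head_dropouts),
            class = "classifier_config")
}

# Expected shape of every parameter tensor as a pure function of
# (vocab_size, encoder config, head config); the single source of truth for
# initialization, checkpoint validation and the shape-audit tests.
expected_param_shapes <- function(kind, vocab_size, enc, head = NULL) {
  shapes <- list(emb = c(vocab_size, enc$embedding_dim))
  for (l in seq_len(enc$n_layers)) {
    ind <- layer_input_dim(enc, l)
    H <- layer_hidden_dim(enc, l)
    shapes[[paste0("lstm_Wx_", l)]] <- c(ind, 4L * H)
    shapes[[paste0("lstm_Wh_", l)]] <- c(H, 4L * H)
    shapes[[paste0("lstm_b_", l)]] <- c(4L * H)
  }
  if (kind == "mspm") {
    if (!enc$tie_weights) {
      shapes$dec_W <- c(enc$embedding_dim, vocab_size)
    }
    shapes$dec_b <- c(vocab_size)
  } else {
    shapes$head_bn1_g <- c(3L * enc$embedding_dim)
    shapes$head_bn1_b <- c(3L * enc$embedding_dim)
    shapes$head_W1 <- c(3L * enc$embedding_dim, head$hidden_dim)
    shapes$head_b1 <- c(head$hidden_dim)
    shapes$head_bn2_g <- c(head$hidden_dim)
    shapes$head_bn2_b <- c(head$hidden_dim)
    shapes$head_W2 <- c(head$hidden_dim, head$output_dim)
    shapes$head_b2 <- c(head$output_dim)
  }
  shapes
}

init_tensor <- function(dims, scale) {
  n <- prod(dims)
  x <- stats::runif(n, -scale, scale)
  if (length(dims) == 1L) x else matrix(x, dims[1], dims[2])
}

init_params <- function(kind, vocab_size, enc, head = NULL) {
  shapes <- expected_param_shapes(kind, vocab_size, enc, head)
  params <- list()
  for (nm in names(shapes)) {
    dims <- shapes[[nm]]
    params[[nm]] <-
      if (nm == "emb") init_tensor(dims, 0.1)
      else if (nm %in% c("head_bn1_g", "head_bn2_g")) rep(1, dims)
      else if (grepl("^lstm_b_", nm) ||
               nm %in% c("dec_b", "head_b1", "head_b2",
                         "head_bn1_b", "head_bn2_b")) {
        if (length(dims) == 1L) numeric(dims) else matrix(0, dims[1], dims[2])
      } else if (grepl("^lstm_", nm)) {
        H <- dims[2] / 4L
        init_tensor(dims, 1 / sqrt(H))
      } else {
        init_tensor(dims, 1 / sqrt(dims[1]))
      }
  }
  params
}

resolve_vocab <- function(vocab) {
  if (inherits(vocab, "smiles_vocab")) {
    list(vocab = vocab, size = vocab_size(vocab))
  } else {
    list(vocab = NULL, size = as.integer(vocab))
  }
}

#' Build a molecular structure prediction model (SMILES language model)
#'
#' Embedding, weight-dropped LSTM encoder and a single softmax decoder over
#' the vocabulary, with the decoder weights tied to the embedding by
#' default. Initialization is deterministic under `seed`.
#'
#' @param vocab A `smiles_vocab` (stored in the model) or an integer
#'   vocabulary size.
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mft_model` of kind `"mspm"`.
#' @export
build_mspm <- function(vocab, config = encoder_config(), seed = 0L) {
  v <- resolve_vocab(vocab)
  if (v$size < 5L) {
    stop("configuration error: vocabulary must hold the reserved block ",
         "plus at least one token", call. = FALSE)
  }
  params <- with_seed(seed, init_params("mspm", v$size, config))
  structure(list(kind = "mspm", enc = config, head = NULL,
                 vocab = v$vocab, vocab_size = v$size, params = params,
                 norm = NULL),
            class = "mft_model")
}

#' Build a QSAR/QSPR model
#'
#' Encoder as in [build_mspm()] plus a concat-pooling two-layer
#' feed-forward head. Regression models (`output_dim = 1`) emit one real
#' value per molecule; classification models emit one score per class.
#'
#' @param vocab A `smiles_vocab` or integer vocabulary size.
#' @param enc An [encoder_config()].
#' @param head A [classifier_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mft_model` of kind `"qsar"`.
#' @export
build_qsar <- function(vocab, enc = encoder_config(),
                       head = classifier_config(), seed = 0L) {
  v <- resolve_vocab(vocab)
  if (v$size < 5L) {
    stop("configuration error: vocabulary too small", call. = FALSE)
  }
  params <- with_seed(seed, init_params("qsar", v$size, enc, head))
  structure(list(kind = "qsar", enc = enc, head = head,
                 vocab = v$vocab, vocab_size = v$size, params = params,
                 norm = NULL,
                 bn = list(mean1 = numeric(3L * enc$embedding_dim),
                           var1 = rep(1, 3L * enc$embedding_dim),
                           mean2 = numeric(head$hidden_dim),
                           var2 = rep(1, head$hidden_dim))),
            class = "mft_model")
}

#' @export
print.mft_model <- function(x, ...) {
  cat(sprintf("<mft_model kind=%s vocab=%d emb=%d hidden=%d layers=%d>\n",
              x$kind, x$vocab_size, x$enc$embedding_dim, x$enc$hidden_dim,
              x$enc$n_layers))
  n_par <- sum(vapply(x$params, length, 0L))
  cat("  parameters:", format(n_par, big.mark = ","), "\n")
  invisible(x)
}

#' Concatenation pooling of encoder outputs
#'
#' Builds the QSAR head input `[max-pool || mean-pool || h_T]` over the
#' valid (non-pad) positions of each sequence. Padding positions are
#' excluded from both pools and `h_T` is the final-layer state at the last
#' non-pad time step, so appending padding never changes the result.
#'
#' @param out `(T*B) x E` matrix of final-layer states in timestep-major
#'   blocks (as returned by the encoder).
#' @param mask `T x B` logical matrix of position validity.
#' @return List with `pooled` (`B x 3E`) and bookkeeping for the backward
#'   pass (`argmax`, `counts`, `t_last`).
#' @export
concat_pool <- function(out, mask) {
  TT <- nrow(mask)
  B <- ncol(mask)
  E <- ncol(out)
  if (!any(mask)) stop("concat_pool: all positions are padding", call. = FALSE)
  if (any(colSums(mask) == 0L)) {
    stop("concat_pool: a sequence consists entirely of padding", call. = FALSE)
  }
  maxv <- matrix(-Inf, B, E)
  amax <- matrix(0L, B, E)
  sums <- matrix(0, B, E)
  counts <- colSums(mask)
  for (t in seq_len(TT)) {
    cur <- out[blk(t, B), , drop = FALSE]
    valid <- mask[t, ]
    if (!any(valid)) next
    curv <- cur
    curv[!valid, ] <- -Inf
    upd <- curv > maxv
    maxv[upd] <- curv[upd]
    amax[upd] <- t
    sums <- sums + cur * valid
  }
  meanv <- sums / counts
  t_last <- apply(mask, 2L, function(m) max(which(m)))
  hT <- out[(t_last - 1L) * B + seq_len(B), , drop = FALSE]
  list(pooled = cbind(maxv, meanv, hT), argmax = amax, counts = counts,
       t_last = t_last)
}

# Distribute head gradients back onto the per-timestep encoder outputs.
concat_pool_backward <- function(dpooled, pool, mask) {
  TT <- nrow(mask)
  B <- ncol(mask)
  E <- ncol(dpooled) / 3L
  dmax <- dpooled[, 1:E, drop = FALSE]
  dmean <- dpooled[, (E + 1):(2 * E), drop = FALSE]
  dlast <- dpooled[, (2 * E + 1):(3 * E), drop = FALSE]
  d_out <- matrix(0, TT * B, E)
  # max-pool: route each element to its argmax timestep
  flat_rows <- (pool$argmax - 1L) * B + seq_len(B)       # B x E row indices
  idx <- cbind(as.vector(flat_rows), rep(seq_len(E), each = B))
  d_out[idx] <- d_out[idx] + as.vector(dmax)
  # last-step
  last_rows <- (pool$t_last - 1L) * B + seq_len(B)
  d_out[last_rows, ] <- d_out[last_rows, ] + dlast
  # mean-pool: distribute over valid positions
  dmean_scaled <- dmean / pool$counts
  for (t in seq_len(TT)) {
    valid <- mask[t, ]
    if (any(valid)) {
      rows <- blk(t, B)
      d_out[rows, ] <- d_out[rows, ] + dmean_scaled * valid
    }
  }
  d_out
}

#' Transfer pretrained embedding and encoder weights into another model
#'
#' Copies the encoder verbatim (the configurations must match) and maps
#' embedding rows across vocabularies: rows of tokens present in both
#' vocabularies are copied to their target indices, rows of target-only
#' tokens are initialized to the mean of all source embedding rows. The
#' target task head is left untouched (freshly initialized).
#'
#' @param source Pretrained `mft_model`.
#' @param target Freshly built `mft_model` (language model or QSAR).
#' @param source_vocab,target_vocab `smiles_vocab` objects; default to the
#'   vocabularies stored in the models.
#' @return `target` with transferred weights.
#' @export
transfer_encoder <- function(source, target, source_vocab = source$vocab,
                             target_vocab = target$vocab) {
  stopifnot(inherits(source, "mft_model"), inherits(target, "mft_model"))
  se <- source$enc; te <- target$enc
  if (se$embedding_dim != te$embedding_dim ||
      se$hidden_dim != te$hidden_dim || se$n_layers != te$n_layers) {
    stop("transfer error: encoder shapes differ between source and target",
         call. = FALSE)
  }
  if (is.null(source_vocab) || is.null(target_vocab)) {
    stop("transfer error: both vocabularies are required", call. = FALSE)
  }
  for (l in seq_len(se$n_layers)) {
    for (part in c("lstm_Wx_", "lstm_Wh_", "lstm_b_")) {
      nm <- paste0(part, l)
      target$params[[nm]] <- source$params[[nm]]
    }
  }
  mean_row <- colMeans(source$params$emb)
  new_emb <- matrix(rep(mean_row, each = vocab_size(target_vocab)),
                    vocab_size(target_vocab), se$embedding_dim)
  shared <- intersect(source_vocab$tokens, target_vocab$tokens)
  src_idx <- unname(source_vocab$index[shared]) + 1L
  tgt_idx <- unname(target_vocab$index[shared]) + 1L
  new_emb[tgt_idx, ] <- source$params$emb[src_idx, , drop = FALSE]
  target$params$emb <- new_emb
  if (target$kind == "mspm" && source$kind == "mspm") {
    new_b <- rep(mean(source$params$dec_b), vocab_size(target_vocab))
    new_b[tgt_idx] <- source$params$dec_b[src_idx]
    target$params$dec_b <- new_b
    if (!te$tie_weights && !se$tie_weights) {
      new_W <- matrix(rep(rowMeans(source$params$dec_W),
                          times = vocab_size(target_vocab)),
                      se$embedding_dim, vocab_size(target_vocab))
      new_W[, tgt_idx] <- source$params$dec_W[, src_idx, drop = FALSE]
      target$params$dec_W <- new_W
    }
  }
  target
}

# ---- forward/backward wrappers used by the training loops ----

# Language-model forward over a window; targets are zero-based ids aligned
# with `ids`. Returns loss (cross-entropy only), decoder/encoder gradients
# (train mode; including activation-regularization terms) and the carried
# state. `ar_alpha` penalizes large final-layer activations and `tar_beta`
# penalizes their temporal differences — both standard AWD-LSTM
# regularizers that keep the recurrent gates out of saturation.
mspm_forward_backward <- function(model, ids, targets, state = NULL,
                                  train = FALSE, compute_grads = train,
                                  ar_alpha = 2, tar_beta = 1) {
  enc <- model$enc
  fwd <- encoder_forward(model$params, enc, ids, state = state,
                         train = train, keep_cache = compute_grads)
  TT <- nrow(ids); B <- ncol(ids)
  H <- fwd$out                       # (T*B) x E, t-major blocks
  out_mask <- if (train) fwd$masks$output else NULL
  if (!is.null(out_mask)) {
    H_d <- H * out_mask[rep(seq_len(B), times = TT), , drop = FALSE]
  } else H_d <- H
  dec_W <- if (enc$tie_weights) t(model$params$emb) else model$params$dec_W
  logits <- add_row_vec(H_d %*% dec_W, model$params$dec_b)
  tgt <- as.integer(t(targets)) + 1L
  cl <- ce_loss(logits, tgt)
  if (!compute_grads) {
    return(list(loss = cl$loss, state = fwd$state))
  }
  dH_d <- cl$dlogits %*% t(dec_W)
  g_dec_b <- colSums(cl$dlogits)
  g_dec_W <- crossprod(H_d, cl$dlogits)  # E x V
  if (train && ar_alpha > 0) {
    dH_d <- dH_d + (2 * ar_alpha / length(H_d)) * H_d
  }
  if (!is.null(out_mask)) {
    dH <- dH_d * out_mask[rep(seq_len(B), times = TT), , drop = FALSE]
  } else dH <- dH_d
  if (train && tar_beta > 0 && TT > 1L) {
    # temporal activation regularization on the raw final-layer output
    first <- seq_len((TT - 1L) * B)
    later <- B + first
    diffs <- H[later, , drop = FALSE] - H[first, , drop = FALSE]
    scale <- 2 * tar_beta / length(diffs)
    dH[later, ] <- dH[later, ] + scale * diffs
    dH[first, ] <- dH[first, ] - scale * diffs
  }
  grads <- encoder_backward(model$params, enc, fwd$cache, dH)
  if (enc$tie_weights) {
    grads$emb <- grads$emb + t(g_dec_W)
  } else {
    grads$dec_W <- g_dec_W
  }
  grads$dec_b <- g_dec_b
  list(loss = cl$loss, grads = grads, state = fwd$state)
}

# QSAR forward (and optional backward) on a padded batch.
# ids: T x B zero-based, 0 = pad. Returns predictions (regression vector or
# class-probability matrix), loss and gradients when labels are given.
qsar_forward_backward <- function(model, ids, labels = NULL, train = FALSE,
                                  task = c("regression", "classification")) {
  task <- match.arg(task)
  enc <- model$enc; head <- model$head
  B <- ncol(ids)
  mask <- ids != model$enc$pad_index
  fwd <- encoder_forward(model$params, enc, ids, train = train,
                         keep_cache = train && !is.null(labels))
  pool <- concat_pool(fwd$out, mask)
  p1 <- head$head_dropouts[1]; p2 <- head$head_dropouts[2]
  bn <- model$bn
  bn1 <- bn_forward(pool$pooled, model$params$head_bn1_g,
                    model$params$head_bn1_b, bn$mean1, bn$var1, train)
  bn$mean1 <- bn1$run_mean; bn$var1 <- bn1$run_var
  m1 <- if (train) drop_mask(B, ncol(bn1$y), p1) else NULL
  x0 <- if (is.null(m1)) bn1$y else bn1$y * m1
  a1 <- add_row_vec(x0 %*% model$params$head_W1, model$params$head_b1)
  r1 <- pmax(a1, 0)
  bn2 <- bn_forward(r1, model$params$head_bn2_g, model$params$head_bn2_b,
                    bn$mean2, bn$var2, train)
  bn$mean2 <- bn2$run_mean; bn$var2 <- bn2$run_var
  m2 <- if (train) drop_mask(B, ncol(bn2$y), p2) else NULL
  x1 <- if (is.null(m2)) bn2$y else bn2$y * m2
  out <- add_row_vec(x1 %*% model$params$head_W2, model$params$head_b2)

  if (task == "regression") {
    pred <- out[, 1L]
  } else {
    mx <- apply(out, 1L, max)
    ex <- exp(out - mx)
    pred <- ex / rowSums(ex)   # class probabilities
  }
  if (is.null(labels)) return(list(pred = pred, bn = bn))

  if (task == "regression") {
    ls <- mse_loss(pred, labels)
    dout <- matrix(ls$dpred, B, 1L)
  } else {
    ls <- ce_loss(out, as.integer(labels) + 1L)  # labels zero-based
    dout <- ls$dlogits
  }
  if (!train) return(list(pred = pred, loss = ls$loss, bn = bn))

  grads <- list()
  grads$head_W2 <- crossprod(x1, dout)
  grads$head_b2 <- colSums(dout)
  dx1 <- dout %*% t(model$params$head_W2)
  if (!is.null(m2)) dx1 <- dx1 * m2
  bnb2 <- bn_backward(dx1, bn2$cache)
  grads$head_bn2_g <- bnb2$dgamma
  grads$head_bn2_b <- bnb2$dbeta
  da1 <- bnb2$dx * (a1 > 0)
  grads$head_W1 <- crossprod(x0, da1)
  grads$head_b1 <- colSums(da1)
  dx0 <- da1 %*% t(model$params$head_W1)
  if (!is.null(m1)) dx0 <- dx0 * m1
  bnb1 <- bn_backward(dx0, bn1$cache)
  grads$head_bn1_g <- bnb1$dgamma
  grads$head_bn1_b <- bnb1$dbeta
  d_out <- concat_pool_backward(bnb1$dx, pool, mask)
  enc_grads <- encoder_backward(model$params, enc, fwd$cache, d_out)
  list(pred = pred, loss = ls$loss, grads = c(enc_grads, grads), bn = bn)
}

# ---- checkpoint IO (single JSON archive; weights as base64 doubles) ----

encode_tensor <- function(x) {
  list(dims = if (is.matrix(x)) dim(x) else length(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8L, endian = "little")))
}

decode_tensor <- function(obj) {
  raw <- jsonlite::base64_dec(obj$data)
  x <- readBin(raw, numeric(), n = length(raw) / 8L, size = 8L,
               endian = "little")
  dims <- as.integer(unlist(obj$dims))
  if (length(dims) == 2L) matrix(x, dims[1], dims[2]) else x
}

#' Save a model checkpoint
#'
#' Writes a single JSON archive holding the configuration, the vocabulary
#' and every named weight tensor (base64-encoded doubles, exact
#' round-trip). [load_model()] validates all tensor shapes before use.
#'
#' @param model An `mft_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mft_model"))
  obj <- list(kind = model$kind,
              enc = unclass(model$enc),
              head = if (!is.null(model$head)) unclass(model$head),
              vocab = if (!is.null(model$vocab)) model$vocab$tokens,
              vocab_size = model$vocab_size,
              norm = model$norm,
              bn = model$bn,
              params = lapply(model$params, encode_tensor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint, validating the shape audit
#' @param path Path written by [save_model()].
#' @return An `mft_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  enc <- do.call(encoder_config, c(
    obj$enc[c("embedding_dim", "hidden_dim", "n_layers", "pad_index",
              "tie_weights")],
    list(dropouts = lapply(obj$enc$dropouts, as.numeric))))
  head <- if (length(obj$head) > 0L) {
    classifier_config(hidden_dim = obj$head$hidden_dim,
                      output_dim = obj$head$output_dim,
                      head_dropouts = as.numeric(unlist(obj$head$head_dropouts)))
  }
  params <- lapply(obj$params, decode_tensor)
  shapes <- expected_param_shapes(obj$kind, obj$vocab_size, enc, head)
  if (!setequal(names(shapes), names(params))) {
    stop("checkpoint is missing parameter tensors", call. = FALSE)
  }
  for (nm in names(shapes)) {
    have <- if (is.matrix(params[[nm]])) dim(params[[nm]]) else length(params[[nm]])
    if (!identical(as.integer(have), as.integer(shapes[[nm]]))) {
      stop("checkpoint shape audit failed for ", nm, call. = FALSE)
    }
  }
  vocab <- if (!is.null(obj$vocab)) new_vocab(unlist(obj$vocab))
  structure(list(kind = obj$kind, enc = enc, head = head, vocab = vocab,
                 vocab_size = as.integer(obj$vocab_size),
                 params = params,
                 norm = if (length(obj$norm) > 0L) lapply(obj$norm, as.numeric),
                 bn = if (length(obj$bn) > 0L) {
                   lapply(obj$bn, function(x) as.numeric(unlist(x)))
                 }),
            class = "mft_model")
}
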