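# Numerical core: AWD-LSTM forward/backward passes, losses, and the Adam
# optimizer, written against plain R matrices. Sequences are processed
# batch-major (each timestep is a B x width matrix); all token indices are
# zero-based with 0 = padding. The LSTM runs layer-major: the input
# projection of a whole window is one large matrix product per layer, only
# the recurrent product stays inside the timestep loop. Gate layout is
# [input | forget | output | cell] so the three sigmoid gates share one
# contiguous slice.

sigm <- function(x) 1 / (1 + exp(-x))

add_row_vec <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)

# Bernoulli keep-mask scaled by 1/(1-p) (inverted dropout).
drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

layer_input_dim <- function(enc, l) {
  if (l == 1L) enc$embedding_dim else enc$hidden_dim
}

layer_hidden_dim <- function(enc, l) {
  if (l == enc$n_layers) enc$embedding_dim else enc$hidden_dim
}

# Fresh per-forward dropout masks for the encoder (train mode).
encoder_masks <- function(params, enc, batch) {
  d <- enc$dropouts
  L <- enc$n_layers
  list(
    emb_row = if (d$embedding > 0) {
      stats::rbinom(nrow(params$emb), 1L, 1 - d$embedding) / (1 - d$embedding)
    } else NULL,
    input = drop_mask(batch, enc$embedding_dim, d$input),
    hidden = lapply(seq_len(L), function(l) {
      if (l < L) drop_mask(batch, layer_hidden_dim(enc, l), d$hidden) else NULL
    }),
    weight = lapply(seq_len(L), function(l) {
      W <- params[[paste0("lstm_Wh_", l)]]
      drop_mask(nrow(W), ncol(W), d$weight)
    }),
    output = drop_mask(batch, enc$embedding_dim, d$output)
  )
}

zero_state <- function(enc, batch) {
  lapply(seq_len(enc$n_layers), function(l) {
    H <- layer_hidden_dim(enc, l)
    list(h = matrix(0, batch, H), c = matrix(0, batch, H))
  })
}

blk <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Forward pass over a window of token ids.
#   ids: T x B integer matrix of zero-based token indices.
# Returns the final-layer output for every timestep (one (T*B) x E matrix,
# timestep-major blocks), the final recurrent state, and (with keep_cache)
# the per-layer activations the backward pass needs.
encoder_forward <- function(params, enc, ids, state = NULL, train = FALSE,
                            masks = NULL, keep_cache = FALSE) {
  TT <- nrow(ids); B <- ncol(ids); L <- enc$n_layers
  if (is.null(state)) state <- zero_state(enc, B)
  if (train && is.null(masks)) masks <- encoder_masks(params, enc, B)
  emb <- params$emb
  if (train && !is.null(masks$emb_row)) emb <- emb * masks$emb_row
  Wh_eff <- lapply(seq_len(L), function(l) {
    W <- params[[paste0("lstm_Wh_", l)]]
    if (train && !is.null(masks$weight[[l]])) W * masks$weight[[l]] else W
  })
  x_emb <- emb[as.integer(t(ids)) + 1L, , drop = FALSE]  # (T*B) x E
  if (train && !is.null(masks$input)) {
    x_emb <- x_emb * masks$input[rep(seq_len(B), times = TT), , drop = FALSE]
  }
  cache <- if (keep_cache) {
    list(ids = ids, masks = masks, train = train, Wh_eff = Wh_eff,
         layers = vector("list", L), TT = TT, B = B, x_emb = x_emb,
         init_state = state)
  } else NULL
  new_state <- vector("list", L)
  x_all <- x_emb
  for (l in seq_len(L)) {
    H <- layer_hidden_dim(enc, l)
    pre_in <- x_all %*% params[[paste0("lstm_Wx_", l)]]
    bias <- matrix(params[[paste0("lstm_b_", l)]], B, 4L * H, byrow = TRUE)
    h <- state[[l]]$h
    cc <- state[[l]]$c
    out <- matrix(0, TT * B, H)
    if (keep_cache) {
      IFO <- matrix(0, TT * B, 3L * H); G <- matrix(0, TT * B, H)
      C <- matrix(0, TT * B, H)
    }
    Wh <- Wh_eff[[l]]
    s3 <- seq_len(3L * H)
    s4 <- 3L * H + seq_len(H)
    s1 <- seq_len(H)
    for (t in seq_len(TT)) {
      rows <- blk(t, B)
      pre <- pre_in[rows, , drop = FALSE] + (h %*% Wh + bias)
      ifo <- sigm(pre[, s3, drop = FALSE])
      g <- tanh(pre[, s4, drop = FALSE])
      cc <- ifo[, H + s1, drop = FALSE] * cc + ifo[, s1, drop = FALSE] * g
      h <- ifo[, 2L * H + s1, drop = FALSE] * tanh(cc)
      if (keep_cache) {
        IFO[rows, ] <- ifo; G[rows, ] <- g; C[rows, ] <- cc
      }
      out[rows, ] <- h
    }
    new_state[[l]] <- list(h = h, c = cc)
    if (keep_cache) {
      cache$layers[[l]] <- list(IFO = IFO, G = G, C = C, out = out)
    }
    x_all <- out
    if (l < L && train && !is.null(masks$hidden[[l]])) {
      x_all <- x_all * masks$hidden[[l]][rep(seq_len(B), times = TT), ,
                                         drop = FALSE]
    }
  }
  list(out = x_all, state = new_state, cache = cache, masks = masks)
}

# Backward pass matching encoder_forward(keep_cache = TRUE).
#   d_out: (T*B) x E gradient w.r.t. the final-layer output blocks (after
#   any masking applied by the caller's head).
# Returns gradients for every encoder parameter.
encoder_backward <- function(params, enc, cache, d_out) {
  TT <- cache$TT; B <- cache$B; L <- enc$n_layers
  masks <- cache$masks; train <- cache$train
  grads <- list()
  dx_up <- d_out
  hid_mask_full <- function(l) {
    masks$hidden[[l]][rep(seq_len(B), times = TT), , drop = FALSE]
  }
  for (l in rev(seq_len(L))) {
    lay <- cache$layers[[l]]
    H <- layer_hidden_dim(enc, l)
    if (l < L && train && !is.null(masks$hidden[[l]])) {
      dx_up <- dx_up * hid_mask_full(l)
    }
    TC <- tanh(lay$C)
    keep <- seq_len((TT - 1L) * B)
    Cprev <- rbind(cache$init_state[[l]]$c, lay$C[keep, , drop = FALSE])
    Hprev <- rbind(cache$init_state[[l]]$h, lay$out[keep, , drop = FALSE])
    Dpre <- matrix(0, TT * B, 4L * H)
    Wh_eff_t <- t(cache$Wh_eff[[l]])
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    s1 <- seq_len(H)
    for (t in rev(seq_len(TT))) {
      rows <- blk(t, B)
      ifo <- lay$IFO[rows, , drop = FALSE]
      i <- ifo[, s1, drop = FALSE]
      f <- ifo[, H + s1, drop = FALSE]
      o <- ifo[, 2L * H + s1, drop = FALSE]
      g <- lay$G[rows, , drop = FALSE]
      tc <- TC[rows, , drop = FALSE]
      dh <- dx_up[rows, , drop = FALSE] + dh_next
      dc <- dc_next + dh * o * (1 - tc^2)
      dpre <- cbind((dc * g) * i * (1 - i),
                    (dc * Cprev[rows, , drop = FALSE]) * f * (1 - f),
                    (dh * tc) * o * (1 - o),
                    (dc * i) * (1 - g^2))
      Dpre[rows, ] <- dpre
      dh_next <- dpre %*% Wh_eff_t
      dc_next <- dc * f
    }
    x_in <- if (l == 1L) {
      cache$x_emb
    } else {
      below <- cache$layers[[l - 1L]]$out
      if (train && !is.null(masks$hidden[[l - 1L]])) {
        below * hid_mask_full(l - 1L)
      } else below
    }
    grads[[paste0("lstm_Wx_", l)]] <- crossprod(x_in, Dpre)
    gWh <- crossprod(Hprev, Dpre)
    if (train && !is.null(masks$weight[[l]])) gWh <- gWh * masks$weight[[l]]
    grads[[paste0("lstm_Wh_", l)]] <- gWh
    grads[[paste0("lstm_b_", l)]] <- colSums(Dpre)
    dx_up <- Dpre %*% t(params[[paste0("lstm_Wx_", l)]])
  }
  if (train && !is.null(masks$input)) {
    dx_up <- dx_up * masks$input[rep(seq_len(B), times = TT), , drop = FALSE]
  }
  ids_by_t <- as.integer(t(cache$ids))
  agg <- rowsum(dx_up, group = ids_by_t)
  g_emb <- params$emb * 0
  rows <- as.integer(rownames(agg)) + 1L
  g_emb[rows, ] <- agg
  if (train && !is.null(masks$emb_row)) g_emb <- g_emb * masks$emb_row
  grads$emb <- g_emb
  grads
}

# Softmax cross-entropy over flattened logits (N x V); targets are
# one-based column indices. Returns mean loss and d(logits).
ce_loss <- function(logits, targets) {
  N <- nrow(logits)
  mx <- logits[cbind(seq_len(N), max.col(logits, ties.method = "first"))]
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  idx <- cbind(seq_len(N), targets)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}

mult_row_vec <- function(m, v) m * matrix(v, nrow(m), length(v), byrow = TRUE)

# BatchNorm over feature columns. In train mode normalizes by batch
# statistics and updates the running estimates (momentum 0.1); in eval mode
# uses the running estimates. Returns the output, the backward cache and
# the updated running stats.
bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1, eps = 1e-5) {
  if (train && nrow(x) > 1L) {
    mu <- colMeans(x)
    xc <- add_row_vec(x, -mu)
    v <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- add_row_vec(x, -mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- mult_row_vec(xc, inv)
  y <- add_row_vec(mult_row_vec(xhat, gamma), beta)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma,
                           batch_stats = train && nrow(x) > 1L),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- mult_row_vec(dy, cache$gamma)
  if (cache$batch_stats) {
    dx <- mult_row_vec(
      dxhat - add_row_vec(matrix(0, m, ncol(dy)), colSums(dxhat)) / m -
        mult_row_vec(cache$xhat, colSums(dxhat * cache$xhat)) / m,
      cache$inv)
  } else {
    dx <- mult_row_vec(dxhat, cache$inv)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

mse_loss <- function(pred, truth) {
  n <- length(truth)
  d <- pred - truth
  list(loss = mean(d^2), dpred = 2 * d / n)
}

# Adam with optional global-norm gradient clipping and per-parameter
# learning rates (named list `lrs`). `state` is an environment.
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

adam_step <- function(params, grads, state, lrs, trainable,
                      beta1 = 0.9, beta2 = 0.99, eps = 1e-8, clip = 0.4,
                      wd = 0) {
  if (!is.null(clip) && clip > 0) {
    sq <- sum(vapply(trainable, function(nm) sum(grads[[nm]]^2), 0))
    gn <- sqrt(sq)
    if (is.finite(gn) && gn > clip) {
      scale <- clip / gn
      for (nm in trainable) grads[[nm]] <- grads[[nm]] * scale
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- mhat / (sqrt(vhat) + eps)
    if (wd > 0) step <- step + wd * params[[nm]]  # decoupled weight decay
    params[[nm]] <- params[[nm]] - lrs[[nm]] * step
  }
  params
}
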