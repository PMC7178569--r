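# Learning-rate machinery: one-cycle scheduling, discriminative layer-wise
# rates, layer-group partition and the gradual-unfreezing stage plan.

#' One-cycle learning-rate schedule specification
#'
#' The schedule starts at `lr_max / div_factor`, warms up to `lr_max` at
#' `pct_start * total_steps` and anneals to
#' `lr_max / (div_factor * final_div)`, both phases cosine-interpolated.
#' Momentum (Adam beta1) counter-cycles between `mom_max` and `mom_min`.
#'
#' @param lr_max Peak learning rate.
#' @param total_steps Number of optimizer steps in the cycle.
#' @param pct_start Fraction of steps spent warming up.
#' @param div_factor Initial divisor.
#' @param final_div Extra terminal divisor.
#' @param mom_max,mom_min Momentum endpoints.
#' @return A `one_cycle_spec`.
#' @export
one_cycle_spec <- function(lr_max, total_steps, pct_start = 0.3,
                           div_factor = 25, final_div = 1e4,
                           mom_max = 0.95, mom_min = 0.85) {
  stopifnot(lr_max > 0, total_steps >= 1, pct_start > 0, pct_start < 1,
            div_factor > 0, final_div > 0)
  structure(list(lr_max = lr_max, total_steps = as.integer(total_steps),
                 pct_start = pct_start, div_factor = div_factor,
                 final_div = final_div, mom_max = mom_max,
                 mom_min = mom_min),
            class = "one_cycle_spec")
}

cosine_interp <- function(from, to, tau) {
  # clamp so the schedule endpoints are exact, not off by cos(pi) rounding
  ifelse(tau <= 0, from,
         ifelse(tau >= 1, to,
                from + (to - from) * (1 - cos(pi * tau)) / 2))
}

#' One-cycle learning rate at a step
#'
#' @param step Step in `[0, total_steps]`; endpoints are exact:
#'   `lr(0) = lr_max / div_factor`,
#'   `lr(pct_start * total_steps) = lr_max`,
#'   `lr(total_steps) = lr_max / (div_factor * final_div)`.
#' @param spec A [one_cycle_spec()].
#' @return Positive learning rate; continuous in `step`.
#' @export
one_cycle_lr <- function(step, spec) {
  stopifnot(inherits(spec, "one_cycle_spec"))
  if (any(step < 0) || any(step > spec$total_steps)) {
    stop("step out of range [0, total_steps]", call. = FALSE)
  }
  peak_at <- spec$pct_start * spec$total_steps
  lr0 <- spec$lr_max / spec$div_factor
  lr_end <- spec$lr_max / (spec$div_factor * spec$final_div)
  ifelse(step <= peak_at,
         cosine_interp(lr0, spec$lr_max, step / peak_at),
         cosine_interp(spec$lr_max, lr_end,
                       (step - peak_at) / (spec$total_steps - peak_at)))
}

#' One-cycle momentum (counter-cycled) at a step
#' @inheritParams one_cycle_lr
#' @return Momentum (Adam beta1) value.
#' @export
one_cycle_mom <- function(step, spec) {
  stopifnot(inherits(spec, "one_cycle_spec"))
  if (any(step < 0) || any(step > spec$total_steps)) {
    stop("step out of range [0, total_steps]", call. = FALSE)
  }
  peak_at <- spec$pct_start * spec$total_steps
  ifelse(step <= peak_at,
         cosine_interp(spec$mom_max, spec$mom_min, step / peak_at),
         cosine_interp(spec$mom_min, spec$mom_max,
                       (step - peak_at) / (spec$total_steps - peak_at)))
}

#' Discriminative layer-wise learning rates
#'
#' The top layer group trains at `base_lr`; each group below trains at the
#' next group's rate divided by `decay` (default 2.6), i.e.
#' `eta_lower = eta_upper / decay`.
#'
#' @param base_lr Learning rate of the top group.
#' @param n_groups Number of layer groups.
#' @param decay Geometric decay factor between adjacent groups.
#' @return Numeric vector of rates ordered bottom to top.
#' @export
discriminative_lrs <- function(base_lr, n_groups, decay = 2.6) {
  stopifnot(base_lr > 0, n_groups >= 1, decay > 0)
  base_lr / decay^((n_groups - 1):0)
}

#' Gradual-unfreezing stage plan
#'
#' @param unfrozen_groups Integer vector: number of top layer groups
#'   trainable in each stage (strictly increasing).
#' @param base_lr Per-stage base learning rate (top group).
#' @param epochs Per-stage epoch count.
#' @param lr_decay_factor Discriminative decay between adjacent groups.
#' @return A `stage_plan`.
#' @export
stage_plan <- function(unfrozen_groups, base_lr, epochs,
                       lr_decay_factor = 2.6) {
  n <- length(unfrozen_groups)
  stopifnot(n >= 1, length(base_lr) == n, length(epochs) == n,
            all(base_lr > 0), all(epochs >= 1))
  if (n > 1 && any(diff(unfrozen_groups) <= 0)) {
    stop("stage plan must unfreeze strictly more groups at every stage",
         call. = FALSE)
  }
  structure(list(stages = data.frame(unfrozen_groups = as.integer(unfrozen_groups),
                                     base_lr = base_lr,
                                     epochs = as.integer(epochs)),
                 lr_decay_factor = lr_decay_factor),
            class = "stage_plan")
}

#' The default four-stage fine-tuning plan
#'
#' Head only at base rate 3e-2 for 4 epochs; head + final LSTM layer at
#' 5e-3 for 4; head + final two LSTM layers at 5e-4 for 4; full model at
#' 5e-5 for 6. Discriminative decay 2.6 between adjacent groups.
#'
#' @return A `stage_plan`.
#' @export
default_stage_plan <- function() {
  stage_plan(unfrozen_groups = 1:4,
             base_lr = c(3e-2, 5e-3, 5e-4, 5e-5),
             epochs = c(4L, 4L, 4L, 6L),
             lr_decay_factor = 2.6)
}

#' Desk-scale four-stage fine-tuning plan
#'
#' The published stage rates pair a GPU-scale encoder with thousands of
#' training molecules; at desk scale (tiny encoder, a few hundred
#' molecules) their late-stage rates are too small to move the deeper
#' groups at all. This plan keeps the same gradual-unfreezing structure and
#' discriminative decay but uses rates and epoch counts calibrated for the
#' synthetic benchmark; both arms of the paired transfer experiment share
#' it.
#'
#' @param epochs Per-stage epoch counts (length 4).
#' @return A `stage_plan`.
#' @export
desk_stage_plan <- function(epochs = c(3L, 3L, 3L, 6L)) {
  stage_plan(unfrozen_groups = 1:4,
             base_lr = c(1e-2, 5e-3, 2e-3, 1e-3),
             epochs = epochs,
             lr_decay_factor = 2.6)
}

#' @export
print.stage_plan <- function(x, ...) {
  cat("<stage_plan> decay", x$lr_decay_factor, "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Partition model parameters into ordered layer groups
#'
#' Bottom to top: (1) embedding plus all LSTM layers below the final two,
#' (2) the second-to-last LSTM layer, (3) the last LSTM layer, (4) the task
#' head (softmax decoder for the language model; the pooled feed-forward
#' head for QSAR models). Unfreezing "k groups" enables the top k. Groups
#' are disjoint and jointly exhaustive over the model's parameters.
#'
#' @param model An `mft_model`.
#' @return List of character vectors of parameter names, bottom to top.
#' @export
layer_groups <- function(model) {
  stopifnot(inherits(model, "mft_model"))
  L <- model$enc$n_layers
  layer_names <- function(l) paste0(c("lstm_Wx_", "lstm_Wh_", "lstm_b_"), l)
  head_names <- if (model$kind == "mspm") {
    c(if (!model$enc$tie_weights) "dec_W", "dec_b")
  } else {
    c("head_bn1_g", "head_bn1_b", "head_W1", "head_b1",
      "head_bn2_g", "head_bn2_b", "head_W2", "head_b2")
  }
  groups <- if (L >= 2L) {
    lower <- if (L >= 3L) unlist(lapply(seq_len(L - 2L), layer_names)) else character(0)
    list(c("emb", lower), layer_names(L - 1L), layer_names(L), head_names)
  } else {
    list("emb", layer_names(1L), head_names)
  }
  stopifnot(setequal(unlist(groups), names(model$params)))
  groups
}
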