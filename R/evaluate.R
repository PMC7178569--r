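# Metrics, split protocols, test-time-augmentation prediction and the
# repeated-split benchmark harness.

#' Root-mean-square error
#' @param truth,pred Equal-length numeric vectors.
#' @return Non-negative RMSE.
#' @export
rmse <- function(truth, pred) {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop("`truth` and `pred` must be equal-length, non-empty", call. = FALSE)
  }
  sqrt(mean((truth - pred)^2))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, ties counted one half; computed from midranks, which is
#' exactly equivalent to the pairwise count.
#'
#' @param labels Binary vector (1 = positive, 0 = negative); both classes
#'   must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores) || length(labels) == 0L) {
    stop("`labels` and `scores` must be equal-length, non-empty", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Split specification
#'
#' @param fractions Train/valid/test fractions, positive, summing to 1.
#' @param mode `"random"` or `"scaffold"`.
#' @param seed Integer seed.
#' @param n_repeats Number of repeated splits for benchmarking.
#' @return A `split_spec`.
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1),
                       mode = c("random", "scaffold"), seed = 0L,
                       n_repeats = 10L) {
  mode <- match.arg(mode)
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9, n_repeats >= 1L)
  structure(list(fractions = fractions, mode = mode, seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats)),
            class = "split_spec")
}

# Partition sizes: train and valid take the floor, the remainder goes to
# test, so splits are reproducible across implementations.
split_sizes <- function(n, fractions) {
  n_train <- floor(fractions[1] * n)
  n_valid <- floor(fractions[2] * n)
  c(train = n_train, valid = n_valid, test = n - n_train - n_valid)
}

#' Random three-way split
#' @param n Number of records (or a data.frame).
#' @param spec A [split_spec()].
#' @return List of disjoint, exhaustive index vectors `train`, `valid`,
#'   `test`.
#' @export
random_split <- function(n, spec = split_spec()) {
  if (is.data.frame(n)) n <- nrow(n)
  sz <- split_sizes(n, spec$fractions)
  perm <- with_seed(spec$seed, sample.int(n))
  list(train = sort(perm[seq_len(sz["train"])]),
       valid = sort(perm[sz["train"] + seq_len(sz["valid"])]),
       test = sort(perm[sz["train"] + sz["valid"] + seq_len(sz["test"])]))
}

#' Scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold and assigns whole groups to
#' partitions, so no scaffold spans the train/test boundary. Groups are
#' placed largest-first (ties broken by scaffold text) into train until its
#' target size is reached, then valid, then test. Acyclic molecules (empty
#' scaffold) form one shared group by default.
#'
#' @param dataset Molecule-record data.frame with `canonical_smiles`.
#' @param spec A [split_spec()].
#' @param acyclic_singletons Treat every acyclic molecule as its own group?
#' @return List of index vectors `train`, `valid`, `test`.
#' @export
scaffold_split <- function(dataset, spec = split_spec(mode = "scaffold"),
                           acyclic_singletons = FALSE) {
  n <- nrow(dataset)
  scaf <- vapply(dataset$canonical_smiles, murcko_scaffold, "",
                 USE.NAMES = FALSE)
  if (acyclic_singletons) {
    empty <- !nzchar(scaf)
    scaf[empty] <- paste0("<acyclic:", which(empty), ">")
  }
  groups <- split(seq_len(n), scaf)
  ord <- order(-lengths(groups), names(groups), method = "radix")
  groups <- groups[ord]
  sz <- split_sizes(n, spec$fractions)
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (g in groups) {
    if (length(out$train) < sz["train"]) {
      out$train <- c(out$train, g)
    } else if (length(out$valid) < sz["valid"]) {
      out$valid <- c(out$valid, g)
    } else {
      out$test <- c(out$test, g)
    }
  }
  lapply(out, sort)
}

#' Write split indices as JSON
#' @param split List of index vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split, path)
  invisible(path)
}

#' Read split indices from JSON (externally supplied splits honored as-is)
#' @param path JSON file with `train`/`valid`/`test` index lists.
#' @return List of integer index vectors.
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("train", "valid", "test") %in% names(x)))
  lapply(x[c("train", "valid", "test")], as.integer)
}

#' Predict one molecule with test-time augmentation
#'
#' Runs the model on the canonical SMILES plus `n_tta` enumerated variants
#' and aggregates by the arithmetic mean — of the raw regression output, or
#' of the positive-class probability for binary classification (set
#' `average = "logit"` to average logits instead).
#'
#' @param model Trained QSAR `mft_model`.
#' @param smiles A single SMILES.
#' @param task `"regression"` or `"classification"`.
#' @param n_tta Variants in addition to the canonical form (default 4).
#' @param seed Integer seed fixing the variant set.
#' @param truth Optional reference label carried into the result.
#' @param average `"probability"` or `"logit"` aggregation (classification).
#' @return A `prediction_set`: variants, per-variant predictions, and the
#'   aggregate prediction.
#' @export
predict_with_tta <- function(model, smiles, task = c("regression",
                                                     "classification"),
                             n_tta = 4L, seed = 0L, truth = NULL,
                             average = c("probability", "logit")) {
  task <- match.arg(task)
  average <- match.arg(average)
  variants <- make_tta_variants(smiles, n_tta = n_tta, seed = seed)
  pred <- predict_qsar(model, variants, task = task)
  if (task == "regression") {
    per_variant <- as.numeric(pred)
    aggregate <- mean(per_variant)
  } else {
    p <- pred[, 2L]
    if (average == "logit") {
      lg <- log(pmax(p, 1e-12)) - log(pmax(1 - p, 1e-12))
      per_variant <- lg
      aggregate <- stats::plogis(mean(lg))
    } else {
      per_variant <- p
      aggregate <- mean(p)
    }
  }
  structure(list(smiles = smiles, variants = variants,
                 per_variant = per_variant, aggregate = aggregate,
                 truth = truth),
            class = "prediction_set")
}

# Batched TTA over a whole test set: one prediction pass over all variant
# strings, then a per-molecule mean.
tta_predict_set <- function(model, smiles, task, n_tta = 4L, seed = 0L,
                            batch_size = 64L) {
  variant_sets <- lapply(seq_along(smiles), function(i) {
    make_tta_variants(smiles[i], n_tta = n_tta, seed = seed + i)
  })
  flat <- unlist(variant_sets)
  owner <- rep(seq_along(smiles), lengths(variant_sets))
  pred <- predict_qsar(model, flat, task = task, batch_size = batch_size)
  if (task == "regression") {
    as.numeric(tapply(as.numeric(pred), owner, mean))
  } else {
    as.numeric(tapply(pred[, 2L], owner, mean))
  }
}

#' Benchmark a model configuration over repeated splits
#'
#' For each repeat: split the data, augment the training partition only
#' (labels of validation and test molecules are never perturbed), fine-tune
#' a QSAR model (transferred from `pretrained` when given, from scratch
#' otherwise), and score the test set with and without test-time
#' augmentation. RMSE for regression, AUROC for classification.
#'
#' @param dataset Labelled molecule-record data.frame.
#' @param task `"regression"` or `"classification"`.
#' @param enc,head Model configurations ([encoder_config()],
#'   [classifier_config()]).
#' @param plan A [stage_plan()].
#' @param spec A [split_spec()]; `spec$n_repeats` splits are run with seeds
#'   `spec$seed + 0:(n_repeats-1)`.
#' @param pretrained Optional pretrained `mft_model` of kind `"mspm"`.
#' @param vocab Vocabulary (defaults to the pretrained model's, or is built
#'   from the dataset).
#' @param aug_spec Optional [augmentation_spec()] for the training set.
#' @param n_tta TTA variants per test molecule.
#' @param batch_size Fine-tuning batch size.
#' @return A `metrics_report`: per-split values (canonical and TTA), their
#'   means and standard deviations.
#' @export
run_benchmark <- function(dataset, task = c("regression", "classification"),
                          enc = encoder_config(), head = NULL,
                          plan = default_stage_plan(),
                          spec = split_spec(), pretrained = NULL,
                          vocab = NULL, aug_spec = NULL, n_tta = 4L,
                          batch_size = 128L) {
  task <- match.arg(task)
  if (is.null(vocab)) {
    vocab <- if (!is.null(pretrained) && !is.null(pretrained$vocab)) {
      pretrained$vocab
    } else {
      build_vocab(lapply(dataset$canonical_smiles, tokenize_smiles))
    }
  }
  if (is.null(head)) {
    out_dim <- if (task == "regression") 1L
               else max(2L, length(unique(dataset$class_id)))
    head <- classifier_config(output_dim = out_dim)
  }
  vals <- numeric(spec$n_repeats)
  vals_tta <- numeric(spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    rspec <- spec
    rspec$seed <- spec$seed + r - 1L
    idx <- if (spec$mode == "scaffold") scaffold_split(dataset, rspec)
           else random_split(dataset, rspec)
    train <- dataset[idx$train, , drop = FALSE]
    test <- dataset[idx$test, , drop = FALSE]
    if (!is.null(aug_spec)) {
      train <- if (task == "regression") {
        augment_regression(train, aug_spec, seed = rspec$seed)
      } else {
        augment_classification(train, aug_spec, seed = rspec$seed)
      }
    }
    model <- build_qsar(vocab, enc = enc, head = head, seed = rspec$seed)
    if (!is.null(pretrained)) {
      model <- transfer_encoder(pretrained, model,
                                source_vocab = pretrained$vocab,
                                target_vocab = vocab)
    }
    fit <- finetune_qsar(model, train, plan, task = task, vocab = vocab,
                         batch_size = batch_size, seed = rspec$seed)
    pred_can <- predict_qsar(fit$model, test$canonical_smiles, task = task)
    score_can <- if (task == "regression") {
      rmse(test$label, pred_can)
    } else {
      auroc(test$class_id, pred_can[, 2L])
    }
    pred_tta <- tta_predict_set(fit$model, test$canonical_smiles, task,
                                n_tta = n_tta, seed = rspec$seed)
    score_tta <- if (task == "regression") {
      rmse(test$label, pred_tta)
    } else {
      auroc(test$class_id, pred_tta)
    }
    vals[r] <- score_can
    vals_tta[r] <- score_tta
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  structure(list(metric_name = if (task == "regression") "RMSE" else "AUROC",
                 canonical = vals, tta = vals_tta,
                 mean = mean(vals), sd = sd0(vals),
                 mean_tta = mean(vals_tta), sd_tta = sd0(vals_tta),
                 n_repeats = spec$n_repeats),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s over %d splits\n", x$metric_name,
              x$n_repeats))
  cat(sprintf("  canonical: %.4f +/- %.4f\n", x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  cat(sprintf("  TTA:       %.4f +/- %.4f\n", x$mean_tta,
              if (is.na(x$sd_tta)) 0 else x$sd_tta))
  invisible(x)
}
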