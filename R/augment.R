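# SMILES-enumeration data augmentation: training-set augmentation with
# Gaussian label noise (regression) or class rebalancing (classification),
# and test-time augmentation (TTA).

#' Augmentation settings
#'
#' @param n_augment Number of enumerated variants requested per molecule
#'   (regression and language-model corpora).
#' @param sigma_noise Standard deviation of the zero-mean Gaussian noise
#'   added to the labels of augmented regression variants. The original
#'   record always keeps its unperturbed label.
#' @param per_class_counts Named vector mapping class id to the number of
#'   variants per molecule of that class (classification rebalancing).
#' @param max_attempt_factor Up to `n * max_attempt_factor` randomized
#'   draws are made before fewer than `n` distinct variants are returned.
#' @param count_mode `"additional"` (default): "augmented N times" means N
#'   variants in addition to the retained original; `"total"`: N records
#'   per molecule in total, the original included.
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(n_augment = 0L, sigma_noise = 0,
                              per_class_counts = NULL,
                              max_attempt_factor = 10L,
                              count_mode = c("additional", "total")) {
  count_mode <- match.arg(count_mode)
  stopifnot(n_augment >= 0L, sigma_noise >= 0, max_attempt_factor >= 1L)
  if (!is.null(per_class_counts)) {
    if (is.null(names(per_class_counts)) || any(per_class_counts < 0)) {
      stop("`per_class_counts` must be a named, non-negative vector",
           call. = FALSE)
    }
  }
  structure(list(n_augment = as.integer(n_augment),
                 sigma_noise = sigma_noise,
                 per_class_counts = per_class_counts,
                 max_attempt_factor = as.integer(max_attempt_factor),
                 count_mode = count_mode),
            class = "augmentation_spec")
}

#' Named augmentation presets for the benchmark endpoints
#'
#' The per-dataset settings used with the four benchmark endpoints:
#' lipophilicity (25 variants, label noise sd 0.3), FreeSolv (50 variants,
#' sd 0.5), HIV (active class 60 variants, inactive 2), and BBBP (positive
#' class 10 variants, negative 30). Class id 1 denotes the positive/active
#' class.
#'
#' @param name One of `"lipophilicity"`, `"freesolv"`, `"hiv"`, `"bbbp"`.
#' @return An `augmentation_spec`.
#' @export
augmentation_preset <- function(name = c("lipophilicity", "freesolv",
                                         "hiv", "bbbp")) {
  switch(match.arg(name),
    lipophilicity = augmentation_spec(n_augment = 25L, sigma_noise = 0.3),
    freesolv = augmentation_spec(n_augment = 50L, sigma_noise = 0.5),
    hiv = augmentation_spec(per_class_counts = c("1" = 60L, "0" = 2L)),
    bbbp = augmentation_spec(per_class_counts = c("1" = 10L, "0" = 30L)))
}

# Draw up to n distinct randomized variants of one parsed molecule,
# each different from `canonical` when possible, using the active RNG.
draw_variants <- function(g, canonical, n, max_attempt_factor) {
  if (n <= 0L) return(character(0))
  out <- character(0)
  attempts <- 0L
  max_attempts <- n * max_attempt_factor
  while (length(out) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    s <- smiles_write(g, sample.int(g$n))
    if (s != canonical && !(s %in% out)) out <- c(out, s)
  }
  out
}

#' Enumerate distinct randomized SMILES variants of one molecule
#'
#' Returns up to `n` distinct randomized SMILES, each different from the
#' canonical form when the molecule admits alternatives. Up to
#' `n * max_attempt_factor` draws are made before giving up and returning
#' fewer (small, symmetric molecules may admit very few variants).
#' Deterministic under a fixed seed.
#'
#' @param smiles A valid SMILES string (canonical form recommended).
#' @param n Number of variants requested.
#' @param seed Integer RNG seed.
#' @param max_attempt_factor Attempt budget multiplier.
#' @return Character vector of at most `n` distinct SMILES.
#' @export
enumerate_variants <- function(smiles, n, seed, max_attempt_factor = 10L) {
  stopifnot(n >= 0L)
  g <- smiles_parse(smiles)
  canonical <- canonicalize(smiles)
  with_seed(seed, draw_variants(g, canonical, n, max_attempt_factor))
}

augment_core <- function(dataset, counts, spec, seed, noise) {
  stopifnot(is.data.frame(dataset), nrow(dataset) == length(counts))
  rows <- with_seed(seed, lapply(seq_len(nrow(dataset)), function(i) {
    rec <- dataset[i, ]
    n_var <- counts[i]
    if (spec$count_mode == "total") n_var <- max(0L, n_var - 1L)
    g <- smiles_parse(rec$canonical_smiles)
    vars <- draw_variants(g, rec$canonical_smiles, n_var,
                          spec$max_attempt_factor)
    k <- length(vars)
    lab <- rec$label
    if (noise && k > 0L && spec$sigma_noise > 0) {
      aug_lab <- lab + stats::rnorm(k, 0, spec$sigma_noise)
    } else {
      aug_lab <- rep(lab, k)
    }
    data.frame(raw_smiles = c(rec$canonical_smiles, vars),
               canonical_smiles = rec$canonical_smiles,
               label = c(lab, aug_lab),
               class_id = rec$class_id,
               is_augmented = c(FALSE, rep(TRUE, k)),
               parent_id = i,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Augment a regression training set by SMILES enumeration
#'
#' Each molecule contributes its original record with the label unchanged,
#' plus up to `spec$n_augment` enumerated variants whose labels are
#' perturbed by independent Gaussian noise with standard deviation
#' `spec$sigma_noise` (a simulation of experimental error). Reproducible
#' under a fixed seed.
#'
#' @param dataset Molecule-record data.frame with real-valued `label`s.
#' @param spec An [augmentation_spec()].
#' @param seed Integer RNG seed.
#' @return Augmented data.frame with a `parent_id` column mapping every
#'   record to its source molecule row.
#' @export
augment_regression <- function(dataset, spec, seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (anyNA(dataset$label)) {
    stop("regression augmentation requires a label on every record",
         call. = FALSE)
  }
  augment_core(dataset, rep(spec$n_augment, nrow(dataset)), spec, seed,
               noise = TRUE)
}

#' Augment a classification training set, rebalancing classes
#'
#' Molecules of class `c` receive up to `spec$per_class_counts[c]`
#' enumerated variants; class labels are copied to variants unperturbed.
#' With all requested variants available, the achieved class ratio equals
#' `(1 + a_pos) * n_pos : (1 + a_neg) * n_neg`.
#'
#' @inheritParams augment_regression
#' @export
augment_classification <- function(dataset, spec, seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (anyNA(dataset$class_id)) {
    stop("classification augmentation requires a class id on every record",
         call. = FALSE)
  }
  if (is.null(spec$per_class_counts)) {
    stop("`spec$per_class_counts` is required for classification",
         call. = FALSE)
  }
  key <- as.character(dataset$class_id)
  missing <- setdiff(unique(key), names(spec$per_class_counts))
  if (length(missing) > 0L) {
    stop("no per-class count for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- as.integer(spec$per_class_counts[key])
  augment_core(dataset, counts, spec, seed, noise = FALSE)
}

#' Test-time augmentation variants of one molecule
#'
#' Returns the canonical SMILES followed by up to `n_tta` distinct
#' randomized variants. Labels are never attached or perturbed at test
#' time. With `n_tta = 0` this reduces to canonical-only evaluation.
#'
#' @param smiles A valid SMILES string.
#' @param n_tta Number of variants in addition to the canonical form
#'   (default 4, i.e. predictions averaged over 5 strings).
#' @param seed Integer RNG seed.
#' @return Character vector: canonical SMILES first, then the variants.
#' @export
make_tta_variants <- function(smiles, n_tta = 4L, seed = 0L) {
  stopifnot(n_tta >= 0L)
  canonical <- canonicalize(smiles)
  g <- smiles_parse(canonical)
  c(canonical, with_seed(seed, draw_variants(g, canonical, n_tta, 10L)))
}

#' Achieved class ratio of a classification dataset
#' @param dataset Data.frame with a `class_id` column.
#' @param positive Class id regarded as positive (default 1).
#' @return Ratio of positive to negative record counts.
#' @export
class_ratio <- function(dataset, positive = 1L) {
  pos <- sum(dataset$class_id == positive)
  neg <- sum(dataset$class_id != positive)
  pos / neg
}

#' Write an augmented dataset as CSV
#' @param dataset Augmented data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_augmented_csv <- function(dataset, path) {
  cols <- intersect(c("raw_smiles", "label", "class_id", "parent_id",
                      "is_augmented"), names(dataset))
  cols <- cols[vapply(cols, function(cl) !all(is.na(dataset[[cl]])), TRUE)]
  out <- dataset[, cols]
  names(out)[names(out) == "raw_smiles"] <- "smiles"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
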