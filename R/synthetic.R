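# Seeded generator of valid synthetic SMILES corpora and labelled QSAR
# datasets. Molecules are assembled as random trees over heavy atoms with
# explicit valence bookkeeping, optionally carrying one or two 5/6-membered
# rings (aromatic or saturated); canonical text and final validity are
# delegated to the chemistry backend. Labels derive from backend-computable
# structure counts only, so ground truth is unambiguous under SMILES
# enumeration.

STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L)

#' Specification for the synthetic-data generator
#'
#' @param n_molecules Number of distinct molecules to generate.
#' @param atom_alphabet Subset of `c("C","N","O","S","F")` to draw heavy
#'   atoms from (carbon-weighted).
#' @param ring_prob Probability that a molecule carries a ring; a second
#'   ring is added with the same probability when size permits.
#' @param size_range Inclusive range of heavy-atom counts per molecule.
#' @param label_model Coefficients of the latent property
#'   `y = a * (#N atoms) + b * (#rings) + c * (#heavy atoms) + eps` with
#'   `eps ~ Normal(0, noise_sd^2)`.
#' @param class_rule Binary labelling rule: molecules whose noiseless
#'   latent `y` exceeds an auto-tuned threshold are positives, targeting
#'   `positive_fraction`.
#' @param seed Integer RNG seed.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_molecules = 1000L,
                       atom_alphabet = c("C", "N", "O", "S", "F"),
                       ring_prob = 0.4,
                       size_range = c(4L, 16L),
                       label_model = list(a = 1.0, b = 0.5, c = 0.1,
                                          noise_sd = 0.1),
                       class_rule = list(positive_fraction = 0.5),
                       seed = 1L) {
  stopifnot(n_molecules >= 1L, length(size_range) == 2L,
            size_range[1] >= 1L, size_range[2] >= size_range[1],
            all(atom_alphabet %in% names(STANDARD_VALENCE)),
            ring_prob >= 0, ring_prob <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 atom_alphabet = atom_alphabet,
                 ring_prob = ring_prob,
                 size_range = as.integer(size_range),
                 label_model = label_model,
                 class_rule = class_rule,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Motif library: molecules are assembled from recurring substructures the
# way real small-molecule collections are — ring systems plus common
# functional groups — rather than from atom-by-atom noise, so a language
# model has local structure to learn. Each motif is a template SMILES whose
# FIRST atom is the attachment point; `needs` lists required alphabet
# elements and `kind` separates ring systems from substituent groups.
MOTIF_LIBRARY <- list(
  list(smiles = "c1ccccc1", kind = "ring", needs = "C"),
  list(smiles = "c1ccncc1", kind = "ring", needs = c("C", "N")),
  list(smiles = "c1cc[nH]c1", kind = "ring", needs = c("C", "N")),
  list(smiles = "C1CCCCC1", kind = "ring", needs = "C"),
  list(smiles = "C1CCOC1", kind = "ring", needs = c("C", "O")),
  list(smiles = "C1CCNC1", kind = "ring", needs = c("C", "N")),
  list(smiles = "C(=O)O", kind = "group", needs = c("C", "O")),
  list(smiles = "C(=O)N", kind = "group", needs = c("C", "N", "O")),
  list(smiles = "C(C)=O", kind = "group", needs = c("C", "O")),
  list(smiles = "C#N", kind = "group", needs = c("C", "N")),
  list(smiles = "OC", kind = "group", needs = c("C", "O")),
  list(smiles = "N", kind = "group", needs = "N"),
  list(smiles = "NC", kind = "group", needs = c("C", "N")),
  list(smiles = "SC", kind = "group", needs = c("C", "S")),
  list(smiles = "S", kind = "group", needs = "S"),
  list(smiles = "F", kind = "group", needs = "F"),
  list(smiles = "O", kind = "group", needs = "O"),
  list(smiles = "C", kind = "group", needs = "C"),
  list(smiles = "CC", kind = "group", needs = "C"),
  list(smiles = "C(C)C", kind = "group", needs = "C"))

# Remaining bonding capacity of every atom in a parsed template/graph.
# Aromatic bonds count as order 1.5, so a benzene carbon keeps one free
# slot and a pyridine nitrogen none; bracket atoms with explicit hydrogens
# are left exactly as written.
free_valences <- function(g) {
  order_of <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
  used <- numeric(g$n)
  for (b in seq_along(g$b_from)) {
    o <- order_of[[g$b_type[b]]]
    used[g$b_from[b]] <- used[g$b_from[b]] + o
    used[g$b_to[b]] <- used[g$b_to[b]] + o
  }
  fv <- integer(g$n)
  for (a in seq_len(g$n)) {
    fv[a] <- if (g$bracket[a] && !is.na(g$hcount[a])) {
      0L
    } else {
      max(0L, as.integer(floor(STANDARD_VALENCE[[g$element[a]]] - used[a])))
    }
  }
  fv
}

# Parsed motif templates with precomputed free valences, filtered to an
# alphabet; cached per alphabet.
motif_templates <- local({
  cache <- list()
  function(alphabet) {
    key <- paste(sort(alphabet), collapse = "")
    if (is.null(cache[[key]])) {
      keep <- Filter(function(m) all(m$needs %in% alphabet), MOTIF_LIBRARY)
      cache[[key]] <<- lapply(keep, function(m) {
        g <- smiles_parse(m$smiles)
        fv <- free_valences(g)
        fv[1L] <- fv[1L] - 1L  # attachment bond consumes one slot
        list(g = g, fv = fv, kind = m$kind, size = g$n)
      })
    }
    cache[[key]]
  }
})

# Build one random molecular graph by seeded motif assembly; returns a
# mol_graph or NULL when the draw is infeasible.
random_molecule_graph <- function(spec) {
  n_heavy <- if (spec$size_range[1] == spec$size_range[2]) spec$size_range[1]
             else sample(spec$size_range[1]:spec$size_range[2], 1L)
  templates <- motif_templates(spec$atom_alphabet)
  if (length(templates) == 0L) return(NULL)
  sizes <- vapply(templates, `[[`, 0L, "size")
  kinds <- vapply(templates, `[[`, "", "kind")

  element <- character(0); aromatic <- logical(0); free <- integer(0)
  hcount <- integer(0); bracket <- logical(0)
  b_from <- integer(0); b_to <- integer(0); b_type <- character(0)

  splice <- function(tpl, anchor) {
    base <- length(element)
    g <- tpl$g
    element <<- c(element, g$element)
    aromatic <<- c(aromatic, g$aromatic)
    hcount <<- c(hcount, g$hcount)
    bracket <<- c(bracket, g$bracket)
    fv <- tpl$fv
    if (is.na(anchor)) fv[1L] <- fv[1L] + 1L  # no link bond for the seed
    free <<- c(free, fv)
    b_from <<- c(b_from, g$b_from + base)
    b_to <<- c(b_to, g$b_to + base)
    b_type <<- c(b_type, g$b_type)
    if (!is.na(anchor)) {
      b_from <<- c(b_from, anchor); b_to <<- c(b_to, base + 1L)
      b_type <<- c(b_type, "1")
      free[anchor] <<- free[anchor] - 1L
    }
  }

  ring_ok <- kinds == "ring"
  # seed motif: a ring system with probability ring_prob, else a group
  seed_pool <- if (any(ring_ok) && stats::runif(1) < spec$ring_prob &&
                   any(sizes[ring_ok] <= n_heavy)) {
    which(ring_ok & sizes <= n_heavy)
  } else {
    which(!ring_ok & sizes <= n_heavy)
  }
  if (length(seed_pool) == 0L) seed_pool <- which(sizes <= n_heavy)
  if (length(seed_pool) == 0L) return(NULL)
  splice(templates[[seed_pool[sample.int(length(seed_pool), 1L)]]],
         NA_integer_)

  while (length(element) < n_heavy) {
    open <- which(free >= 1L)
    if (length(open) == 0L) break
    budget <- n_heavy - length(element)
    allow_ring <- stats::runif(1) < spec$ring_prob / 2
    pool <- which(sizes <= budget & (allow_ring | kinds == "group"))
    if (length(pool) == 0L) pool <- which(sizes <= budget)
    if (length(pool) == 0L) break
    anchor <- open[sample.int(length(open), 1L)]
    splice(templates[[pool[sample.int(length(pool), 1L)]]], anchor)
  }

  if (length(element) == 0L) return(NULL)
  n <- length(element)
  structure(list(element = element, aromatic = aromatic,
                 charge = integer(n), isotope = integer(n),
                 hcount = hcount, bracket = bracket,
                 b_from = b_from, b_to = b_to, b_type = b_type, n = n),
            class = "mol_graph")
}

#' Generate a corpus of distinct synthetic molecules
#'
#' Molecules are drawn by seeded random assembly until `n_molecules`
#' distinct canonical SMILES have been collected; every generated string
#' parses, canonicalizes, and survives corpus curation. A generation error
#' is raised when the requested count is infeasible within the attempt
#' budget (e.g. a degenerate `size_range`).
#'
#' @param spec A [synth_spec()].
#' @return A molecule-record data.frame with attribute `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  target <- spec$n_molecules
  seen <- character(0)
  with_seed(spec$seed, {
    attempts <- 0L
    max_attempts <- max(200L, 30L * target)
    while (length(seen) < target && attempts < max_attempts) {
      batch_n <- min(max(64L, target - length(seen)),
                     max_attempts - attempts)
      raw <- character(0)
      for (i in seq_len(batch_n)) {
        g <- random_molecule_graph(spec)
        attempts <- attempts + 1L
        if (!is.null(g)) raw <- c(raw, smiles_write(g, sample.int(g$n)))
      }
      can <- ob_canonical(raw)
      can <- can[!is.na(can)]
      seen <- unique(c(seen, can))
    }
  })
  if (length(seen) < target) {
    stop("generation error: could only produce ", length(seen),
         " distinct molecules for a request of ", target, call. = FALSE)
  }
  out <- data.frame(raw_smiles = seen[seq_len(target)],
                    canonical_smiles = seen[seq_len(target)],
                    label = NA_real_, class_id = NA_integer_,
                    is_augmented = FALSE, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

# Structure counts feeding the latent label.
structure_counts <- function(smiles) {
  graphs <- lapply(smiles, smiles_parse)
  data.frame(
    n_nitrogen = vapply(graphs, function(g) sum(g$element == "N"), 0L),
    n_rings = vapply(graphs, function(g) {
      length(g$b_from) - g$n + max(mol_components(g))
    }, 0L),
    n_heavy = vapply(graphs, function(g) sum(g$element != "H"), 0L))
}

latent_labels <- function(records, lm) {
  cts <- structure_counts(records$canonical_smiles)
  list(y = lm$a * cts$n_nitrogen + lm$b * cts$n_rings + lm$c * cts$n_heavy,
       counts = cts)
}

#' Generate a labelled synthetic regression dataset
#'
#' Labels follow `y = a * #N + b * #rings + c * #heavy + eps` with
#' `eps ~ Normal(0, noise_sd^2)`, computed from true structural counts of
#' the canonical form (so two renderings of one molecule always agree).
#' The generating coefficients and the count matrix are stored as
#' attributes for recovery tests; generation fails if the count matrix is
#' rank-deficient (labels would not be identifiable).
#'
#' @param spec A [synth_spec()].
#' @return Molecule records with numeric `label`, plus attributes
#'   `truth` (coefficients) and `counts`.
#' @export
generate_regression_dataset <- function(spec) {
  records <- generate_corpus(spec)
  lm <- spec$label_model
  lat <- latent_labels(records, lm)
  eps <- with_seed(spec$seed + 1L,
                   stats::rnorm(nrow(records), 0, lm$noise_sd))
  records$label <- lat$y + eps
  X <- cbind(1, as.matrix(lat$counts))
  if (qr(X)$rank < ncol(X)) {
    stop("generation error: structure-count matrix is rank-deficient; ",
         "label coefficients would not be identifiable", call. = FALSE)
  }
  attr(records, "truth") <- lm
  attr(records, "counts") <- lat$counts
  records
}

#' Generate a labelled synthetic classification dataset
#'
#' Binary classes are assigned by thresholding the noiseless latent
#' property at the quantile matching `class_rule$positive_fraction`
#' (class 1 above the threshold). A generation error is raised if the
#' achieved positive fraction misses the target by more than 20% relative
#' (possible only under extreme label ties) or if a class is empty.
#'
#' @param spec A [synth_spec()].
#' @return Molecule records with integer `class_id` (1 = positive), plus
#'   attributes `truth` and `threshold`.
#' @export
generate_classification_dataset <- function(spec) {
  records <- generate_corpus(spec)
  lat <- latent_labels(records, spec$label_model)
  frac <- spec$class_rule$positive_fraction
  stopifnot(frac > 0, frac < 1)
  thr <- stats::quantile(lat$y, probs = 1 - frac, names = FALSE, type = 1)
  cls <- as.integer(lat$y > thr)
  achieved <- mean(cls)
  if (achieved == 0 || achieved == 1 ||
      abs(achieved - frac) > 0.2 * frac) {
    # ties at the threshold can starve the positive class; nudge downward
    thr2 <- max(lat$y[lat$y < thr], -Inf)
    cls2 <- as.integer(lat$y > thr2)
    if (abs(mean(cls2) - frac) < abs(achieved - frac)) cls <- cls2
    achieved <- mean(cls)
    if (achieved == 0 || achieved == 1 || abs(achieved - frac) > 0.2 * frac) {
      stop("generation error: achieved positive fraction ", achieved,
           " misses target ", frac, call. = FALSE)
    }
  }
  records$class_id <- cls
  attr(records, "truth") <- spec$label_model
  attr(records, "threshold") <- thr
  records
}
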