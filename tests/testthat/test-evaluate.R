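test_that("rmse matches a direct loop oracle", {
  expect_identical(rmse(c(1, 2), c(1, 2)), 0)
  expect_identical(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2), tolerance = 1e-15)
  loop_rmse <- function(truth, pred) {
    acc <- 0
    for (i in seq_along(truth)) acc <- acc + (truth[i] - pred[i])^2
    sqrt(acc / length(truth))
  }
  for (seed in 1:20) {
    n <- with_seed(seed, sample(2:80, 1L))
    truth <- with_seed(seed + 100L, stats::rnorm(n))
    pred <- with_seed(seed + 200L, stats::rnorm(n))
    expect_equal(rmse(truth, pred), loop_rmse(truth, pred),
                 tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:2), "equal-length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("auroc equals the exhaustive pairwise oracle, ties counted one half", {
  expect_identical(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_identical(auroc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)

  pairwise <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  for (seed in 1:100) {
    n <- with_seed(seed, sample(4:200, 1L))
    labels <- with_seed(seed + 300L,
                        c(0L, 1L, sample(0:1, n - 2L, replace = TRUE)))
    # coarse scores force plenty of ties
    scores <- with_seed(seed + 400L,
                        sample(seq(0, 1, by = 0.1), n, replace = TRUE))
    expect_equal(auroc(labels, scores), pairwise(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("random splits are sized, seeded, disjoint and exhaustive", {
  spec <- split_spec(seed = 3L)
  s <- random_split(100L, spec)
  expect_length(s$train, 80L)
  expect_length(s$valid, 10L)
  expect_length(s$test, 10L)
  expect_identical(sort(c(s$train, s$valid, s$test)), 1:100)
  expect_identical(s, random_split(100L, spec))
  s2 <- random_split(100L, split_spec(seed = 4L))
  expect_false(identical(s, s2))
  # remainder goes to test
  odd <- random_split(103L, spec)
  expect_length(odd$train, 82L)
  expect_length(odd$test, 103L - 82L - 10L)
})

test_that("scaffold splits never leak a scaffold across partitions", {
  ds <- generate_classification_dataset(synth_spec(n_molecules = 150L,
                                                   seed = 19L))
  s <- scaffold_split(ds, split_spec(mode = "scaffold", seed = 1L))
  expect_identical(sort(c(s$train, s$valid, s$test)), seq_len(nrow(ds)))
  scaf <- vapply(ds$canonical_smiles, murcko_scaffold, "", USE.NAMES = FALSE)
  ring <- nzchar(scaf)
  expect_length(intersect(scaf[s$train][ring[s$train]],
                          scaf[s$test][ring[s$test]]), 0L)
  expect_length(intersect(scaf[s$train][ring[s$train]],
                          scaf[s$valid][ring[s$valid]]), 0L)
  # molecules sharing a scaffold co-locate
  for (sc in unique(scaf[duplicated(scaf) & nzchar(scaf)])) {
    idx <- which(scaf == sc)
    part <- c(all(idx %in% s$train), all(idx %in% s$valid),
              all(idx %in% s$test))
    expect_true(any(part))
  }
})

test_that("unique-scaffold datasets degenerate to a plain sized split", {
  smiles <- c("CCO", "CCN", "CCC", "CCS", "CCF", "OCCO", "NCCN", "OCCN",
              "CC(C)O", "CC(C)N")
  ds <- molecule_records(smiles)
  s <- scaffold_split(ds, split_spec(mode = "scaffold", seed = 2L),
                      acyclic_singletons = TRUE)
  expect_length(s$train, 8L)
  expect_length(s$valid, 1L)
  expect_length(s$test, 1L)
})

test_that("externally supplied split files are honored exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  orig <- list(train = c(3L, 1L, 8L), valid = c(2L, 5L), test = c(4L, 6L, 7L))
  write_split(orig, path)
  back <- read_split(path)
  expect_identical(back, orig)
})

test_that("TTA prediction aggregates by the arithmetic mean", {
  vocab <- fixture_vocab()
  model <- build_qsar(vocab, test_encoder(), classifier_config(output_dim = 1L),
                      seed = 2L)
  ps <- predict_with_tta(model, "CC(=O)Oc1ccccc1C(=O)O",
                         task = "regression", n_tta = 4L, seed = 3L)
  expect_length(ps$variants, 5L)
  expect_identical(ps$variants[1], canonicalize("CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(ps$aggregate, mean(ps$per_variant), tolerance = 1e-15)

  ps0 <- predict_with_tta(model, "CC(=O)Oc1ccccc1C(=O)O",
                          task = "regression", n_tta = 0L)
  expect_equal(ps0$aggregate,
               as.numeric(predict_qsar(model, canonicalize("CC(=O)Oc1ccccc1C(=O)O"),
                                       task = "regression")),
               tolerance = 1e-12)

  cls <- build_qsar(vocab, test_encoder(), classifier_config(output_dim = 2L),
                    seed = 2L)
  pc <- predict_with_tta(cls, "Cc1cc[nH]c1", task = "classification",
                         n_tta = 3L, seed = 1L)
  expect_true(all(pc$per_variant >= 0 & pc$per_variant <= 1))
  expect_equal(pc$aggregate, mean(pc$per_variant), tolerance = 1e-15)
})

test_that("the repeated-split benchmark reports recomputable summaries", {
  ds <- generate_regression_dataset(synth_spec(n_molecules = 60L, seed = 23L))
  plan <- stage_plan(c(1L, 4L), c(5e-3, 1e-3), c(1L, 1L))
  rep <- run_benchmark(ds, task = "regression", enc = test_encoder(0),
                       plan = plan,
                       spec = split_spec(seed = 1L, n_repeats = 2L),
                       n_tta = 2L, batch_size = 16L)
  expect_identical(rep$metric_name, "RMSE")
  expect_length(rep$canonical, 2L)
  expect_equal(rep$mean, mean(rep$canonical), tolerance = 1e-15)
  expect_equal(rep$sd, stats::sd(rep$canonical), tolerance = 1e-15)
  expect_equal(rep$mean_tta, mean(rep$tta), tolerance = 1e-15)

  one <- run_benchmark(ds, task = "regression", enc = test_encoder(0),
                       plan = plan,
                       spec = split_spec(seed = 2L, n_repeats = 1L),
                       n_tta = 0L, batch_size = 16L)
  expect_identical(one$sd, 0)
})
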