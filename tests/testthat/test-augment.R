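test_that("variant enumeration respects count, distinctness and structure preservation", {
  expect_identical(enumerate_variants("CCO", 0L, seed = 1L), character(0))
  # single-atom molecule admits no alternative rendering
  expect_length(enumerate_variants("C", 5L, seed = 1L), 0L)

  for (s in c("Cc1cc[nH]c1", "CC(=O)Oc1ccccc1C(=O)O", "C1CCOC1CN")) {
    can <- canonicalize(s)
    vars <- enumerate_variants(can, 6L, seed = 3L)
    expect_false(any(duplicated(vars)))
    expect_false(can %in% vars)
    expect_true(all(canonicalize_all(vars) == can))
    expect_identical(vars, enumerate_variants(can, 6L, seed = 3L))
  }
})

test_that("regression augmentation keeps the original label and perturbs only variants", {
  ds <- molecule_records(c("CC(=O)Oc1ccccc1", "CCCNO"), label = c(2.5, -1))

  zero <- augment_regression(ds, augmentation_spec(n_augment = 5L,
                                                   sigma_noise = 0),
                             seed = 4L)
  expect_true(all(zero$label[zero$parent_id == 1L] == 2.5))
  expect_true(all(zero$label[zero$parent_id == 2L] == -1))

  noisy <- augment_regression(ds, augmentation_spec(n_augment = 5L,
                                                    sigma_noise = 0.3),
                              seed = 4L)
  originals <- noisy[!noisy$is_augmented, ]
  expect_identical(originals$label, c(2.5, -1))
  expect_identical(originals$raw_smiles, originals$canonical_smiles)
  variants <- noisy[noisy$is_augmented, ]
  expect_true(all(variants$label != ifelse(variants$parent_id == 1L, 2.5, -1)))
  expect_true(all(canonicalize_all(variants$raw_smiles) ==
                    variants$canonical_smiles))
  # reproducibility
  expect_identical(noisy,
                   augment_regression(ds, augmentation_spec(5L, 0.3), seed = 4L))
  expect_error(augment_regression(molecule_records("CCO"),
                                  augmentation_spec(2L), seed = 1L),
               "label")
})

test_that("label noise is zero-mean Gaussian with the requested sd", {
  ds <- molecule_records(rep("CC(=O)Oc1ccccc1C(=O)O", 80L),
                         label = rep(0, 80L))
  aug <- augment_regression(ds, augmentation_spec(n_augment = 25L,
                                                  sigma_noise = 0.3),
                            seed = 9L)
  eps <- aug$label[aug$is_augmented]
  n <- length(eps)
  expect_gt(n, 1500L)
  expect_lt(abs(mean(eps)), 4 * 0.3 / sqrt(n))
  expect_lt(abs(stats::sd(eps) - 0.3), 0.03)
})

test_that("classification augmentation rebalances by the stated arithmetic", {
  # restrict to molecules that admit the requested variants, so the
  # all-variants-available arithmetic applies exactly
  pool <- fixture_corpus(80L, 77L)$canonical_smiles
  rich <- pool[vapply(pool, function(s) {
    length(enumerate_variants(s, 4L, seed = 1L)) == 4L
  }, TRUE)]
  pos <- molecule_records(rich[1:10], class_id = rep(1L, 10L))
  neg <- molecule_records(rich[11:60], class_id = rep(0L, 50L))
  ds <- rbind(pos, neg)
  spec <- augmentation_spec(per_class_counts = c("1" = 4L, "0" = 0L))
  aug <- augment_classification(ds, spec, seed = 2L)
  # all-variants-available arithmetic: (1+4)*10 positives, (1+0)*50 negatives
  expect_identical(sum(aug$class_id == 1L), 50L)
  expect_identical(sum(aug$class_id == 0L), 50L)
  expect_equal(class_ratio(aug), 1.0)
  # labels copied unperturbed
  expect_true(all(aug$class_id[aug$parent_id <= 10L] == 1L))

  expect_error(augment_classification(ds, augmentation_spec(
    per_class_counts = c("1" = 4L)), seed = 1L), "per-class")
})

test_that("enumeration exhaustion yields fewer variants without error", {
  ds <- molecule_records("C", class_id = 1L)
  spec <- augmentation_spec(per_class_counts = c("1" = 60L))
  aug <- augment_classification(ds, spec, seed = 1L)
  expect_identical(nrow(aug), 1L)
  expect_false(aug$is_augmented)
})

test_that("count_mode 'total' treats N as the total records per molecule", {
  ds <- molecule_records("CC(=O)Oc1ccccc1", label = 1)
  tot <- augment_regression(ds, augmentation_spec(n_augment = 4L,
                                                  count_mode = "total"),
                            seed = 1L)
  expect_identical(nrow(tot), 4L)
  add <- augment_regression(ds, augmentation_spec(n_augment = 4L), seed = 1L)
  expect_identical(nrow(add), 5L)
})

test_that("test-time augmentation returns canonical-first, label-free variants", {
  tta0 <- make_tta_variants("OCC", n_tta = 0L, seed = 1L)
  expect_identical(tta0, "CCO")
  tta <- make_tta_variants("CC(=O)Oc1ccccc1C(=O)O", n_tta = 4L, seed = 1L)
  expect_length(tta, 5L)
  expect_identical(tta[1], canonicalize("CC(=O)Oc1ccccc1C(=O)O"))
  expect_true(all(canonicalize_all(tta) == tta[1]))
  expect_identical(tta, make_tta_variants("CC(=O)Oc1ccccc1C(=O)O",
                                          n_tta = 4L, seed = 1L))
})

test_that("the benchmark endpoint presets carry the published settings", {
  lipo <- augmentation_preset("lipophilicity")
  expect_identical(lipo$n_augment, 25L)
  expect_equal(lipo$sigma_noise, 0.3)
  free <- augmentation_preset("freesolv")
  expect_identical(free$n_augment, 50L)
  expect_equal(free$sigma_noise, 0.5)
  hiv <- augmentation_preset("hiv")
  expect_identical(hiv$per_class_counts, c("1" = 60L, "0" = 2L))
  bbbp <- augmentation_preset("bbbp")
  expect_identical(bbbp$per_class_counts, c("1" = 10L, "0" = 30L))
})

test_that("augmented CSV export has the documented columns", {
  ds <- molecule_records(c("CCO", "CCN"), label = c(1, 2))
  aug <- augment_regression(ds, augmentation_spec(n_augment = 2L), seed = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_augmented_csv(aug, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("smiles", "label", "parent_id", "is_augmented"))
  expect_identical(nrow(back), nrow(aug))
})
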