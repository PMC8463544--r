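# Phantom image/corpus generator.

test_that("generate_image is deterministic and respects the label contract", {
  spec <- toy_spec()
  y <- c(1L, 0L)
  expect_identical(generate_image(y, spec, seed = 3),
                   generate_image(y, spec, seed = 3))
  expect_false(identical(generate_image(y, spec, seed = 3),
                         generate_image(y, spec, seed = 4)))
  expect_error(generate_image(c(1L, 0L, 1L), spec), "labels length")
})

test_that("noise-free all-zero labels give exactly the background phantom", {
  spec <- toy_spec(noise_sigma = 0)
  img <- generate_image(c(0L, 0L), spec)
  expect_identical(img, synthrad:::background_phantom(spec))
})

test_that("one positive label raises the lesion region mean by the contrast", {
  spec <- toy_spec(resolution = 32, contrast = 0.3, noise_sigma = 0)
  img0 <- generate_image(c(0L, 0L), spec)
  img1 <- generate_image(c(1L, 0L), spec)
  mask <- synthrad:::lesion_mask(spec$lesion_descriptors[[1]], 32)
  expect_true(sum(mask) > 0)
  expect_equal(mean(img1[mask]) - mean(img0[mask]), 0.3, tolerance = 1e-12)
  expect_equal(img1[!mask], img0[!mask])
})

test_that("generate_dataset meets the exact count and fold contract", {
  cl <- default_class_list(2, 2)
  store <- generate_dataset(toy_spec(), cl, per_class = 10,
                            fold_fractions = c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(store_size(store), 20L)
  expect_equal(unname(table(store$fold)[c("train", "val", "test")]),
               c(16L, 2L, 2L), ignore_attr = TRUE)
  # per-class counts in the emitted label table equal per_class
  expect_equal(unname(as.integer(table(synthrad:::combo_key(store$labels)))),
               c(10L, 10L))
  expect_error(generate_dataset(toy_spec(),
                                structure(list(), class = "not_classes"), 10),
               "class_list")
})

test_that("dataset generation is byte-identical under an identical seed", {
  a <- toy_store(per_class = 5, seed = 11)
  b <- toy_store(per_class = 5, seed = 11)
  expect_identical(a, b)
  c <- toy_store(per_class = 5, seed = 12)
  expect_false(identical(a$images, c$images))
})

test_that("patients are blocks of images_per_patient and never span classes", {
  store <- toy_store(per_class = 12, seed = 2, images_per_patient = 3)
  tab <- table(store$patient_id)
  expect_true(all(tab == 3))
  by_pat <- split(synthrad:::combo_key(store$labels), store$patient_id)
  expect_true(all(vapply(by_pat, function(k) length(unique(k)) == 1,
                         logical(1))))
  # patient-level split: no patient in two folds
  by_fold <- split(store$fold, store$patient_id)
  expect_true(all(vapply(by_fold, function(f) length(unique(f)) == 1,
                         logical(1))))
})

test_that("a small classifier separates two well-separated classes (AUC >= 0.9)", {
  store <- toy_store(per_class = 100, seed = 42)
  fit <- train_classifier(store_fold(store, "train"), store_fold(store, "val"),
                          fast_clf_config())
  rep <- evaluate_mean_auc(fit$model, store_fold(store, "test"))
  expect_gte(rep$mean_auc, 0.9)
})

test_that("probe AUC is monotone in lesion contrast and null at zero contrast", {
  aucs <- vapply(c(0, 0.2, 0.4), function(ct) {
    store <- generate_dataset(toy_spec(contrast = ct, noise_sigma = 0.1),
                              default_class_list(2, 2), per_class = 80,
                              seed = 7)
    fit <- train_classifier(store_fold(store, "train"),
                            store_fold(store, "val"),
                            fast_clf_config(seed = 9, max_epochs = 5))
    evaluate_mean_auc(fit$model, store_fold(store, "test"))$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.05))   # non-decreasing up to sampling noise
  expect_gte(aucs[3], 0.9)
})

test_that("at zero contrast the probe classifier is at chance (0.5 +/- 0.1)", {
  spec0 <- toy_spec(contrast = 0, noise_sigma = 0.1)
  cl <- default_class_list(2, 2)
  store <- generate_dataset(spec0, cl, per_class = 80, seed = 7)
  fit <- train_classifier(store_fold(store, "train"), store_fold(store, "val"),
                          fast_clf_config(seed = 9, max_epochs = 5))
  # evaluate on a large freshly drawn fold so the chance band is tight
  eval_store <- generate_dataset(spec0, cl, per_class = 250, seed = 8)
  rep <- evaluate_mean_auc(fit$model, eval_store)
  expect_true(abs(rep$mean_auc - 0.5) <= 0.1)
})
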