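# Pre-processing and benchmark-construction rules.

test_that("binarize_labels handles both corpus conventions", {
  raw <- data.frame(a = c("0", "1", "uncertain"), b = c("1", "0", "0"))
  out <- binarize_labels(raw, "uncertain_positive")
  expect_identical(out[, "a"], c(0L, 1L, 1L))
  expect_error(binarize_labels(data.frame(a = "maybe"), "uncertain_positive"),
               "unknown label symbol")
  probs <- matrix(c(0, 0.3, 1, 0), 2)
  expect_identical(binarize_labels(probs, "probability_positive"),
                   matrix(c(0L, 1L, 1L, 0L), 2))
  expect_error(binarize_labels(matrix(1.2), "probability_positive"), "0,1")
  zero <- matrix(0, 2, 3)
  expect_identical(binarize_labels(zero, "probability_positive"),
                   matrix(0L, 2, 3))
})

test_that("undersample_negative_class enforces the 50% positive share", {
  labels <- rbind(matrix(0L, 900, 2),
                  cbind(rep(1L, 100), rep(0L, 100)))
  n <- nrow(labels)
  store <- synthrad:::new_dataset_store(
    images = array(0, c(n, 8, 8)), labels = labels,
    label_names = c("a", "b"), image_id = sprintf("i%04d", 1:n),
    patient_id = sprintf("p%04d", 1:n), fold = rep("train", n),
    origin = "real", resolution = 8)
  out <- undersample_negative_class(store, 0.5, seed = 1)
  n_neg <- sum(rowSums(out$labels) == 0)
  n_pos <- sum(rowSums(out$labels) > 0)
  expect_equal(n_pos, 100)
  expect_lte(n_neg, 100)
  expect_gte(n_pos / (n_pos + n_neg), 0.5)
  # balanced input untouched
  bal <- store_subset(store, c(1:100, 901:1000))
  expect_identical(undersample_negative_class(bal, 0.5, 1)$labels, bal$labels)
})

test_that("stratified split apportions 10 single-image patients as 8/1/1", {
  labels <- matrix(rep(c(1L, 0L), each = 10), 10)
  store <- synthrad:::new_dataset_store(
    images = array(0, c(10, 8, 8)), labels = labels,
    label_names = c("a", "b"), image_id = sprintf("i%02d", 1:10),
    patient_id = sprintf("p%02d", 1:10), fold = rep("unassigned", 10),
    origin = "real", resolution = 8)
  out <- stratified_patient_split(store, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(sum(out$fold == "train"), 8)
  expect_equal(sum(out$fold == "val"), 1)
  expect_equal(sum(out$fold == "test"), 1)
  expect_error(stratified_patient_split(store, c(0.7, 0.2, 0.2)), "summing to 1")
})

test_that("split is a patient partition with < 1 patient deviation per stratum", {
  store <- toy_store(per_class = 40, seed = 6, n_labels = 3, n_classes = 4,
                     images_per_patient = 2)
  strata <- synthrad:::patient_strata(store)
  pat_fold <- vapply(split(store$fold, store$patient_id),
                     function(f) unique(f), character(1))
  expect_true(all(lengths(lapply(split(store$fold, store$patient_id),
                                 unique)) == 1))
  for (s in unique(strata)) {
    pats <- names(strata)[strata == s]
    counts <- table(factor(pat_fold[pats], levels = c("train", "val", "test")))
    expect_true(all(abs(counts - length(pats) * c(0.8, 0.1, 0.1)) < 1))
  }
})

test_that("filter_rare_classes thresholds, is idempotent and monotone", {
  labels <- rbind(matrix(rep(c(0L, 0L), 300), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1L, 0L), 100), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1L, 1L), 50), ncol = 2, byrow = TRUE))
  n <- nrow(labels)
  store <- synthrad:::new_dataset_store(
    images = array(0, c(n, 8, 8)), labels = labels,
    label_names = c("a", "b"), image_id = sprintf("i%04d", 1:n),
    patient_id = sprintf("p%04d", 1:n), fold = rep("train", n),
    origin = "real", resolution = 8)
  out <- filter_rare_classes(store, 100)
  expect_equal(sort(unique(synthrad:::combo_key(out$labels))), c("00", "10"))
  expect_equal(store_size(out), 400)
  expect_identical(filter_rare_classes(out, 100)$labels, out$labels)  # idempotent
  expect_identical(filter_rare_classes(store, 1)$labels, store$labels) # identity
  expect_lte(store_size(filter_rare_classes(store, 250)),
             store_size(filter_rare_classes(store, 100)))              # monotone
  expect_error(filter_rare_classes(store, 1000), "every record")
})

test_that("build_benchmark_setting oversamples to an exactly uniform histogram", {
  store <- toy_store(per_class = 30, seed = 9, n_labels = 3, n_classes = 3)
  # request more per class than available -> oversampling with replacement
  setting <- benchmark_setting(resolution = 16, n_classes = 3, per_class = 40,
                               val_size = 9, test_size = 9)
  out <- build_benchmark_setting(store, setting, seed = 4)
  tr <- store_fold(out, "train")
  expect_equal(store_size(tr), 120L)
  expect_true(all(table(synthrad:::combo_key(tr$labels)) == 40))
  # per_class equal to the real count -> multiset of records unchanged
  avail <- min(table(synthrad:::combo_key(store$labels)[store$fold == "train"]))
  set2 <- benchmark_setting(16, 3, avail, 9, 9)
  out2 <- store_fold(build_benchmark_setting(store, set2, seed = 4), "train")
  expect_true(all(table(synthrad:::combo_key(out2$labels)) == avail))
  expect_error(build_benchmark_setting(store, benchmark_setting(16, 9, 5, 2, 2)),
               "classes")
})

test_that("published settings table matches its stated row structure", {
  chest <- benchmark_table("chest")
  brain <- benchmark_table("brain")
  # balanced rows satisfy train = classes x per-class
  bal <- chest[chest$type != "resolution", ]
  expect_true(all(bal$train_size == bal$n_classes * bal$per_class_min))
  expect_true(all(brain$resolution %in% c(32, 64, 128, 256, 512)))
  expect_equal(chest$train_size[1], 29000)
  expect_equal(brain[brain$type == "classes", ]$n_classes, c(10, 8, 6, 4, 2))
})

test_that("synthetic folds are label-equivalent by construction", {
  store <- toy_store(per_class = 20, seed = 3)
  gen <- function(labels, seed) {
    synthrad:::with_seed(seed,
      array(stats::runif(nrow(labels) * 16 * 16), c(nrow(labels), 16, 16)))
  }
  syn <- make_equivalent_synthetic_folds(gen, store, seed = 1)
  expect_identical(syn$labels, store$labels)
  expect_identical(syn$fold, store$fold)
  expect_equal(syn$origin, "synthetic")
  for (f in c("train", "val", "test")) {
    expect_equal(store_size(store_fold(syn, f)), store_size(store_fold(store, f)))
    expect_identical(sort(synthrad:::combo_key(store_fold(syn, f)$labels)),
                     sort(synthrad:::combo_key(store_fold(store, f)$labels)))
  }
  syn2 <- make_equivalent_synthetic_folds(gen, store, seed = 2)
  expect_false(identical(syn$images, syn2$images))
  expect_identical(syn$labels, syn2$labels)
  bad <- function(labels, seed) array(0, c(nrow(labels), 8, 8))
  expect_error(make_equivalent_synthetic_folds(bad, store), "shape")
})
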