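# DatasetStore container and the benchmark-construction / pre-processing rules:
# label binarization, no-finding undersampling, patient-stratified splitting,
# rare-class filtering, Table-style setting construction with oversampling, and
# label-equivalent synthetic fold synthesis.

new_dataset_store <- function(images, labels, label_names, image_id, patient_id,
                              fold, origin, resolution) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  n <- nrow(labels)
  check_that(dim(images)[1] == n, "images and labels disagree in length")
  check_that(!anyDuplicated(image_id), "image_id must be unique within a store")
  check_that(all(labels %in% c(0L, 1L)), "labels must be binary")
  structure(list(images = images, labels = labels, label_names = label_names,
                 image_id = image_id, patient_id = patient_id,
                 fold = fold, origin = origin,
                 resolution = as.integer(resolution)),
            class = "dataset_store")
}

#' @export
print.dataset_store <- function(x, ...) {
  tab <- table(factor(x$fold, levels = c("train", "val", "test", "unassigned")))
  cat(sprintf("dataset_store (%s): %d images at %dx%d, %d labels, %d patients\n",
              x$origin, nrow(x$labels), x$resolution, x$resolution,
              ncol(x$labels), length(unique(x$patient_id))))
  cat(sprintf("  folds: train %d / val %d / test %d / unassigned %d\n",
              tab["train"], tab["val"], tab["test"], tab["unassigned"]))
  cat(sprintf("  classes (unique label combinations): %d\n",
              length(unique(combo_key(x$labels)))))
  invisible(x)
}

#' Number of images in a dataset store
#' @param store A `dataset_store`.
#' @return Integer count.
#' @export
store_size <- function(store) nrow(store$labels)

#' Subset a dataset store by record index
#' @param store A `dataset_store`.
#' @param idx Integer index vector (duplicates allowed: records are repeated).
#' @return A `dataset_store` with the selected records.
#' @export
store_subset <- function(store, idx) {
  ids <- store$image_id[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  new_dataset_store(images = store$images[idx, , , drop = FALSE],
                    labels = store$labels[idx, , drop = FALSE],
                    label_names = store$label_names,
                    image_id = ids,
                    patient_id = store$patient_id[idx],
                    fold = store$fold[idx],
                    origin = store$origin,
                    resolution = store$resolution)
}

#' Extract one fold of a dataset store
#' @param store A `dataset_store`.
#' @param fold One of "train", "val", "test".
#' @return A `dataset_store` restricted to that fold.
#' @export
store_fold <- function(store, fold) {
  check_that(fold %in% c("train", "val", "test", "unassigned"), "unknown fold")
  store_subset(store, which(store$fold == fold))
}

# ---- label binarization ------------------------------------------------------

#' Binarize a raw label table
#'
#' Two modes mirror the handling of the two source corpora: with
#' `uncertain_positive`, entries are in \{0, 1, "uncertain"\} and uncertain
#' labels become positives; with `probability_positive`, entries are
#' probabilities in [0,1] and any p > 0 becomes a positive label.
#'
#' @param raw_table Data frame or matrix of raw label entries.
#' @param mode `"uncertain_positive"` or `"probability_positive"`.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_labels <- function(raw_table,
                            mode = c("uncertain_positive", "probability_positive")) {
  mode <- match.arg(mode)
  m <- as.matrix(raw_table)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  if (mode == "uncertain_positive") {
    ok <- m %in% c("0", "1", "uncertain", 0, 1)
    check_that(all(ok), "unknown label symbol; expected 0, 1 or 'uncertain'")
    out[m == "1" | m == "uncertain"] <- 1L
  } else {
    p <- suppressWarnings(as.numeric(m))
    check_that(!anyNA(p) && all(p >= 0 & p <= 1),
               "probabilities must lie in [0,1]")
    out[p > 0] <- 1L
  }
  out
}

# ---- no-finding undersampling ------------------------------------------------

#' Undersample the all-zero "no finding" class
#'
#' Seeded uniform removal of no-finding records until their share is at most
#' `max_negative_fraction`; positive records are untouched. A no-op when the
#' store already satisfies the bound.
#'
#' @param store A `dataset_store`.
#' @param max_negative_fraction Maximum allowed share of all-zero records
#'   (default 0.5, i.e. at least half the images show some finding).
#' @param seed Integer seed.
#' @return A `dataset_store`.
#' @export
undersample_negative_class <- function(store, max_negative_fraction = 0.5,
                                       seed = 1L) {
  neg <- which(rowSums(store$labels) == 0L)
  pos <- which(rowSums(store$labels) > 0L)
  n_neg <- length(neg); n_pos <- length(pos)
  if (n_neg == 0 || n_neg / (n_neg + n_pos) <= max_negative_fraction)
    return(store)
  keep_neg <- floor(max_negative_fraction / (1 - max_negative_fraction) * n_pos)
  kept <- with_seed(seed, sample(neg, keep_neg))
  store_subset(store, sort(c(pos, kept)))
}

# ---- patient-stratified splitting -------------------------------------------

# one stratum per patient: the patient's most frequent label combination,
# ties broken lexicographically by combination key
patient_strata <- function(store) {
  keys <- combo_key(store$labels)
  vapply(split(keys, store$patient_id), function(k) {
    tab <- sort(table(k), decreasing = TRUE)
    nm <- names(tab)[tab == tab[1]]
    sort(nm)[1]
  }, character(1))
}

#' Patient-level stratified train/validation/test split
#'
#' Every patient's images land in exactly one fold. Within each stratum (the
#' patient's most frequent label combination), patient counts approximate the
#' requested fractions by largest-remainder apportionment; a seeded shuffle
#' decides which patients fill which fold.
#'
#' @param store A `dataset_store` with patient ids.
#' @param fractions Train/val/test fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed.
#' @return The store with `fold` assigned for every record.
#' @export
stratified_patient_split <- function(store, fractions = c(0.8, 0.1, 0.1),
                                     seed = 1L) {
  check_that(length(fractions) == 3 && abs(sum(fractions) - 1) < 1e-8,
             "fractions must be a triple summing to 1")
  strata <- patient_strata(store)
  fold_of_patient <- character(0)
  for (s in sort(unique(strata))) {
    pats <- names(strata)[strata == s]
    pats <- with_seed(fanout_seed(seed, utils::head(utf8ToInt(s), 1) +
                                    100L * match(s, sort(unique(strata)))),
                      sample(pats))
    counts <- largest_remainder(length(pats), fractions)
    f <- rep(c("train", "val", "test"), counts)
    fold_of_patient[pats] <- f
  }
  store$fold <- unname(fold_of_patient[store$patient_id])
  store
}

# ---- rare-class filtering ----------------------------------------------------

#' Remove label combinations below a frequency threshold
#'
#' Every surviving label combination has total frequency >= `min_count`;
#' records of dropped combinations are removed entirely. Idempotent and
#' monotone in `min_count`. The source corpora used thresholds of 256
#' (chest radiographs) and 100 (brain CT label combinations).
#'
#' @param store A `dataset_store`.
#' @param min_count Minimum class frequency (>= 1).
#' @return A `dataset_store`.
#' @export
filter_rare_classes <- function(store, min_count) {
  check_that(min_count >= 1, "min_count must be >= 1")
  keys <- combo_key(store$labels)
  tab <- table(keys)
  keep_keys <- names(tab)[tab >= min_count]
  idx <- which(keys %in% keep_keys)
  check_that(length(idx) > 0, "filter_rare_classes removed every record")
  store_subset(store, idx)
}

# ---- benchmark setting construction -----------------------------------------

#' One row of the benchmark settings table
#'
#' @param resolution Image resolution (pixels per side).
#' @param n_classes Number of unique label combinations to include.
#' @param per_class Training images per class (balanced settings satisfy
#'   train_size = n_classes * per_class).
#' @param val_size,test_size Validation / test fold sizes (images).
#' @param n_labels Optional number of binary labels (informational).
#' @return Object of class `benchmark_setting`.
#' @export
benchmark_setting <- function(resolution, n_classes, per_class,
                              val_size, test_size, n_labels = NA_integer_) {
  structure(list(resolution = as.integer(resolution),
                 n_labels = as.integer(n_labels),
                 n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 train_size = as.integer(n_classes) * as.integer(per_class),
                 val_size = as.integer(val_size),
                 test_size = as.integer(test_size)),
            class = "benchmark_setting")
}

#' @export
print.benchmark_setting <- function(x, ...) {
  cat(sprintf("benchmark_setting: %dx%d px, %d classes x %d/class = %d train, %d val, %d test\n",
              x$resolution, x$resolution, x$n_classes, x$per_class,
              x$train_size, x$val_size, x$test_size))
  invisible(x)
}

#' The published benchmark settings table
#'
#' Returns the class/sample/resolution sweep compositions for the two source
#' corpora (chest radiographs with 14 binary labels; brain CT scans with 6) as
#' a data frame: one row per setting with resolution, label count, class
#' count, fold sizes and per-class training counts (a range for the unbalanced
#' full-pool settings).
#'
#' @param dataset `"chest"` or `"brain"`.
#' @return A data frame with columns `type`, `resolution`, `n_labels`,
#'   `n_classes`, `train_size`, `testval_size`, `per_class_min`,
#'   `per_class_max`.
#' @export
benchmark_table <- function(dataset = c("chest", "brain")) {
  dataset <- match.arg(dataset)
  row <- function(type, res, nl, nc, tr, tv, pmin, pmax = pmin)
    data.frame(type = type, resolution = res, n_labels = nl, n_classes = nc,
               train_size = tr, testval_size = tv,
               per_class_min = pmin, per_class_max = pmax)
  if (dataset == "chest") {
    rbind(
      row("classes", 32, 9, 20, 29000, 3800, 1450),
      row("classes", 32, 8, 15, 24000, 2850, 1600),
      row("classes", 32, 5, 10, 20000, 1900, 2000),
      row("classes", 32, 5, 6, 13800, 1140, 2300),
      row("classes", 32, 5, 4, 15600, 760, 3900),
      row("classes", 32, 4, 2, 12600, 380, 6300),
      row("samples", 32, 4, 3, 17850, 2250, 5950),
      row("samples", 32, 4, 3, 13500, 2250, 4500),
      row("samples", 32, 4, 3, 9000, 2250, 3000),
      row("samples", 32, 4, 3, 4500, 2250, 1500),
      row("samples", 32, 4, 3, 3000, 2250, 1000),
      row("samples", 32, 4, 3, 1500, 2250, 500),
      row("samples", 32, 4, 3, 1200, 2250, 400),
      row("samples", 32, 4, 3, 600, 2250, 200),
      row("resolution", 32, 14, 138, 117168, 4000, 256, 7586),
      row("resolution", 64, 14, 138, 117168, 4000, 256, 7586),
      row("resolution", 128, 14, 138, 117168, 4000, 256, 7586),
      row("resolution", 256, 14, 138, 117168, 4000, 256, 7586),
      row("resolution", 512, 14, 138, 117168, 4000, 256, 7586))
  } else {
    rbind(
      row("classes", 32, 5, 10, 25000, 3000, 2500),
      row("classes", 32, 5, 8, 24960, 2400, 3120),
      row("classes", 32, 5, 6, 25020, 1800, 4170),
      row("classes", 32, 4, 4, 25000, 1200, 6250),
      row("classes", 32, 2, 2, 25000, 600, 12500),
      row("samples", 32, 5, 6, 32400, 3000, 5400),
      row("samples", 32, 5, 6, 27000, 3000, 4500),
      row("samples", 32, 5, 6, 18000, 3000, 3000),
      row("samples", 32, 5, 6, 9000, 3000, 1500),
      row("samples", 32, 5, 6, 6000, 3000, 1000),
      row("samples", 32, 5, 6, 3000, 3000, 500),
      row("samples", 32, 5, 6, 1800, 3000, 300),
      row("samples", 32, 5, 6, 600, 3000, 100),
      row("resolution", 32, 6, 20, 117168, 4000, 155, 85876),
      row("resolution", 64, 6, 20, 117168, 4000, 155, 85876),
      row("resolution", 128, 6, 20, 117168, 4000, 155, 85876),
      row("resolution", 256, 6, 20, 117168, 4000, 155, 85876),
      row("resolution", 512, 6, 20, 117168, 4000, 155, 85876))
  }
}

#' Build one benchmark setting from a dataset store
#'
#' Selects the `n_classes` most frequent label combinations in the store's
#' train fold (ties broken lexicographically), resamples the train fold so
#' every class has exactly `per_class` records (classes with fewer real
#' records are oversampled with replacement, seeded; classes with more are
#' subsampled without replacement), and restricts the validation/test folds to
#' the chosen classes at the configured sizes.
#'
#' @param store A split `dataset_store`.
#' @param setting A [benchmark_setting()].
#' @param seed Integer seed.
#' @param classes Optional explicit 0/1 matrix of class combinations to use
#'   instead of the most-frequent rule.
#' @return A `dataset_store` whose train fold class histogram is exactly
#'   uniform at `per_class`.
#' @export
build_benchmark_setting <- function(store, setting, seed = 1L, classes = NULL) {
  check_that(inherits(setting, "benchmark_setting"), "need a benchmark_setting")
  keys <- combo_key(store$labels)
  train_idx <- which(store$fold == "train")
  if (is.null(classes)) {
    tab <- table(keys[train_idx])
    ord <- order(-as.integer(tab), names(tab))
    check_that(length(tab) >= setting$n_classes,
               "store has only ", length(tab), " classes; setting needs ",
               setting$n_classes)
    sel_keys <- names(tab)[ord][seq_len(setting$n_classes)]
  } else {
    sel_keys <- combo_key(as.matrix(classes))
    check_that(all(sel_keys %in% keys[train_idx]),
               "requested class absent from the train fold")
  }
  new_train <- integer(0)
  for (j in seq_along(sel_keys)) {
    cls_idx <- train_idx[keys[train_idx] == sel_keys[j]]
    take <- with_seed(fanout_seed(seed, j), {
      if (length(cls_idx) >= setting$per_class)
        sample(cls_idx, setting$per_class)
      else
        c(cls_idx, sample(cls_idx, setting$per_class - length(cls_idx),
                          replace = TRUE))
    })
    new_train <- c(new_train, take)
  }
  pick_fold <- function(fold, size, stream) {
    idx <- which(store$fold == fold & keys %in% sel_keys)
    if (length(idx) > size)
      idx <- with_seed(fanout_seed(seed, stream), sample(idx, size))
    sort(idx)
  }
  val_idx <- pick_fold("val", setting$val_size, 10001L)
  test_idx <- pick_fold("test", setting$test_size, 10002L)
  out <- store_subset(store, c(new_train, val_idx, test_idx))
  out$fold <- rep(c("train", "val", "test"),
                  c(length(new_train), length(val_idx), length(test_idx)))
  out
}

# ---- label-equivalent synthetic folds ---------------------------------------

#' Build synthetic folds label-equivalent to a real store
#'
#' For each real record, one synthetic image is generated conditioned on that
#' record's labels with fresh seeded noise, so the label multisets and sizes of
#' the real and synthetic train/val/test folds are identical by construction.
#'
#' @param generator_handle A function `(labels_matrix, seed)` returning an
#'   image array (n, res, res) in [0,1] — e.g. [as_conditional_sampler()]
#'   around a trained GAN.
#' @param real_store The real `dataset_store` to mirror.
#' @param seed Integer seed for the synthesis noise.
#' @return A `dataset_store` with `origin = "synthetic"` and the same label
#'   table and folds as `real_store`.
#' @export
make_equivalent_synthetic_folds <- function(generator_handle, real_store,
                                            seed = 1L) {
  imgs <- generator_handle(real_store$labels, seed)
  check_that(length(dim(imgs)) == 3 &&
               all(dim(imgs) == c(store_size(real_store),
                                  real_store$resolution,
                                  real_store$resolution)),
             "generator output shape does not match the real store")
  out <- real_store
  out$images <- imgs
  out$origin <- "synthetic"
  out
}
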