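# Shared fixtures: all built in code, desk scale.

# two well-separated classes (no-finding vs blob), 16 px
toy_spec <- function(resolution = 16, n_labels = 2, contrast = 0.4,
                     noise_sigma = 0.05, images_per_patient = 1) {
  phantom_spec(resolution = resolution, n_labels = n_labels,
               contrast = contrast, noise_sigma = noise_sigma,
               images_per_patient = images_per_patient)
}

toy_store <- function(per_class = 100, seed = 42, n_labels = 2, n_classes = 2,
                      ...) {
  generate_dataset(toy_spec(n_labels = n_labels, ...),
                   default_class_list(n_labels, n_classes),
                   per_class = per_class, seed = seed)
}

fast_clf_config <- function(resolution = 16, seed = 5, max_epochs = 8,
                            lr = 2e-3) {
  classifier_config(input_size = resolution, batch_size = 32,
                    max_epochs = max_epochs, lr = lr, seed = seed)
}

# oracle generator: replays the real image carrying the same labels.
# When the requested label sequence is exactly the store's record order
# (as in make_equivalent_synthetic_folds) the replay is positional, so the
# synthetic store equals the real one record for record; otherwise images are
# cycled within the matching label class.
identity_generator_factory <- function(bstore, seed) {
  force(bstore); force(seed)
  function(labels, gseed) {
    if (nrow(labels) == store_size(bstore) &&
        all(labels == bstore$labels)) {
      return(bstore$images)
    }
    keys <- synthrad:::combo_key(labels)
    real_keys <- synthrad:::combo_key(bstore$labels)
    idx <- integer(length(keys))
    counters <- new.env()
    for (i in seq_along(keys)) {
      pool <- which(real_keys == keys[i])
      ct <- (get0(keys[i], counters, ifnotfound = 0L) %% length(pool)) + 1L
      assign(keys[i], ct, counters)
      idx[i] <- pool[ct]
    }
    bstore$images[idx, , , drop = FALSE]
  }
}

# adversarial generator: background + noise only, plus a high-contrast corner
# tag encoding the class id -- the classic label-overfitting signature
corner_tag_generator_factory <- function(bstore, seed) {
  spec <- toy_spec(resolution = bstore$resolution,
                   n_labels = ncol(bstore$labels))
  all_keys <- sort(unique(synthrad:::combo_key(bstore$labels)))
  force(seed)
  function(labels, gseed) {
    n <- nrow(labels)
    res <- spec$resolution
    out <- array(0, c(n, res, res))
    zero <- integer(ncol(labels))
    for (i in seq_len(n)) {
      img <- generate_image(zero, spec, seed = fanout_seed(gseed, i))
      cls <- match(synthrad:::combo_key(labels[i, , drop = FALSE]), all_keys)
      cols <- ((cls - 1L) * 2L) %% res + 1:2   # class-specific corner position
      img[1:2, cols] <- 1
      out[i, , ] <- img
    }
    out
  }
}
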