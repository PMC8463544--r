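# Post-hoc analyses: occlusion feature-importance maps, the nearest-neighbour
# privacy audit in classifier feature space, and reader-study statistics.

#' Occlusion feature-importance map
#'
#' Successively zero-masks non-overlapping `mask_size x mask_size` tiles of
#' the input image (stride = mask size; a 224 px input with 2 px masks gives
#' exactly 12,544 tiles), computes the increased model loss for each, then
#' subtracts the baseline loss and min-max normalises the map to [0,1].
#' The loss is the per-image binary cross-entropy against the ground-truth
#' labels summed over labels; there is no learning involved. The mask value
#' is 0 in the model's input space, i.e. mid-gray for inputs in [-1,1].
#'
#' @param model A `synthrad_classifier`, or a function mapping an image array
#'   (n, H, W) in model input space to a probability matrix (n x L).
#' @param image A single image matrix (H x W) already at model input size,
#'   in the model's input space.
#' @param labels Ground-truth 0/1 label vector.
#' @param mask_size Tile side length in pixels (default 2); must divide the
#'   image size.
#' @param mask_value Fill value in input space (default 0).
#' @param chunk Tiles evaluated per forward batch.
#' @return Object of class `attribution_map`: `map` ((H/mask) x (W/mask)
#'   normalised grid), `raw` (loss increases), `baseline_loss`, `mask_size`,
#'   `n_tiles`.
#' @export
attribution_map <- function(model, image, labels, mask_size = 2L,
                            mask_value = 0, chunk = 256L) {
  image <- as.matrix(image)
  H <- nrow(image); W <- ncol(image)
  check_that(H %% mask_size == 0 && W %% mask_size == 0,
             "input size not divisible by mask size")
  predict_fn <- if (is.function(model)) model else {
    function(x) predict_proba(model, (x + 1) / 2)   # model input space -> store space
  }
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -rowSums(log(p) * rep(y, each = nrow(p)) +
               log(1 - p) * rep(1 - y, each = nrow(p)))
  }
  base <- array(image, c(1L, H, W))
  baseline_loss <- bce(predict_fn(base), labels)
  gh <- H %/% mask_size; gw <- W %/% mask_size
  n_tiles <- gh * gw
  raw <- numeric(n_tiles)
  tile <- 1L
  while (tile <= n_tiles) {
    last <- min(n_tiles, tile + chunk - 1L)
    ids <- tile:last
    batch <- array(rep(image, each = length(ids)), c(length(ids), H, W))
    for (k in seq_along(ids)) {
      t0 <- ids[k] - 1L
      gi <- t0 %% gh          # row tile index (0-based)
      gj <- t0 %/% gh         # col tile index
      rows <- gi * mask_size + seq_len(mask_size)
      cols <- gj * mask_size + seq_len(mask_size)
      batch[k, rows, cols] <- mask_value
    }
    raw[ids] <- bce(predict_fn(batch), labels) - baseline_loss
    tile <- last + 1L
  }
  rng <- range(raw)
  map <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
         else rep(0, n_tiles)
  structure(list(map = matrix(map, gh, gw), raw = matrix(raw, gh, gw),
                 baseline_loss = unname(baseline_loss),
                 mask_size = as.integer(mask_size), n_tiles = n_tiles),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("attribution_map: %dx%d tiles (mask %d px), baseline loss %.4g\n",
              nrow(x$map), ncol(x$map), x$mask_size, x$baseline_loss))
  invisible(x)
}

#' Nearest-neighbour privacy audit
#'
#' For every synthetic query image, finds the real training image minimising
#' the cosine distance between penultimate-layer feature vectors of the
#' classifier trained on real data. Small distances flag potential training
#' image memorisation. Ties are broken by the lowest real image id.
#'
#' @param synthetic Image array (n, res, res) in [0,1] or a `dataset_store`.
#' @param real_train A `dataset_store` (the real train fold).
#' @param extractor A `synthrad_classifier` (penultimate features are used)
#'   or a function mapping an image array to a feature matrix.
#' @return Data frame: `synthetic_id`, `nearest_real_id`, `distance`
#'   (cosine, in [0,2]).
#' @export
nearest_neighbors <- function(synthetic, real_train, extractor) {
  check_that(store_size(real_train) > 0, "real train fold is empty")
  feat_fn <- if (is.function(extractor)) extractor
             else function(x) penultimate_features(extractor, x)
  syn_imgs <- if (inherits(synthetic, "dataset_store")) synthetic$images
              else synthetic
  syn_ids <- if (inherits(synthetic, "dataset_store")) synthetic$image_id
             else sprintf("syn%06d", seq_len(dim(syn_imgs)[1]))
  fs <- as.matrix(feat_fn(syn_imgs))
  fr <- as.matrix(feat_fn(real_train$images))
  norm_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  cs <- tcrossprod(norm_rows(fs), norm_rows(fr))   # cosine similarity
  dist <- 1 - cs
  ord <- order(real_train$image_id)
  best <- apply(dist[, ord, drop = FALSE], 1, which.min)  # ties -> lowest id
  data.frame(synthetic_id = syn_ids,
             nearest_real_id = real_train$image_id[ord][best],
             distance = pmin(pmax(dist[cbind(seq_len(nrow(dist)), ord[best])], 0), 2))
}

# ---- reader study ------------------------------------------------------------

#' Reader-study record for one reader
#'
#' @param TR,FR,TS,FS True-real / false-real / true-synthetic /
#'   false-synthetic counts. `TR + FS` is the number of real images shown and
#'   `TS + FR` the number of synthetics.
#' @param reader Optional reader identifier.
#' @return Object of class `reader_record` with the accuracy
#'   `acc = (TR + TS) / (TR + TS + FR + FS)`.
#' @export
reader_record <- function(TR, FR, TS, FS, reader = NA_character_) {
  check_that(all(c(TR, FR, TS, FS) >= 0), "counts must be non-negative")
  total <- TR + TS + FR + FS
  check_that(total > 0, "record has zero total")
  structure(list(reader = reader, TR = TR, FR = FR, TS = TS, FS = FS,
                 n_real = TR + FS, n_synthetic = TS + FR,
                 acc = (TR + TS) / total),
            class = "reader_record")
}

# exact distribution of the one-sided Wilcoxon signed-rank statistic W+ by
# dynamic programming over doubled (hence integer) midranks
wilcoxon_exact_p <- function(w_obs, ranks2) {
  maxw <- sum(ranks2)
  cnt <- numeric(maxw + 1L)
  cnt[1L] <- 1
  for (r in ranks2) {
    nxt <- cnt
    nxt[(r + 1L):(maxw + 1L)] <- nxt[(r + 1L):(maxw + 1L)] + cnt[1:(maxw - r + 1L)]
    cnt <- nxt
  }
  sum(cnt[(w_obs + 1L):(maxw + 1L)]) / 2^length(ranks2)
}

#' One-sided Wilcoxon signed-rank test against a null value
#'
#' Tests whether the sample tends to exceed `mu` using the signed-rank
#' statistic W+ (zeros dropped, midranks for ties). Exact p by enumeration of
#' the sign-assignment distribution for n <= 15; normal approximation with
#' tie correction otherwise.
#'
#' @param x Numeric sample.
#' @param mu Null location (default 0.5, the random-classifier accuracy).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `W` (W+), `n_used`, `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 0.5,
                                 alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - mu
  if (alternative == "less") d <- -d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, n_used = 0L, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 15) {
    p <- wilcoxon_exact_p(round(2 * W), round(2 * r))
    list(W = W, n_used = n, p = p, method = "exact")
  } else {
    mu_w <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu_w - 0.5) / sqrt(sig2)
    list(W = W, n_used = n, p = stats::pnorm(z, lower.tail = FALSE),
         method = "normal")
  }
}

#' Reader-study statistics
#'
#' Per-reader accuracy, panel mean and standard deviation, and — when the
#' panel has at least `min_readers_for_test` readers — a one-sided Wilcoxon
#' signed-rank test of whether reader accuracy exceeds the random-classifier
#' null (expected accuracy 0.5 on a balanced set). Small panels report only
#' accuracy mean and SD, without a test.
#'
#' @param records List of [reader_record()] objects.
#' @param null_accuracy Null accuracy (default 0.5).
#' @param min_readers_for_test Minimum panel size for the test (default 5).
#' @return Object of class `reader_study`: `acc` (per reader), `mean_acc`,
#'   `sd_acc`, `test` (or NULL).
#' @export
reader_study_stats <- function(records, null_accuracy = 0.5,
                               min_readers_for_test = 5L) {
  check_that(length(records) >= 1, "need at least one record")
  acc <- vapply(records, function(r) {
    check_that(inherits(r, "reader_record"), "records must be reader_record")
    r$acc
  }, numeric(1))
  test <- NULL
  if (length(acc) >= min_readers_for_test)
    test <- wilcoxon_signed_rank(acc, mu = null_accuracy,
                                 alternative = "greater")
  structure(list(acc = acc, mean_acc = mean(acc), sd_acc = stats::sd(acc),
                 null_accuracy = null_accuracy, test = test),
            class = "reader_study")
}

#' @export
print.reader_study <- function(x, ...) {
  cat(sprintf("reader_study: %d readers, accuracy %.3f +/- %.3f",
              length(x$acc), x$mean_acc, x$sd_acc))
  if (!is.null(x$test))
    cat(sprintf("; one-sided Wilcoxon vs %.2f: p = %.4g (%s)",
                x$null_accuracy, x$test$p, x$test$method))
  cat("\n")
  invisible(x)
}

#' Null accuracy of uniform random real/synthetic labelling
#'
#' Analytically, a reader answering uniformly at random on any set attains
#' expected accuracy 1/2 regardless of composition. `n_draws` Monte-Carlo
#' panels verify this for a balanced set of `n_images` images.
#'
#' @param n_images Set size (default 100: 50 real + 50 synthetic).
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed Integer seed.
#' @return List with `analytic` (0.5) and `monte_carlo` (simulated mean
#'   accuracy).
#' @export
reader_null_accuracy <- function(n_images = 100L, n_draws = 1e5, seed = 1L) {
  correct <- with_seed(seed, stats::rbinom(n_draws, n_images, 0.5))
  list(analytic = 0.5, monte_carlo = mean(correct / n_images))
}
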