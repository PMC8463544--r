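# Occlusion attribution, nearest-neighbour audit, reader-study statistics.

# cheap linear "model": probability = sigmoid of a weighted pixel sum
linear_predictor <- function(w_img, n_labels = 1) {
  function(x) {
    n <- dim(x)[1]
    s <- matrix(x, n, length(w_img)) %*% as.vector(w_img)
    matrix(1 / (1 + exp(-s)), n, n_labels)
  }
}

test_that("2x2 masks over a 224 px input enumerate exactly 12,544 tiles", {
  img <- matrix(0, 224, 224)
  am <- attribution_map(linear_predictor(matrix(0, 224, 224)), img,
                        labels = 1, mask_size = 2)
  expect_equal(am$n_tiles, 12544L)
  expect_equal(dim(am$map), c(112, 112))
})

test_that("tile count is (H/mask)(W/mask) and values lie in [0,1]", {
  for (sz in c(32, 64)) {
    for (mk in c(2, 4)) {
      img <- matrix(stats::runif(sz * sz), sz, sz)
      w <- matrix(stats::rnorm(sz * sz, sd = 0.1), sz, sz)
      am <- attribution_map(linear_predictor(w), img, labels = 1,
                            mask_size = mk)
      expect_equal(am$n_tiles, (sz / mk)^2)
      expect_true(all(am$map >= 0 & am$map <= 1))
    }
  }
  expect_error(attribution_map(linear_predictor(matrix(0, 9, 9)),
                               matrix(0, 9, 9), 1, mask_size = 2),
               "divisible")
})

test_that("constant models attribute zero; localized models localize", {
  img <- matrix(stats::runif(64), 8, 8) + 0.5
  const_model <- function(x) matrix(0.7, dim(x)[1], 1)
  am <- attribution_map(const_model, img, labels = 1, mask_size = 2)
  expect_true(all(am$raw == 0))
  expect_true(all(am$map == 0))
  # model reading only pixel (1,1): only the first tile moves the loss
  w <- matrix(0, 8, 8); w[1, 1] <- 3
  am2 <- attribution_map(linear_predictor(w), img, labels = 1, mask_size = 2)
  nz <- which(abs(am2$raw) > 1e-12, arr.ind = TRUE)
  expect_equal(unname(nz), matrix(c(1L, 1L), 1))
})

test_that("nearest neighbours match a hand-computed cosine oracle", {
  fr <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  fs <- rbind(c(1, 0, 0), c(0.9, 1, 0))
  # the audit embeds the synthetic queries first, then the real fold
  extractor <- local({
    feats <- rbind(fs, fr)
    i <- 0
    function(x) {
      n <- dim(x)[1]
      out <- feats[i + seq_len(n), , drop = FALSE]
      i <<- i + n
      out
    }
  })
  real <- toy_store(per_class = 2, seed = 71)   # 4 images; use first 3
  real <- store_subset(real, 1:3)
  syn <- real$images[1:2, , , drop = FALSE]
  nn <- nearest_neighbors(syn, real, extractor)
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(nn$nearest_real_id[1], real$image_id[1])  # identical -> dist 0
  expect_equal(nn$distance[1], 0, tolerance = 1e-12)
  d2 <- apply(fr, 1, cosd, u = fs[2, ])
  expect_equal(nn$nearest_real_id[2], real$image_id[which.min(d2)])
  expect_equal(nn$distance[2], min(d2), tolerance = 1e-12)
  expect_true(all(nn$distance >= 0 & nn$distance <= 2))
})

test_that("every training image is its own nearest neighbour at distance 0", {
  store <- toy_store(per_class = 6, seed = 72)
  cfg <- fast_clf_config()
  model <- synthrad:::with_seed(3, synthrad:::build_classifier(cfg, 2))
  nn <- nearest_neighbors(store, store, model)
  expect_equal(nn$distance, rep(0, store_size(store)), tolerance = 1e-10)
  expect_identical(nn$nearest_real_id, store$image_id)
  expect_error(nearest_neighbors(store, store_subset(store, integer(0)), model),
               "empty")
})

test_that("reader records compute the published accuracy formula", {
  r <- reader_record(TR = 40, TS = 31, FR = 19, FS = 10)
  expect_equal(r$acc, 0.71)
  expect_equal(r$n_real, 50)
  expect_equal(r$n_synthetic, 50)
  all_right <- reader_record(TR = 50, TS = 50, FR = 0, FS = 0)
  expect_equal(all_right$acc, 1)
  expect_error(reader_record(0, 0, 0, 0), "zero total")
})

test_that("exact Wilcoxon branch equals enumeration over all 2^n sign vectors", {
  brute_p <- function(x, mu) {
    d <- x - mu; d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
    mean(ws >= w_obs)
  }
  set.seed(73)
  for (k in 1:15) {
    n <- sample(3:10, 1)
    x <- 0.5 + round(rnorm(n, 0.05, 0.1), 2)   # rounding induces ties
    x <- x[x != 0.5]
    if (length(x) < 2) next
    r <- wilcoxon_signed_rank(x, mu = 0.5, alternative = "greater")
    expect_equal(r$method, "exact")
    expect_equal(r$p, brute_p(x, 0.5), tolerance = 1e-12)
  }
})

test_that("reader_study_stats tests only panels of >= 5 readers", {
  recs <- lapply(c(60, 55, 58, 62, 53, 57), function(tr)
    reader_record(TR = tr, TS = tr - 5, FR = 55 - tr + 10, FS = 50 - tr + 45))
  small <- reader_study_stats(recs[1:3])
  expect_null(small$test)
  expect_equal(small$mean_acc, mean(vapply(recs[1:3], `[[`, 1, "acc")))
  full <- reader_study_stats(recs)
  expect_false(is.null(full$test))
  expect_true(full$test$p >= 0 && full$test$p <= 1)
})

test_that("uniform random labelling has expected accuracy 0.5", {
  r <- reader_null_accuracy(n_images = 100, n_draws = 1e5, seed = 4)
  expect_equal(r$analytic, 0.5)
  expect_lt(abs(r$monte_carlo - 0.5), 0.001)
})
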