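# Gaussian summaries, the Frechet distance, the fixed-N cycling protocol and
# the convergence controller.

test_that("summarize_features has the documented moments", {
  f <- matrix(c(0, 2), 2, 1)
  s <- summarize_features(f)
  expect_equal(s$m, 1)
  expect_equal(as.vector(s$C), 2)          # divisor n - 1: ((0-1)^2+(2-1)^2)/1
  expect_equal(s$n, 2)
  # identical vectors -> zero covariance
  s0 <- summarize_features(matrix(1, 5, 3))
  expect_equal(unname(s0$C), matrix(0, 3, 3))
  # permutation invariance
  set.seed(31)
  m <- matrix(rnorm(30), 10, 3)
  s1 <- summarize_features(m)
  s2 <- summarize_features(m[sample(10), ])
  expect_equal(s1$m, s2$m)
  expect_equal(s1$C, s2$C)
  expect_error(summarize_features(matrix(1, 1, 3)), "at least 2")
})

test_that("frechet_distance matches the 1-D closed form on 100 random pairs", {
  set.seed(32)
  for (k in 1:100) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    c1 <- rexp(1) + 0.01; c2 <- rexp(1) + 0.01
    A <- structure(list(m = m1, C = matrix(c1), n = 10),
                   class = "gaussian_summary")
    B <- structure(list(m = m2, C = matrix(c2), n = 10),
                   class = "gaussian_summary")
    closed <- (m1 - m2)^2 + c1 + c2 - 2 * sqrt(c1 * c2)
    expect_equal(frechet_distance(A, B), max(closed, 0), tolerance = 1e-10)
  }
  # closed-form case: m=0,C=1 vs m=1,C=1 -> 1
  A <- summarize_features(matrix(c(-1, 1), 2) / sqrt(2))
  expect_equal(frechet_distance(
    structure(list(m = 0, C = matrix(1), n = 2), class = "gaussian_summary"),
    structure(list(m = 1, C = matrix(1), n = 2), class = "gaussian_summary")), 1)
})

test_that("frechet_distance agrees with an eigendecomposition oracle on SPD pairs", {
  set.seed(33)
  rspd <- function(d) { M <- matrix(rnorm(d * d), d); M %*% t(M) + 0.1 * diag(d) }
  for (k in 1:100) {
    C1 <- rspd(3); C2 <- rspd(3)
    m1 <- rnorm(3); m2 <- rnorm(3)
    A <- structure(list(m = m1, C = C1, n = 10), class = "gaussian_summary")
    B <- structure(list(m = m2, C = C2, n = 10), class = "gaussian_summary")
    # independent oracle: sqrtm of the (non-symmetric) product C1 C2 directly
    e <- eigen(C1 %*% C2)
    S <- Re(e$vectors %*% diag(sqrt(as.complex(e$values))) %*% solve(e$vectors))
    oracle <- sum((m1 - m2)^2) + sum(diag(C1 + C2 - 2 * S))
    d2 <- frechet_distance(A, B)
    expect_equal(d2, oracle, tolerance = 1e-8)
    # symmetry and identity
    expect_equal(d2, frechet_distance(B, A), tolerance = 1e-8)
    expect_equal(frechet_distance(A, A), 0, tolerance = 1e-8)
    expect_gte(d2, 0)
  }
})

test_that("assemble_fid_sample cycles the real fold with usage counts within 1", {
  store <- toy_store(per_class = 20, seed = 3)    # 40 images
  s <- assemble_fid_sample(store, N = 100, seed = 2)
  expect_length(s$real_idx, 100)
  use <- table(factor(s$real_idx, levels = seq_len(40)))
  expect_true(all(use %in% c(2, 3)))
  expect_equal(sum(use), 100)
  # |fold| = N -> each image exactly once
  s2 <- assemble_fid_sample(store, N = 40, seed = 2)
  expect_true(all(table(s2$real_idx) == 1))
  # synthetic side conditioned on the repeated labels
  sampler <- function(labels, seed) array(0.5, c(nrow(labels), 16, 16))
  s3 <- assemble_fid_sample(store, N = 50, seed = 2, sampler = sampler)
  expect_equal(dim(s3$synthetic), c(50, 16, 16))
  expect_identical(s3$labels, store$labels[s3$real_idx, ])
  # protocol default is N = 10,000 with 400k cadence and patience 2
  proto <- fid_protocol()
  expect_equal(proto$N, 10000L)
  expect_equal(proto$eval_cadence, 400000)
  expect_equal(proto$patience, 2L)
})

test_that("convergence controller implements the two-strike rule after the budget", {
  proto <- fid_protocol(N = 10, eval_cadence = 1, patience = 2, min_images = 5)
  tr <- function(seen, fid) data.frame(real_images_seen = seen, fid = fid)
  # strictly decreasing trace never stops
  expect_equal(convergence_check(tr(5:10, seq(10, 5)), proto), "continue")
  # trace [10, 9, 9.5, 9.4]: stop at the 4th evaluation
  expect_equal(convergence_check(tr(5:8, c(10, 9, 9.5, 9.4)), proto), "stop")
  expect_equal(convergence_check(tr(5:7, c(10, 9, 9.5)), proto), "continue")
  # evaluations before the minimum budget are not counted
  expect_equal(convergence_check(tr(1:4, c(10, 9, 9.5, 9.4)), proto), "continue")
  expect_equal(convergence_check(tr(c(1, 2, 6, 7, 8), c(5, 4, 10, 11, 12)),
                                 proto), "stop")
})

test_that("FID under identity generators concentrates towards 0 as N grows", {
  spec <- toy_spec(resolution = 8)
  store <- generate_dataset(spec, default_class_list(2, 2), per_class = 400,
                            seed = 13)
  emb <- fid_embedder(8, dim = 8)
  sampler <- function(labels, seed) {
    idx <- synthrad:::with_seed(seed, sample(store_size(store), nrow(labels),
                                             replace = TRUE))
    store$images[idx, , , drop = FALSE]
  }
  med_fid <- vapply(c(100, 400, 1600), function(N) {
    stats::median(vapply(1:3, function(r) {
      compute_fid(emb, store, sampler, N = N, seed = 100 + r)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_fid) < 0))
  expect_lt(med_fid[3], med_fid[1] / 2)
})
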