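# Conditional normalisation, projection scoring, minibatch stddev, losses,
# the progressive schedule, and forward-pass contracts.

test_that("conditional pixel norm matches a per-channel scalar oracle", {
  set.seed(21)
  n <- 3; cc <- 4; zd <- 5; L <- 2
  a <- array(rnorm(n * 2 * 2 * cc), c(n, 2, 2, cc))
  z <- matrix(rnorm(n * zd), n)
  y <- matrix(rbinom(n * L, 1, 0.5), n)
  params <- list(W1 = matrix(rnorm((zd + L) * cc), zd + L),
                 b1 = rnorm(cc),
                 W2 = matrix(rnorm((zd + L) * cc), zd + L),
                 b2 = rnorm(cc), eps = 1e-8)
  out <- conditional_pixel_norm(a, z, y, params)
  # independent oracle: evaluate the normalisation formula element by element
  zy <- cbind(z, y)
  for (i in seq_len(n)) for (x in 1:2) for (yy in 1:2) for (ch in seq_len(cc)) {
    gamma <- sum(zy[i, ] * params$W1[, ch]) + params$b1[ch]
    beta <- sum(zy[i, ] * params$W2[, ch]) + params$b2[ch]
    rms <- sqrt(mean(a[i, x, yy, ]^2) + 1e-8)
    expect_equal(out[i, x, yy, ch], a[i, x, yy, ch] / rms * gamma + beta,
                 tolerance = 1e-12)
  }
})

test_that("degenerate conditioning reduces to plain pixel norm; gamma=1 self-normalises", {
  set.seed(22)
  a <- array(rnorm(2 * 4 * 4 * 8), c(2, 4, 4, 8))
  z <- matrix(rnorm(2 * 3), 2); y <- matrix(c(1, 0), 2, 1)
  zero <- matrix(0, 4, 8)
  params <- list(W1 = zero, b1 = rep(1, 8), W2 = zero, b2 = rep(0, 8))
  expect_equal(conditional_pixel_norm(a, z, y, params), pixel_norm(a),
               tolerance = 1e-12)
  # constant positive channels -> outputs ~ 1
  ac <- array(3, c(1, 2, 2, 8))
  out <- conditional_pixel_norm(ac, matrix(0, 1, 3), matrix(0, 1, 1), params)
  expect_equal(as.vector(out), rep(1, 32), tolerance = 1e-6)
  # unit RMS property of the plain norm
  pn <- pixel_norm(a)
  expect_equal(apply(pn^2, c(1, 2, 3), mean), array(1, c(2, 4, 4)),
               tolerance = 1e-6)
})

test_that("projection score is exact and linear in the labels", {
  f <- matrix(c(1, 2, 3, -1, 0.5, 2), 2, byrow = TRUE)
  emb <- matrix(c(0.1, -0.2, 0.3, 1, 0, -1), 2, 3, byrow = TRUE)
  head <- list(w = c(1, -1, 2), b = 0.5)
  y <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  s <- projection_score(f, y, emb, head)
  # arithmetic oracle, hand-expanded
  expect_equal(s[1], (1 - 2 + 6) + 0.5 + sum(emb[1, ] * f[1, ]))
  expect_equal(s[2], (-1 - 0.5 + 4) + 0.5 + sum((emb[1, ] + emb[2, ]) * f[2, ]))
  # zero labels -> unconditional head alone
  s0 <- projection_score(f, matrix(0, 2, 2), emb, head)
  expect_equal(s0, drop(f %*% head$w) + head$b)
  # superposition over random label pairs
  set.seed(23)
  for (k in 1:10) {
    y1 <- matrix(rbinom(2, 1, 0.5), 1); y2 <- matrix(rbinom(2, 1, 0.5), 1)
    fr <- matrix(rnorm(3), 1)
    lhs <- projection_score(fr, y1 + y2, emb, head)
    rhs <- projection_score(fr, y1, emb, head) +
      projection_score(fr, y2, emb, head) - (drop(fr %*% head$w) + head$b)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("minibatch stddev channel has the documented statistics", {
  x <- array(rnorm(4 * 2 * 2 * 3), c(4, 2, 2, 3))
  out <- minibatch_stddev_channel(x)
  expect_equal(dim(out), c(4, 2, 2, 4))
  expect_equal(out[, , , 1:3], x)
  # identical members -> zero channel
  xc <- array(rep(rnorm(12), each = 4), c(4, 2, 2, 3))
  expect_equal(as.vector(minibatch_stddev_channel(xc)[, , , 4]), rep(0, 16),
               tolerance = 1e-12)
  # shift invariance
  expect_equal(minibatch_stddev_channel(x + 5)[, , , 4], out[, , , 4],
               tolerance = 1e-12)
  # two 1x1x1 maps {0, 2}: population std over the batch = 1
  x2 <- array(c(0, 2), c(2, 1, 1, 1))
  expect_equal(as.vector(minibatch_stddev_channel(x2)[, , , 2]), c(1, 1))
  # batch of one: defined as a zero channel
  expect_equal(as.vector(minibatch_stddev_channel(x[1, , , , drop = FALSE])[, , , 4]),
               rep(0, 4))
})

test_that("WGAN-GP losses match analytic cases and the mode contract", {
  cfg_cpd <- gan_config("cpd", resolution = 8, n_labels = 2, z_dim = 4)
  # unit-norm input gradients -> zero penalty
  g_unit <- array(0, c(3, 2, 2, 1)); g_unit[, 1, 1, 1] <- 1
  l0 <- gan_losses(real_scores = c(1, 2, 3), fake_scores = c(0, 0, 0),
                   interp_grads = g_unit, config = cfg_cpd)
  expect_equal(l0$penalty, 0)
  expect_equal(l0$d_loss, 0 - 2)
  expect_equal(l0$g_loss, 0)
  # 1-D critic f(x) = 2x: gradient 2 -> penalty gp_weight * (2 - 1)^2
  l1 <- gan_losses(0, 0, interp_grads = array(2, c(1, 1, 1, 1)),
                   config = cfg_cpd)
  expect_equal(l1$penalty, 10 * (2 - 1)^2)
  # cpd mode carries no aux terms; prog requires them
  expect_error(gan_losses(0, 0, g_unit[1, , , , drop = FALSE],
                          gan_config("prog", resolution = 8, n_labels = 2)),
               "aux")
  y <- matrix(c(1, 0), 1)
  lp <- gan_losses(0, 0, array(1/2, c(1, 2, 1, 1)),
                   gan_config("prog", resolution = 8, n_labels = 2),
                   labels = y, aux_real = matrix(c(5, -5), 1),
                   aux_fake = matrix(c(5, -5), 1))
  # near-perfect aux prediction adds ~0 to both losses; penalty (sqrt(1/2)-1)^2
  expect_equal(lp$penalty, 10 * (sqrt(0.5) - 1)^2, tolerance = 1e-12)
  expect_lt(lp$d_loss - lp$penalty, 1e-3)
})

test_that("progressive schedule reproduces the published budgets", {
  s1 <- progressive_schedule(8, 32, 1.4e6)
  expect_equal(nrow(s1), 5)
  expect_equal(attr(s1, "total"), 7e6)
  s2 <- progressive_schedule(8, 128, 1e6)
  expect_equal(nrow(s2), 9)
  expect_equal(attr(s2, "total"), 9e6)
  s3 <- progressive_schedule(16, 16, 1e6)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$kind, "stabilize")
  # phase count identity
  for (tgt in c(8, 16, 32, 64)) {
    s <- progressive_schedule(8, tgt, 1)
    expect_equal(nrow(s), 2 * log2(tgt / 8) + 1)
  }
})

test_that("generator/discriminator passes are shape-consistent across resolutions", {
  for (res in c(8, 16, 32, 64)) {
    for (kind in c("cpd", "prog")) {
      cfg <- gan_config(kind, resolution = res, z_dim = 8, n_labels = 3,
                        max_channels = 8, batch_size = 2)
      G <- synthrad:::with_seed(1, synthrad:::build_generator(cfg))
      D <- synthrad:::with_seed(2, synthrad:::build_discriminator(cfg))
      z <- matrix(rnorm(2 * 8), 2)
      y <- matrix(c(1, 0, 0, 0, 1, 1), 2)
      img <- synthrad:::g_forward(G, z, y)$img
      expect_equal(dim(img), c(2, res, res, 1))
      out <- synthrad:::d_forward(D, img, y)
      expect_length(out$score, 2)
      if (kind == "prog") expect_equal(dim(out$aux_logits), c(2, 3))
    }
  }
})

test_that("generation is deterministic, bounded, label- and seed-sensitive", {
  cfg <- gan_config("cpd", resolution = 16, z_dim = 8, n_labels = 2,
                    max_channels = 8)
  G <- synthrad:::with_seed(4, synthrad:::build_generator(cfg))
  gan <- structure(list(generator = G, config = cfg), class = "trained_gan")
  y <- matrix(c(1, 0, 0, 1), 2)
  a <- gan_generate(gan, y, seed = 5)
  expect_identical(a, gan_generate(gan, y, seed = 5))
  expect_equal(dim(a), c(2, 16, 16))
  expect_true(all(a >= -1 & a <= 1))
  b <- gan_generate(gan, y, seed = 6)
  expect_false(identical(a, b))        # fresh noise -> different images
  expect_error(gan_generate(gan, matrix(1, 1, 3)), "dimensionality")
  smp <- as_conditional_sampler(gan)(y, 5)
  expect_true(all(smp >= 0 & smp <= 1))
  expect_equal(dim(smp), c(2, 16, 16))
})
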