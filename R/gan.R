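# Public GAN operations: conditional pixel normalisation, projection scoring,
# minibatch stddev, WGAN-GP losses, the progressive schedule, training with
# FID-based stopping, and conditional generation.

#' Conditional pixel-wise feature vector normalisation
#'
#' Normalises each pixel's feature vector to unit RMS over channels and
#' applies a label- and noise-dependent affine transform:
#' \deqn{b_i = a_i / \sqrt{1/N \sum_j a_j^2 + \epsilon} \cdot \gamma_i + \beta_i}
#' with \eqn{\gamma = W_1 [z;y] + b_1} and \eqn{\beta = W_2 [z;y] + b_2}.
#' With \eqn{W_1 = 0, b_1 = 1, W_2 = 0, b_2 = 0} this reduces to plain
#' pixel-wise feature vector normalisation.
#'
#' @param a Feature map array (batch, height, width, channels).
#' @param z Noise matrix (batch x z_dim).
#' @param y Binary label matrix (batch x n_labels).
#' @param params List with `W1`, `b1`, `W2`, `b2` (and optionally `eps`,
#'   default 1e-8): `W1`, `W2` have one row per `[z;y]` entry and one column
#'   per channel.
#' @return Normalised feature map, same shape as `a`.
#' @export
conditional_pixel_norm <- function(a, z, y, params) {
  check_that(length(dim(a)) == 4, "a must be a (n,h,w,c) array")
  zy <- cbind(as.matrix(z), as.matrix(y))
  cc <- dim(a)[4]
  check_that(ncol(params$W1) == cc && ncol(params$W2) == cc &&
               nrow(params$W1) == ncol(zy) && nrow(params$W2) == ncol(zy),
             "conditioning parameters are not dimensioned for ", cc, " channels")
  eps <- params$eps %||% 1e-8
  gamma <- sweep(zy %*% params$W1, 2, params$b1, "+")
  beta <- sweep(zy %*% params$W2, 2, params$b2, "+")
  cpixnorm_fw(a, gamma, beta, eps)$out
}

#' Projection-discriminator score
#'
#' Conditioning by inner product: the score is the unconditional head applied
#' to the (sum-pooled) discriminator features plus the inner product between
#' the embedded label vector and the features — exactly linear in `y`.
#'
#' @param features Pooled feature matrix (batch x F).
#' @param y Label matrix (batch x L).
#' @param embedding Embedding weight matrix (L x F).
#' @param head List with `w` (length F) and `b` (scalar): the unconditional
#'   linear head.
#' @return Numeric score vector (batch).
#' @export
projection_score <- function(features, y, embedding, head) {
  features <- as.matrix(features); y <- as.matrix(y)
  check_that(ncol(y) == nrow(embedding) && ncol(features) == ncol(embedding),
             "embedding dimensions do not match features/labels")
  check_that(length(head$w) == ncol(features), "head dimension mismatch")
  drop(features %*% head$w) + head$b + rowSums((y %*% embedding) * features)
}

#' Append the minibatch standard deviation channel
#'
#' Computes the across-batch standard deviation of every feature (population
#' divisor), averages it over all channels and positions, and appends the
#' resulting scalar as one extra constant feature channel — the diversity
#' feature of the progressive-growing discriminator. A batch of one yields a
#' zero channel.
#'
#' @param x Feature map array (batch, height, width, channels).
#' @return Array with one extra channel.
#' @export
minibatch_stddev_channel <- function(x) {
  check_that(length(dim(x)) == 4, "x must be a (n,h,w,c) array")
  if (dim(x)[1] < 2) {
    d <- dim(x)
    out <- array(0, c(d[1], d[2], d[3], d[4] + 1L))
    out[, , , seq_len(d[4])] <- x
    return(out)
  }
  mbstd_fw(x, eps = 0)$out
}

#' WGAN-GP generator and discriminator losses
#'
#' Discriminator (critic) loss: mean fake score - mean real score +
#' `gp_weight * mean((||grad|| - 1)^2)` over interpolates. Generator loss:
#' -mean fake score. In `prog` mode the auxiliary softmax cross-entropy
#' between true and predicted labels is added for real and fake images to the
#' discriminator loss and for fake images to the generator loss; `cpd` mode
#' has no auxiliary terms.
#'
#' @param real_scores,fake_scores Critic score vectors.
#' @param interp_grads Per-sample critic input gradients at interpolates: an
#'   array whose first dimension indexes samples.
#' @param config A [gan_config()].
#' @param labels Label matrix (needed for aux terms in prog mode).
#' @param aux_real,aux_fake Aux-classifier logit matrices (prog mode).
#' @return List with `g_loss`, `d_loss`, `penalty`, `wasserstein`.
#' @export
gan_losses <- function(real_scores, fake_scores, interp_grads, config,
                       labels = NULL, aux_real = NULL, aux_fake = NULL) {
  gnorm <- grad_norms(interp_grads)
  penalty <- config$gp_weight * mean((gnorm - 1)^2)
  wass <- mean(fake_scores) - mean(real_scores)
  d_loss <- wass + penalty
  g_loss <- -mean(fake_scores)
  if (config$kind == "prog") {
    check_that(!is.null(aux_real) && !is.null(aux_fake) && !is.null(labels),
               "prog mode requires aux logits and labels")
    d_loss <- d_loss + config$aux_weight *
      (softmax_xent(aux_real, labels)$loss + softmax_xent(aux_fake, labels)$loss)
    g_loss <- g_loss + config$aux_weight * softmax_xent(aux_fake, labels)$loss
  }
  list(g_loss = g_loss, d_loss = d_loss, penalty = penalty, wasserstein = wass)
}

grad_norms <- function(g) {
  d <- dim(g)
  if (is.null(d)) return(abs(g))
  m <- matrix(g, d[1], prod(d[-1]))
  sqrt(rowSums(m^2))
}

# softmax cross-entropy with multi-hot targets: the target distribution is
# y / sum(y), uniform for the all-zero "no finding" vector
softmax_xent <- function(logits, y) {
  t <- y
  s <- rowSums(t)
  t[s == 0, ] <- 1
  t <- t / rowSums(t)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  loss <- -mean(rowSums(t * log(pmax(p, 1e-12))))
  list(loss = loss, dlogits = (p - t) / nrow(logits))
}

#' Progressive-growing phase schedule
#'
#' The schedule is an initial stabilisation phase at the start resolution
#' followed by a (transition, stabilisation) pair per resolution doubling;
#' each phase lasts `images_per_phase` real images, so the total budget is
#' `(2 * log2(target/start) + 1) * images_per_phase`.
#'
#' @param start_res,target_res Powers of two, start <= target.
#' @param images_per_phase Real images per phase.
#' @return Data frame with `phase`, `res`, `kind` ("stabilize"/"transition"),
#'   `images`, `cum_images`; attribute `total` carries the full budget.
#' @export
progressive_schedule <- function(start_res, target_res, images_per_phase) {
  check_that(is_power_of_two(start_res) && is_power_of_two(target_res) &&
               start_res <= target_res, "invalid resolution pair")
  res <- c(start_res)
  kind <- c("stabilize")
  r <- start_res
  while (r < target_res) {
    r <- r * 2
    res <- c(res, r, r)
    kind <- c(kind, "transition", "stabilize")
  }
  out <- data.frame(phase = seq_along(res), res = as.integer(res), kind = kind,
                    images = images_per_phase,
                    cum_images = cumsum(rep(images_per_phase, length(res))))
  attr(out, "total") <- length(res) * images_per_phase
  out
}

# growth state (level, alpha) for a prog run after `seen` real images
schedule_position <- function(schedule, seen, start_res) {
  p <- findInterval(seen, schedule$cum_images, left.open = FALSE) + 1L
  p <- min(p, nrow(schedule))
  row <- schedule[p, ]
  level <- as.integer(log2(row$res / start_res)) + 1L
  alpha <- 1
  if (row$kind == "transition") {
    start <- if (p == 1) 0 else schedule$cum_images[p - 1]
    alpha <- min(1, max(1e-6, (seen - start) / row$images))
  }
  list(level = level, alpha = alpha)
}

# ---- training ----------------------------------------------------------------

#' Train a conditional GAN with FID-based stopping
#'
#' Runs `n_critic` critic updates per generator update with WGAN-GP (plus
#' auxiliary classifier terms in prog mode, projection conditioning in cpd
#' mode), equalised learning rate, and — in prog mode — the progressive
#' growth schedule with smooth head interpolation. After the protocol's
#' minimum real-image budget, FID between `protocol$N` real and fresh
#' synthetic images is evaluated every `protocol$eval_cadence` real images;
#' training stops after `protocol$patience` consecutive non-improving
#' evaluations (or at `config$max_images`).
#'
#' The parameter gradient of the gradient-penalty term is computed with a
#' central-difference Hessian-vector product (two extra perturbed backward
#' passes); the input gradient itself is exact.
#'
#' @param train_fold A `dataset_store` (images in [0,1]).
#' @param config A [gan_config()].
#' @param protocol A [fid_protocol()].
#' @param seed Integer seed.
#' @param embedder Optional [fid_embedder()]; built automatically when NULL.
#' @return Object of class `trained_gan`: generator, discriminator, config,
#'   and `state` (FID trace, images seen, stop reason).
#' @export
train_gan <- function(train_fold, config, protocol, seed = 1L, embedder = NULL) {
  check_that(store_size(train_fold) > 0, "train fold is empty")
  check_that(train_fold$resolution == config$resolution,
             "data resolution ", train_fold$resolution,
             " does not match config resolution ", config$resolution)
  check_that(ncol(train_fold$labels) == config$n_labels,
             "label dimensionality mismatch")
  if (is.null(embedder))
    embedder <- fid_embedder(min(config$resolution, 16L))
  G <- with_seed(fanout_seed(seed, 1L), build_generator(config))
  D <- with_seed(fanout_seed(seed, 2L), build_discriminator(config))
  optG <- adam_new(G$params, lr = config$lr, beta1 = config$beta1,
                   beta2 = config$beta2)
  optD <- adam_new(D$params, lr = config$lr, beta1 = config$beta1,
                   beta2 = config$beta2)
  schedule <- if (config$kind == "prog")
    progressive_schedule(config$start_resolution, config$resolution,
                         config$images_per_phase)
  else NULL
  n <- store_size(train_fold)
  bs <- config$batch_size
  seen <- 0
  next_eval <- protocol$min_images
  trace <- data.frame(real_images_seen = numeric(0), fid = numeric(0))
  stop_reason <- "max_images"
  imgs_all <- as_model_input(train_fold$images)   # (n, res, res, 1) in [-1,1]
  with_seed(fanout_seed(seed, 3L), {
    repeat {
      if (seen >= config$max_images) break
      pos <- if (is.null(schedule)) list(level = nrow(G$lv), alpha = 1)
             else schedule_position(schedule, seen, config$start_resolution)
      cur_res <- G$lv$res[pos$level]
      for (ic in seq_len(config$n_critic)) {
        idx <- sample(n, bs, replace = bs > n)
        x_r <- imgs_all[idx, , , , drop = FALSE]
        if (cur_res < config$resolution) x_r <- downsample_to(x_r, cur_res)
        y <- train_fold$labels[idx, , drop = FALSE]
        step <- d_train_step(G, D, x_r, y, config, pos)
        upd <- adam_step(optD, D$params, step$grads)
        optD <- upd$opt; D$params <- upd$params
        seen <- seen + bs
      }
      y_g <- train_fold$labels[sample(n, bs, replace = bs > n), , drop = FALSE]
      gstep <- g_train_step(G, D, y_g, config, pos)
      upd <- adam_step(optG, G$params, gstep$grads)
      optG <- upd$opt; G$params <- upd$params
      if (seen >= next_eval && pos$alpha >= 1 &&
            pos$level == nrow(G$lv)) {
        gan <- structure(list(generator = G, config = config), class = "trained_gan")
        fid <- compute_fid(embedder, train_fold, as_conditional_sampler(gan),
                           N = protocol$N,
                           seed = fanout_seed(seed, 1000L + nrow(trace)))
        trace <- rbind(trace, data.frame(real_images_seen = seen, fid = fid))
        next_eval <- seen + protocol$eval_cadence
        if (convergence_check(trace, protocol) == "stop") {
          stop_reason <- "fid_converged"
          break
        }
      }
      if (seen >= config$max_images) break
    }
  })
  structure(list(generator = G, discriminator = D, config = config,
                 state = list(fid_trace = trace, real_images_seen = seen,
                              stop_reason = stop_reason, seed = seed)),
            class = "trained_gan")
}

#' @export
print.trained_gan <- function(x, ...) {
  cat(sprintf("trained_gan (%s): %dx%d px, %d labels; %s after %.3g real images; %d FID evaluations\n",
              x$config$kind, x$config$resolution, x$config$resolution,
              x$config$n_labels, x$state$stop_reason,
              x$state$real_images_seen, nrow(x$state$fid_trace)))
  invisible(x)
}

# one critic update: WGAN-GP (+ aux in prog mode)
d_train_step <- function(G, D, x_r, y, config, pos) {
  bs <- dim(x_r)[1]
  z <- matrix(stats::rnorm(bs * config$z_dim), bs)
  gf <- g_forward(G, z, y, pos$level, pos$alpha)
  x_f <- gf$img
  fwd_f <- d_forward(D, x_f, y, pos$level, pos$alpha)
  fwd_r <- d_forward(D, x_r, y, pos$level, pos$alpha)
  d_aux_f <- d_aux_r <- NULL
  if (config$kind == "prog") {
    d_aux_f <- config$aux_weight * softmax_xent(fwd_f$aux_logits, y)$dlogits
    d_aux_r <- config$aux_weight * softmax_xent(fwd_r$aux_logits, y)$dlogits
  }
  bw_f <- d_backward(D, fwd_f$cache, rep(1 / bs, bs), d_aux_f)
  bw_r <- d_backward(D, fwd_r$cache, rep(-1 / bs, bs), d_aux_r)
  grads <- grad_acc(bw_f$grads, bw_r$grads)
  # gradient penalty on interpolates
  u <- stats::runif(bs)
  x_i <- x_r * array(u, dim(x_r)) + x_f * array(1 - u, dim(x_f))
  fwd_i <- d_forward(D, x_i, y, pos$level, pos$alpha)
  bw_i <- d_backward(D, fwd_i$cache, rep(1, bs))
  g_in <- bw_i$dx
  gn <- grad_norms(g_in)
  coef <- config$gp_weight * (gn - 1) / pmax(gn, 1e-12) / bs
  v <- g_in * array(2 * coef, dim(g_in))
  eps_fd <- 1e-4 / max(max(abs(v)), 1e-12)
  fwd_p <- d_forward(D, x_i + eps_fd * v, y, pos$level, pos$alpha)
  bw_p <- d_backward(D, fwd_p$cache, rep(1, bs))
  fwd_m <- d_forward(D, x_i - eps_fd * v, y, pos$level, pos$alpha)
  bw_m <- d_backward(D, fwd_m$cache, rep(1, bs))
  for (nm in names(bw_p$grads)) {
    grads[[nm]] <- grads[[nm]] +
      (bw_p$grads[[nm]] - bw_m$grads[[nm]]) / (2 * eps_fd)
  }
  list(grads = grads,
       d_loss = mean(fwd_f$score) - mean(fwd_r$score) +
         config$gp_weight * mean((gn - 1)^2))
}

# one generator update
g_train_step <- function(G, D, y, config, pos) {
  bs <- nrow(y)
  z <- matrix(stats::rnorm(bs * config$z_dim), bs)
  gf <- g_forward(G, z, y, pos$level, pos$alpha)
  fwd <- d_forward(D, gf$img, y, pos$level, pos$alpha)
  d_aux <- NULL
  if (config$kind == "prog")
    d_aux <- config$aux_weight * softmax_xent(fwd$aux_logits, y)$dlogits
  bw <- d_backward(D, fwd$cache, rep(-1 / bs, bs), d_aux)
  grads <- g_backward(G, gf$cache, bw$dx)
  list(grads = grads, g_loss = -mean(fwd$score))
}

# ---- generation --------------------------------------------------------------

#' Generate images conditioned on label vectors
#'
#' One image per label row, deterministic in (weights, labels, seed); output
#' values lie in [-1,1] (tanh for cpd; prog output is clipped).
#'
#' @param gan A `trained_gan` (or list with `generator` and `config`).
#' @param labels Binary label matrix (n x n_labels).
#' @param seed Integer seed for the input noise.
#' @return Image array (n, res, res) in [-1,1].
#' @export
gan_generate <- function(gan, labels, seed = 1L) {
  labels <- as.matrix(labels)
  cfg <- gan$config
  check_that(ncol(labels) == cfg$n_labels, "label dimensionality mismatch")
  check_that(all(labels %in% c(0, 1)), "labels must be binary")
  n <- nrow(labels)
  z <- with_seed(seed, matrix(stats::rnorm(n * cfg$z_dim), n))
  out <- array(0, c(n, cfg$resolution, cfg$resolution))
  # generate in chunks to bound memory
  chunk <- max(1L, min(n, 256L))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    img <- g_forward(gan$generator, z[i:j, , drop = FALSE],
                     labels[i:j, , drop = FALSE])$img
    out[i:j, , ] <- img[, , , 1]
    i <- j + 1L
  }
  pmin(pmax(out, -1), 1)
}

#' Wrap a trained GAN as a conditional dataset sampler
#'
#' Returns a function `(labels, seed) -> images` producing images in [0,1]
#' (the dataset-store convention), for use with
#' [make_equivalent_synthetic_folds()] and [compute_fid()].
#'
#' @param gan A `trained_gan`.
#' @return A sampler function.
#' @export
as_conditional_sampler <- function(gan) {
  force(gan)
  function(labels, seed) (gan_generate(gan, labels, seed) + 1) / 2
}
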