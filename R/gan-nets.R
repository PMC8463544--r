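# Generator / discriminator network definitions with hand-coded forward and
# backward passes.
#
# Two model kinds share one parameter layout:
#  * "prog": progressive-growing reference — plain pixel-wise feature
#    normalisation, a single to-image head at the current resolution (blended
#    with the previous head during transition phases), auxiliary-classifier
#    conditioning in the discriminator, WGAN-GP, minibatch stddev, equalised
#    learning rate.
#  * "cpd": no growth; conditional pixel normalisation (scale gamma and bias
#    beta computed from [z;y]) after every generator convolution, to-image
#    output-skip heads at every resolution summed in image space, tanh output,
#    residual discriminator blocks, projection conditioning.

#' GAN configuration
#'
#' @param kind `"cpd"` (conditional pixel-norm + projection discriminator) or
#'   `"prog"` (progressive-growing reference).
#' @param resolution Target image resolution (power of two >= 8).
#' @param start_resolution Base resolution of the architecture (default 8,
#'   the lowest resolution at which the source images remain informative).
#' @param z_dim Noise dimension (default 512; desk-scale runs use less).
#' @param n_labels Number of binary condition labels.
#' @param max_channels Channel count at and below 32 px, halved per resolution
#'   doubling above (default 64 at desk scale; 512 at full GPU scale).
#' @param n_critic Discriminator updates per generator update (default 1).
#' @param gp_weight Gradient-penalty weight (default 10).
#' @param aux_weight Auxiliary classifier loss weight, prog only (default 1).
#' @param lr,beta1,beta2 Adam settings (defaults 1e-3, 0, 0.99).
#' @param batch_size Minibatch size (default 16).
#' @param images_per_phase Real images per progressive phase (prog only;
#'   default 1.4e6 — the full-scale protocol value, overridden at desk scale).
#' @param eqlr Apply equalised learning rate (runtime He rescaling).
#' @param max_images Hard cap on real images seen (safety bound for training).
#' @return Object of class `gan_config`.
#' @export
gan_config <- function(kind = c("cpd", "prog"), resolution = 32,
                       start_resolution = 8, z_dim = 512L, n_labels,
                       max_channels = 64L, n_critic = 1L, gp_weight = 10,
                       aux_weight = 1, lr = 1e-3, beta1 = 0, beta2 = 0.99,
                       batch_size = 16L, images_per_phase = 1.4e6,
                       eqlr = TRUE, max_images = Inf) {
  kind <- match.arg(kind)
  check_that(is_power_of_two(resolution) && is_power_of_two(start_resolution),
             "resolutions must be powers of two")
  check_that(start_resolution <= resolution, "start_resolution > resolution")
  check_that(n_critic >= 1, "n_critic must be >= 1")
  structure(list(kind = kind, resolution = as.integer(resolution),
                 start_resolution = as.integer(start_resolution),
                 z_dim = as.integer(z_dim), n_labels = as.integer(n_labels),
                 max_channels = as.integer(max_channels),
                 n_critic = as.integer(n_critic), gp_weight = gp_weight,
                 aux_weight = aux_weight, lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 images_per_phase = images_per_phase, eqlr = eqlr,
                 max_images = max_images),
            class = "gan_config")
}

# channel schedule: constant up to 32 px, halved per doubling above
gan_channels <- function(res, max_channels) {
  if (res <= 32) max_channels
  else max(4L, as.integer(max_channels / 2^(log2(res) - 5)))
}

gan_levels <- function(cfg) {
  rs <- 2^(log2(cfg$start_resolution):log2(cfg$resolution))
  data.frame(level = seq_along(rs), res = as.integer(rs),
             ch = vapply(rs, gan_channels, integer(1), cfg$max_channels))
}

# -- parameter construction ----------------------------------------------------

# one entry per weight; eqlr scale computed from fan-in (1 when eqlr off)
gan_add_param <- function(net, nm, nrow, ncol, fan_in, gain = 2) {
  net$params[[nm]] <- nn_init_w(nrow, ncol, net$cfg$eqlr, fan_in, gain)
  net$scales[[nm]] <- if (net$cfg$eqlr) nn_he_scale(fan_in, gain) else 1
  net$params[[paste0(nm, ".b")]] <- rep(0, ncol)
  net$scales[[paste0(nm, ".b")]] <- 1
  net
}

build_generator <- function(cfg) {
  lv <- gan_levels(cfg)
  net <- list(cfg = cfg, lv = lv, params = list(), scales = list())
  zy <- cfg$z_dim + cfg$n_labels
  s0 <- cfg$start_resolution
  net <- gan_add_param(net, "fc", zy, s0 * s0 * lv$ch[1], fan_in = zy)
  for (l in seq_len(nrow(lv))) {
    cin <- if (l == 1) lv$ch[1] else lv$ch[l - 1]
    ch <- lv$ch[l]
    net <- gan_add_param(net, paste0("g", l, ".c1"), 9 * cin, ch, fan_in = 9 * cin)
    net <- gan_add_param(net, paste0("g", l, ".c2"), 9 * ch, ch, fan_in = 9 * ch)
    net <- gan_add_param(net, paste0("g", l, ".head"), ch, 1, fan_in = ch, gain = 1)
    if (cfg$kind == "cpd") {
      for (k in 1:2) {
        net <- gan_add_param(net, paste0("g", l, ".n", k, ".g"), zy, ch,
                             fan_in = zy, gain = 1)
        net <- gan_add_param(net, paste0("g", l, ".n", k, ".b"), zy, ch,
                             fan_in = zy, gain = 1)
        # gamma bias starts at 1 so conditioning begins near identity
        net$params[[paste0("g", l, ".n", k, ".g.b")]] <- rep(1, ch)
      }
    }
  }
  class(net) <- "gan_generator"
  net
}

build_discriminator <- function(cfg) {
  lv <- gan_levels(cfg)
  net <- list(cfg = cfg, lv = lv, params = list(), scales = list())
  L <- nrow(lv)
  for (l in seq_len(L)) {
    ch <- lv$ch[l]
    # from-image head per level (prog growth needs all; cpd uses the top one)
    net <- gan_add_param(net, paste0("d", l, ".from"), 1, ch, fan_in = 1)
    if (l >= 2) {
      # the first conv of a block raises the channel count (doubling above 32 px)
      cout <- lv$ch[l - 1]
      net <- gan_add_param(net, paste0("d", l, ".c1"), 9 * ch, cout, fan_in = 9 * ch)
      net <- gan_add_param(net, paste0("d", l, ".c2"), 9 * cout, cout, fan_in = 9 * cout)
      if (cfg$kind == "cpd")
        net <- gan_add_param(net, paste0("d", l, ".sk"), ch, cout, fan_in = ch,
                             gain = 1)
    }
  }
  ch1 <- lv$ch[1]
  net <- gan_add_param(net, "d1.c1", 9 * (ch1 + 1), ch1, fan_in = 9 * (ch1 + 1))
  net <- gan_add_param(net, "d.out", ch1, 1, fan_in = ch1, gain = 1)
  if (cfg$kind == "cpd") {
    net <- gan_add_param(net, "d.proj", cfg$n_labels, ch1, fan_in = cfg$n_labels,
                         gain = 1)
  } else {
    net <- gan_add_param(net, "d.aux", ch1, cfg$n_labels, fan_in = ch1, gain = 1)
  }
  class(net) <- "gan_discriminator"
  net
}

pget <- function(net, nm) list(W = net$params[[nm]], b = net$params[[paste0(nm, ".b")]],
                               s = net$scales[[nm]])

# -- generator forward / backward ---------------------------------------------

# level_top: highest active level (prog growth); alpha: transition blend in (0,1]
g_forward <- function(net, z, y, level_top = nrow(net$lv), alpha = 1) {
  cfg <- net$cfg; lv <- net$lv
  n <- nrow(z)
  zy <- cbind(z, y)
  s0 <- cfg$start_resolution
  fc <- pget(net, "fc")
  d1 <- dense_fw(zy, fc$W, fc$b, fc$s)
  a0 <- lrelu_fw(d1$out)
  h <- as_fmap(a0$out, n, s0, s0)
  caches <- list(fc = d1$cache, a0 = a0$cache, zy = zy, n = n)
  img <- NULL
  lvl_caches <- vector("list", level_top)
  for (l in seq_len(level_top)) {
    cl <- list()
    if (l > 1) h <- up2_fw(h)
    for (k in 1:2) {
      cv <- pget(net, paste0("g", l, ".c", k))
      conv <- conv3_fw(h, cv$W, cv$b, cv$s)
      act <- lrelu_fw(conv$out)
      if (cfg$kind == "cpd") {
        pg <- pget(net, paste0("g", l, ".n", k, ".g"))
        pb <- pget(net, paste0("g", l, ".n", k, ".b"))
        gma <- dense_fw(zy, pg$W, pg$b, pg$s)
        bta <- dense_fw(zy, pb$W, pb$b, pb$s)
        nrm <- cpixnorm_fw(act$out, gma$out, bta$out)
      } else {
        nrm <- pixnorm_fw(act$out)
      }
      h <- nrm$out
      cl[[paste0("c", k)]] <- conv$cache
      cl[[paste0("a", k)]] <- act$cache
      cl[[paste0("n", k)]] <- nrm$cache
      if (cfg$kind == "cpd") {
        cl[[paste0("gm", k)]] <- gma$cache
        cl[[paste0("bt", k)]] <- bta$cache
      }
    }
    cl$h_out <- h
    if (cfg$kind == "cpd") {
      hd <- pget(net, paste0("g", l, ".head"))
      o <- conv1_fw(h, hd$W, hd$b, hd$s)
      cl$head <- o$cache
      img <- if (l == 1) o$out else up2_fw(img) + o$out
    } else {
      if (l == level_top) {
        hd <- pget(net, paste0("g", l, ".head"))
        o <- conv1_fw(h, hd$W, hd$b, hd$s)
        cl$head <- o$cache
        img <- o$out
      } else if (l == level_top - 1 && alpha < 1) {
        hd <- pget(net, paste0("g", l, ".head"))
        o <- conv1_fw(h, hd$W, hd$b, hd$s)
        cl$head <- o$cache
        cl$head_out <- o$out
      }
    }
    lvl_caches[[l]] <- cl
  }
  if (cfg$kind == "prog" && alpha < 1 && level_top > 1) {
    img <- alpha * img + (1 - alpha) * up2_fw(lvl_caches[[level_top - 1]]$head_out)
  }
  tn <- NULL
  if (cfg$kind == "cpd") {
    tf <- tanh_fw(img)
    tn <- tf$cache
    img <- tf$out
  }
  list(img = img,
       cache = list(base = caches, levels = lvl_caches, tanh = tn,
                    level_top = level_top, alpha = alpha))
}

g_backward <- function(net, cache, d_img) {
  cfg <- net$cfg
  grads <- list()
  level_top <- cache$level_top
  alpha <- cache$alpha
  zy <- cache$base$zy
  if (cfg$kind == "cpd") d_img <- tanh_bw(d_img, cache$tanh)
  d_prev_head <- NULL
  if (cfg$kind == "prog" && alpha < 1 && level_top > 1) {
    d_prev_head <- up2_bw(d_img) * (1 - alpha)
    d_img <- d_img * alpha
  }
  dh_above <- NULL
  d_zy <- matrix(0, cache$base$n, ncol(zy))
  for (l in rev(seq_len(level_top))) {
    cl <- cache$levels[[l]]
    dh <- if (is.null(dh_above)) NULL else dh_above
    # head contribution
    take_head <- if (cfg$kind == "cpd") TRUE
                 else (l == level_top || (l == level_top - 1 && alpha < 1))
    if (take_head) {
      d_o <- if (cfg$kind == "cpd") d_img
             else if (l == level_top) d_img else d_prev_head
      hd <- pget(net, paste0("g", l, ".head"))
      hb <- conv1_bw(d_o, cl$head, hd$W, hd$s)
      grads[[paste0("g", l, ".head")]] <- hb$dW
      grads[[paste0("g", l, ".head.b")]] <- hb$db
      dh <- if (is.null(dh)) hb$dx else dh + hb$dx
      if (cfg$kind == "cpd" && l > 1) d_img <- up2_bw(d_img)
    }
    # two conv(+norm) stages in reverse
    for (k in 2:1) {
      if (cfg$kind == "cpd") {
        nb <- cpixnorm_bw(dh, cl[[paste0("n", k)]])
        pg <- pget(net, paste0("g", l, ".n", k, ".g"))
        pb <- pget(net, paste0("g", l, ".n", k, ".b"))
        gb <- dense_bw(nb$dgamma, cl[[paste0("gm", k)]], pg$W, pg$s)
        bb <- dense_bw(nb$dbeta, cl[[paste0("bt", k)]], pb$W, pb$s)
        grads[[paste0("g", l, ".n", k, ".g")]] <- gb$dW
        grads[[paste0("g", l, ".n", k, ".g.b")]] <- gb$db
        grads[[paste0("g", l, ".n", k, ".b")]] <- bb$dW
        grads[[paste0("g", l, ".n", k, ".b.b")]] <- bb$db
        d_zy <- d_zy + gb$dx + bb$dx
        dh <- nb$dx
      } else {
        dh <- pixnorm_bw(dh, cl[[paste0("n", k)]])
      }
      dh <- lrelu_bw(dh, cl[[paste0("a", k)]])
      cv <- pget(net, paste0("g", l, ".c", k))
      cb <- conv3_bw(dh, cl[[paste0("c", k)]], cv$W, cv$s)
      grads[[paste0("g", l, ".c", k)]] <- cb$dW
      grads[[paste0("g", l, ".c", k, ".b")]] <- cb$db
      dh <- cb$dx
    }
    if (l > 1) dh_above <- up2_bw(dh) else dh_above <- dh
  }
  d_fc_out <- dh_above
  dim(d_fc_out) <- c(cache$base$n, length(d_fc_out) / cache$base$n)
  d_fc_out <- lrelu_bw(d_fc_out, cache$base$a0)
  fc <- pget(net, "fc")
  fb <- dense_bw(d_fc_out, cache$base$fc, fc$W, fc$s)
  grads$fc <- fb$dW
  grads$fc.b <- fb$db
  # conditioning gradients into [z;y] are not propagated further (z, y inputs)
  grads
}

# -- discriminator forward / backward -----------------------------------------

d_forward <- function(net, img, y, level_top = nrow(net$lv), alpha = 1) {
  cfg <- net$cfg; lv <- net$lv
  n <- dim(img)[1]
  caches <- list(n = n, level_top = level_top, alpha = alpha, y = y)
  fr <- pget(net, paste0("d", level_top, ".from"))
  c_from <- conv1_fw(img, fr$W, fr$b, fr$s)
  a_from <- lrelu_fw(c_from$out)
  h <- a_from$out
  caches$from <- c_from$cache
  caches$a_from <- a_from$cache
  if (cfg$kind == "prog" && alpha < 1 && level_top > 1) {
    ds_img <- avgpool2_fw(img)
    fr2 <- pget(net, paste0("d", level_top - 1, ".from"))
    c_from2 <- conv1_fw(ds_img, fr2$W, fr2$b, fr2$s)
    a_from2 <- lrelu_fw(c_from2$out)
    caches$from2 <- c_from2$cache
    caches$a_from2 <- a_from2$cache
    caches$skip_in <- a_from2$out
  }
  lvl_caches <- vector("list", level_top)
  for (l in rev(seq_len(level_top))) {
    if (l == 1) break
    cl <- list()
    c1 <- pget(net, paste0("d", l, ".c1"))
    cv1 <- conv3_fw(h, c1$W, c1$b, c1$s)
    ac1 <- lrelu_fw(cv1$out)
    c2 <- pget(net, paste0("d", l, ".c2"))
    cv2 <- conv3_fw(ac1$out, c2$W, c2$b, c2$s)
    ac2 <- lrelu_fw(cv2$out)
    hmain <- ac2$out
    if (cfg$kind == "cpd") {
      sk <- pget(net, paste0("d", l, ".sk"))
      skc <- conv1_fw(h, sk$W, sk$b, sk$s)
      hmain <- (hmain + skc$out) / sqrt(2)
      cl$sk <- skc$cache
    }
    h <- avgpool2_fw(hmain)
    cl$c1 <- cv1$cache; cl$a1 <- ac1$cache
    cl$c2 <- cv2$cache; cl$a2 <- ac2$cache
    lvl_caches[[l]] <- cl
    if (cfg$kind == "prog" && alpha < 1 && l == level_top)
      h <- alpha * h + (1 - alpha) * caches$skip_in
  }
  mb <- mbstd_fw(h)
  c1 <- pget(net, "d1.c1")
  cv <- conv3_fw(mb$out, c1$W, c1$b, c1$s)
  ac <- lrelu_fw(cv$out)
  gp <- gpool_fw(ac$out, "sum")
  f <- gp$out
  out <- pget(net, "d.out")
  score <- drop(f %*% (out$W * out$s)) + as.vector(out$b)
  res <- list(score = score, features = f)
  if (cfg$kind == "cpd") {
    pj <- pget(net, "d.proj")
    emb <- y %*% (pj$W * pj$s)
    res$score <- res$score + rowSums(emb * f)
  } else {
    ax <- pget(net, "d.aux")
    res$aux_logits <- sweep(f %*% (ax$W * ax$s), 2, ax$b, "+")
  }
  caches$levels <- lvl_caches
  caches$mb <- mb$cache
  caches$fin_c <- cv$cache; caches$fin_a <- ac$cache; caches$gpool <- gp$cache
  caches$f <- f
  res$cache <- caches
  res
}

# dscore: numeric vector (N); d_aux: optional (N x L) gradient on aux logits
d_backward <- function(net, cache, dscore, d_aux = NULL) {
  cfg <- net$cfg
  grads <- list()
  f <- cache$f
  out <- pget(net, "d.out")
  grads$d.out <- crossprod(f, dscore) * out$s
  grads$d.out.b <- sum(dscore)
  df <- tcrossprod(dscore, out$W[, 1]) * out$s
  if (cfg$kind == "cpd") {
    pj <- pget(net, "d.proj")
    emb <- cache$y %*% (pj$W * pj$s)
    df <- df + emb * dscore
    grads$d.proj <- crossprod(cache$y, f * dscore) * pj$s
    grads$d.proj.b <- rep(0, length(net$params$d.proj.b))
  } else if (!is.null(d_aux)) {
    ax <- pget(net, "d.aux")
    grads$d.aux <- crossprod(f, d_aux) * ax$s
    grads$d.aux.b <- colSums(d_aux)
    df <- df + tcrossprod(d_aux, ax$W * ax$s)
  }
  dh <- gpool_bw(df, cache$gpool)
  dh <- lrelu_bw(dh, cache$fin_a)
  c1 <- pget(net, "d1.c1")
  cb <- conv3_bw(dh, cache$fin_c, c1$W, c1$s)
  grads$d1.c1 <- cb$dW; grads$d1.c1.b <- cb$db
  dh <- mbstd_bw(cb$dx, cache$mb)
  level_top <- cache$level_top; alpha <- cache$alpha
  d_skip_in <- NULL
  for (l in seq_len(level_top)) {
    if (l == 1) next
    cl <- cache$levels[[l]]
    if (cfg$kind == "prog" && alpha < 1 && l == level_top) {
      d_skip_in <- dh * (1 - alpha)
      dh <- dh * alpha
    }
    dh <- avgpool2_bw(dh)
    if (cfg$kind == "cpd") dh <- dh / sqrt(2)
    dmain <- dh
    dmain <- lrelu_bw(dmain, cl$a2)
    c2 <- pget(net, paste0("d", l, ".c2"))
    cb2 <- conv3_bw(dmain, cl$c2, c2$W, c2$s)
    grads[[paste0("d", l, ".c2")]] <- cb2$dW
    grads[[paste0("d", l, ".c2.b")]] <- cb2$db
    din <- lrelu_bw(cb2$dx, cl$a1)
    c1l <- pget(net, paste0("d", l, ".c1"))
    cb1 <- conv3_bw(din, cl$c1, c1l$W, c1l$s)
    grads[[paste0("d", l, ".c1")]] <- cb1$dW
    grads[[paste0("d", l, ".c1.b")]] <- cb1$db
    dh_next <- cb1$dx
    if (cfg$kind == "cpd") {
      sk <- pget(net, paste0("d", l, ".sk"))
      skb <- conv1_bw(dh, cl$sk, sk$W, sk$s)
      grads[[paste0("d", l, ".sk")]] <- skb$dW
      grads[[paste0("d", l, ".sk.b")]] <- skb$db
      dh_next <- dh_next + skb$dx
    }
    dh <- dh_next
  }
  dh <- lrelu_bw(dh, cache$a_from)
  fr <- pget(net, paste0("d", level_top, ".from"))
  frb <- conv1_bw(dh, cache$from, fr$W, fr$s)
  grads[[paste0("d", level_top, ".from")]] <- frb$dW
  grads[[paste0("d", level_top, ".from.b")]] <- frb$db
  dx <- frb$dx
  if (!is.null(d_skip_in)) {
    dsk <- lrelu_bw(d_skip_in, cache$a_from2)
    fr2 <- pget(net, paste0("d", cache$level_top - 1, ".from"))
    frb2 <- conv1_bw(dsk, cache$from2, fr2$W, fr2$s)
    grads[[paste0("d", cache$level_top - 1, ".from")]] <- frb2$dW
    grads[[paste0("d", cache$level_top - 1, ".from.b")]] <- frb2$db
    dx <- dx + avgpool2_bw(frb2$dx)
  }
  list(grads = grads, dx = dx)
}
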