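# Minimal CPU neural-network engine.
#
# Feature maps are arrays with dim (N, H, W, C); the flattened matrix view has
# N*H*W rows (sample index varying fastest) and C columns, so reshaping between
# the two is a dim<- with no copy of element order. Convolutions are 3x3
# same-padding or 1x1, realised as im2col + BLAS matmul. Every primitive has a
# matching backward taking the upstream gradient and the forward cache.
#
# Weights can be stored "equalised": kept at unit variance and rescaled by the
# He constant sqrt(gain / fan_in) at every use, so the effective learning rate
# per layer is normalised at each optimisation step.

as_fmap <- function(m, n, h, w) { dim(m) <- c(n, h, w, dim2 <- length(m) / (n * h * w)); m }
as_fmat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2] * d[3], d[4]); x }

nn_he_scale <- function(fan_in, gain = 2) sqrt(gain / fan_in)

# weight init: unit normal if equalised (scaled at runtime), He-scaled otherwise
nn_init_w <- function(nrow, ncol, eqlr, fan_in, gain = 2) {
  w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (!eqlr) w <- w * nn_he_scale(fan_in, gain)
  w
}

# ---- conv 3x3, stride 1, zero pad 1 -----------------------------------------

pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  xp
}

im2col3 <- function(x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  xp <- pad1(x)
  cols <- matrix(0, n * h * w, 9L * cc)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    sl <- xp[, (1L + di):(h + di), (1L + dj):(w + dj), , drop = FALSE]
    dim(sl) <- c(n * h * w, cc)
    cols[, (k * cc + 1L):((k + 1L) * cc)] <- sl
    k <- k + 1L
  }
  cols
}

col2im3 <- function(dcols, n, h, w, cc) {
  dxp <- array(0, c(n, h + 2L, w + 2L, cc))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    sl <- dcols[, (k * cc + 1L):((k + 1L) * cc), drop = FALSE]
    dim(sl) <- c(n, h, w, cc)
    dxp[, (1L + di):(h + di), (1L + dj):(w + dj), ] <-
      dxp[, (1L + di):(h + di), (1L + dj):(w + dj), , drop = FALSE] + sl
    k <- k + 1L
  }
  dxp[, 2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

conv3_fw <- function(x, W, b, scale = 1) {
  d <- dim(x)
  cols <- im2col3(x)
  out <- cols %*% (W * scale)
  out <- sweep(out, 2, b, "+")
  list(out = as_fmap(out, d[1], d[2], d[3]),
       cache = list(cols = cols, d = d))
}

conv3_bw <- function(dout, cache, W, scale = 1) {
  d <- cache$d
  dm <- as_fmat(dout)
  dW <- crossprod(cache$cols, dm) * scale
  db <- colSums(dm)
  dcols <- tcrossprod(dm, W * scale)
  dx <- col2im3(dcols, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

# ---- conv 1x1 ----------------------------------------------------------------

conv1_fw <- function(x, W, b, scale = 1) {
  d <- dim(x)
  xm <- as_fmat(x)
  out <- xm %*% (W * scale)
  out <- sweep(out, 2, b, "+")
  list(out = as_fmap(out, d[1], d[2], d[3]), cache = list(xm = xm, d = d))
}

conv1_bw <- function(dout, cache, W, scale = 1) {
  d <- cache$d
  dm <- as_fmat(dout)
  dW <- crossprod(cache$xm, dm) * scale
  db <- colSums(dm)
  dx <- as_fmap(tcrossprod(dm, W * scale), d[1], d[2], d[3])
  list(dx = dx, dW = dW, db = db)
}

# ---- dense -------------------------------------------------------------------

dense_fw <- function(x, W, b, scale = 1) {
  out <- sweep(x %*% (W * scale), 2, b, "+")
  list(out = out, cache = list(x = x))
}

dense_bw <- function(dout, cache, W, scale = 1) {
  list(dx = tcrossprod(dout, W * scale),
       dW = crossprod(cache$x, dout) * scale,
       db = colSums(dout))
}

# ---- pointwise activations ---------------------------------------------------

lrelu_fw <- function(x, a = 0.2) {
  out <- x; neg <- x < 0; out[neg] <- a * out[neg]
  list(out = out, cache = neg)
}
lrelu_bw <- function(dout, neg, a = 0.2) { dout[neg] <- a * dout[neg]; dout }

tanh_fw <- function(x) { y <- tanh(x); list(out = y, cache = y) }
tanh_bw <- function(dout, y) dout * (1 - y^2)

sigmoid_fw <- function(x) { y <- 1 / (1 + exp(-x)); list(out = y, cache = y) }
sigmoid_bw <- function(dout, y) dout * y * (1 - y)

# ---- resampling --------------------------------------------------------------

up2_fw <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

up2_bw <- function(dout) {
  d <- dim(dout); h <- d[2] %/% 2L; w <- d[3] %/% 2L
  i1 <- seq(1L, d[2], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3], 2L); j2 <- j1 + 1L
  dout[, i1, j1, , drop = FALSE] + dout[, i2, j1, , drop = FALSE] +
    dout[, i1, j2, , drop = FALSE] + dout[, i2, j2, , drop = FALSE]
}

avgpool2_fw <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3], 2L); j2 <- j1 + 1L
  (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
     x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
}

avgpool2_bw <- function(dout) {
  up2_fw(dout) / 4
}

# downsample an image stack (N,H,W,C) by repeated 2x2 average pooling to `res`
downsample_to <- function(x, res) {
  while (dim(x)[2] > res) x <- avgpool2_fw(x)
  x
}

# ---- global pooling ----------------------------------------------------------

gpool_fw <- function(x, type = c("avg", "sum")) {
  type <- match.arg(type)
  d <- dim(x)
  grp <- rep(seq_len(d[1]), d[2] * d[3])
  s <- rowsum(as_fmat(x), grp, reorder = TRUE)
  if (type == "avg") s <- s / (d[2] * d[3])
  list(out = s, cache = list(d = d, type = type))
}

gpool_bw <- function(dout, cache) {
  d <- cache$d
  scale <- if (cache$type == "avg") 1 / (d[2] * d[3]) else 1
  dm <- dout[rep(seq_len(d[1]), d[2] * d[3]), , drop = FALSE] * scale
  as_fmap(dm, d[1], d[2], d[3])
}

# ---- pixel-wise feature vector normalisation --------------------------------

#' Pixel-wise feature vector normalisation
#'
#' Normalises the feature vector of every pixel to unit root-mean-square over
#' channels: \eqn{b_i = a_i / \sqrt{1/N \sum_j a_j^2 + \epsilon}}. This is the
#' unconditional normalisation used throughout the progressive-growing
#' generator.
#'
#' @param x Feature map array with dim (batch, height, width, channels).
#' @param eps Numerical stabiliser (default 1e-8).
#' @return Array of the same shape.
#' @export
pixel_norm <- function(x, eps = 1e-8) {
  pixnorm_fw(x, eps)$out
}

pixnorm_fw <- function(x, eps = 1e-8) {
  d <- dim(x)
  xm <- as_fmat(x)
  inv <- 1 / sqrt(rowMeans(xm^2) + eps)
  out <- xm * inv
  list(out = as_fmap(out, d[1], d[2], d[3]),
       cache = list(xm = xm, inv = inv, d = d))
}

pixnorm_bw <- function(dout, cache) {
  d <- cache$d; cc <- d[4]
  dm <- as_fmat(dout)
  s <- rowSums(dm * cache$xm)
  dx <- dm * cache$inv - cache$xm * (s * cache$inv^3 / cc)
  as_fmap(dx, d[1], d[2], d[3])
}

# conditional pixel norm: gamma/beta are (N x C) per-sample per-channel
cpixnorm_fw <- function(x, gamma, beta, eps = 1e-8) {
  pn <- pixnorm_fw(x, eps)
  d <- dim(x)
  sidx <- rep(seq_len(d[1]), d[2] * d[3])
  pm <- as_fmat(pn$out)
  out <- pm * gamma[sidx, , drop = FALSE] + beta[sidx, , drop = FALSE]
  list(out = as_fmap(out, d[1], d[2], d[3]),
       cache = list(pn = pn, pm = pm, sidx = sidx, gamma = gamma, d = d))
}

cpixnorm_bw <- function(dout, cache) {
  dm <- as_fmat(dout)
  dgamma <- rowsum(dm * cache$pm, cache$sidx, reorder = TRUE)
  dbeta <- rowsum(dm, cache$sidx, reorder = TRUE)
  dp <- dm * cache$gamma[cache$sidx, , drop = FALSE]
  d <- cache$d
  dx <- pixnorm_bw(as_fmap(dp, d[1], d[2], d[3]), cache$pn$cache)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- minibatch standard deviation channel -----------------------------------

mbstd_fw <- function(x, eps = 1e-8) {
  d <- dim(x); n <- d[1]
  xm <- matrix(x, n, d[2] * d[3] * d[4])        # (N, HWC)
  mu <- colMeans(xm)
  dev <- sweep(xm, 2, mu)
  v <- colMeans(dev^2)
  s <- sqrt(v + eps)
  stat <- mean(s)                               # one scalar for the batch
  out <- array(0, c(n, d[2], d[3], d[4] + 1L))
  out[, , , seq_len(d[4])] <- x
  out[, , , d[4] + 1L] <- stat
  list(out = out, cache = list(d = d, dev = dev, s = s))
}

mbstd_bw <- function(dout, cache) {
  d <- cache$d; n <- d[1]
  dx <- dout[, , , seq_len(d[4]), drop = FALSE]
  dstat <- sum(dout[, , , d[4] + 1L])
  k <- length(cache$s)                          # = HWC
  ds <- dstat / k
  dv <- ds / (2 * cache$s)
  dfromstat <- sweep(cache$dev, 2, dv * 2 / n, "*")
  dx + array(dfromstat, d)
}

# ---- Adam optimiser ----------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
  list(opt = opt, params = params)
}

# accumulate gradient lists (named); b entries added into a
grad_acc <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]] else a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}
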