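# Frechet-distance image quality metric, the fixed-N cycling sampling
# protocol, and the convergence-based training stop controller.
#
# Image sets are summarised as multivariate Gaussians (m, C) of feature
# embeddings and compared with the squared Frechet distance
#   d^2 = ||m - m_w||^2 + Tr(C + C_w - 2 (C C_w)^{1/2}).
# At desk scale the embedder is a small fixed-seed convolutional encoder
# rather than Inception-v3: FID values are therefore only comparable within
# one embedder, which is all the convergence controller needs.

#' Gaussian summary (mean and covariance) of a feature set
#'
#' @param features Numeric matrix, one feature vector per row (>= 2 rows).
#' @return Object of class `gaussian_summary` with fields `m` (mean vector),
#'   `C` (sample covariance, divisor n - 1) and `n`.
#' @export
summarize_features <- function(features) {
  features <- as.matrix(features)
  check_that(nrow(features) >= 2, "need at least 2 feature vectors")
  m <- colMeans(features)
  C <- stats::cov(features)              # divisor n - 1 (unbiased)
  structure(list(m = m, C = C, n = nrow(features)), class = "gaussian_summary")
}

# symmetric PSD square root via eigendecomposition, eigenvalues clipped at 0
sym_sqrtm <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  check_that(min(lam) > -tol * max(abs(lam), 1),
             "matrix is not positive semi-definite beyond tolerance")
  lam <- pmax(lam, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Squared Frechet distance between two Gaussian summaries
#'
#' Computes \eqn{d^2 = ||m - m_w||^2 + Tr(C + C_w - 2 (C C_w)^{1/2})}. The
#' matrix square root is taken as the symmetric PSD root of
#' \eqn{C^{1/2} C_w C^{1/2}} (equal in trace to \eqn{(C C_w)^{1/2}}), with
#' negative eigenvalues clipped at zero, and the result floored at 0.
#'
#' @param A,B `gaussian_summary` objects of matching dimension.
#' @param tol Relative tolerance for the PSD check.
#' @return Non-negative scalar d^2; symmetric in its arguments.
#' @export
frechet_distance <- function(A, B, tol = 1e-6) {
  check_that(inherits(A, "gaussian_summary") && inherits(B, "gaussian_summary"),
             "arguments must be gaussian_summary objects")
  check_that(length(A$m) == length(B$m), "summary dimensions differ")
  sA <- sym_sqrtm(A$C, tol)
  M <- sA %*% B$C %*% sA
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  check_that(min(e) > -tol * max(abs(e), 1),
             "product matrix is not PSD beyond tolerance")
  tr_sqrt <- sum(sqrt(pmax(e, 0)))
  d2 <- sum((A$m - B$m)^2) + sum(diag(A$C)) + sum(diag(B$C)) - 2 * tr_sqrt
  max(d2, 0)
}

# ---- embedding model ---------------------------------------------------------

#' Fixed-seed convolutional feature embedder for FID
#'
#' A small deterministic random-weight convolutional encoder mapping images in
#' [-1,1] to feature vectors. Random convolutional features are a standard
#' stand-in for a pretrained Inception network at toy scale: the extractor is
#' fixed, seeded, and identical across the real/synthetic evaluation, which is
#' what the convergence controller requires.
#'
#' @param resolution Input image side length (power of two >= 8).
#' @param dim Feature dimension (default 32).
#' @param channels Internal channel count (default 16).
#' @param seed Seed fixing the random weights (default 7).
#' @return Object of class `fid_embedder`; call [embed_images()] to use it.
#' @export
fid_embedder <- function(resolution, dim = 32L, channels = 16L, seed = 7L) {
  check_that(is_power_of_two(resolution) && resolution >= 8,
             "resolution must be a power of two >= 8")
  n_pool <- as.integer(log2(resolution / 4))   # pool down to 4x4
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(n_pool)) {
      p[[paste0("W", l)]] <- nn_init_w(9L * cin, channels, eqlr = FALSE,
                                       fan_in = 9L * cin)
      p[[paste0("b", l)]] <- stats::rnorm(channels, 0, 0.1)
      cin <- channels
    }
    p$Wout <- nn_init_w(16L * channels, dim, eqlr = FALSE,
                        fan_in = 16L * channels)
    p$bout <- rep(0, dim)
    p
  })
  structure(list(params = params, resolution = as.integer(resolution),
                 dim = as.integer(dim), channels = as.integer(channels),
                 n_pool = n_pool, seed = as.integer(seed)),
            class = "fid_embedder")
}

#' Embed an image stack into FID feature space
#'
#' @param embedder A [fid_embedder()].
#' @param images Array (n, res, res) in [0,1] or (n, res, res, 1) in [-1,1].
#' @return Matrix (n, dim) of deterministic features.
#' @export
embed_images <- function(embedder, images) {
  x <- as_model_input(images, embedder$resolution)
  p <- embedder$params
  for (l in seq_len(embedder$n_pool)) {
    x <- conv3_fw(x, p[[paste0("W", l)]], p[[paste0("b", l)]])$out
    x <- lrelu_fw(x)$out
    x <- avgpool2_fw(x)
  }
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3] * d[4])
  sweep(xm %*% p$Wout, 2, p$bout, "+")
}

# images stored in [0,1] as (n,h,w) are mapped affinely to [-1,1] NHWC;
# already-4D input is assumed to be in model space
as_model_input <- function(images, resolution = NULL) {
  d <- dim(images)
  if (length(d) == 3) {
    x <- array(images * 2 - 1, c(d, 1L))
  } else x <- images
  if (!is.null(resolution) && dim(x)[2] != resolution) {
    check_that(dim(x)[2] >= resolution, "image smaller than required input")
    x <- downsample_to(x, resolution)
  }
  x
}

# ---- sampling protocol -------------------------------------------------------

#' Evaluation protocol for FID-based training control
#'
#' @param N Evaluation sample size (default 10,000).
#' @param eval_cadence Real images between FID evaluations (default 400,000).
#' @param patience Consecutive non-improving evaluations before stopping
#'   (default 2).
#' @param min_images Minimum real-image budget before evaluations start.
#' @return Object of class `fid_protocol`.
#' @export
fid_protocol <- function(N = 10000L, eval_cadence = 400000L, patience = 2L,
                         min_images = 7e6) {
  check_that(N > 0 && eval_cadence > 0 && patience > 0 && min_images > 0,
             "all protocol fields must be positive")
  structure(list(N = as.integer(N), eval_cadence = eval_cadence,
                 patience = as.integer(patience), min_images = min_images),
            class = "fid_protocol")
}

#' Assemble the fixed-N real/synthetic FID sample
#'
#' The real side cycles through the fold: full passes plus one seeded partial
#' pass, so per-image usage counts differ by at most one. The synthetic side
#' draws N fresh images conditioned on the (possibly repeated) real labels
#' with fresh noise.
#'
#' @param real_fold A `dataset_store` (typically the train fold).
#' @param N Sample size (default 10,000).
#' @param seed Integer seed.
#' @param sampler Optional conditional sampler `(labels, seed) -> images`;
#'   when NULL only the real indices/labels are returned.
#' @return List with `real_idx` (length N), `labels` (N x L), `real` and
#'   (when a sampler is given) `synthetic` image arrays.
#' @export
assemble_fid_sample <- function(real_fold, N = 10000L, seed = 1L,
                                sampler = NULL) {
  n <- store_size(real_fold)
  check_that(n > 0, "real fold is empty")
  full <- N %/% n
  rest <- N - full * n
  idx <- rep(seq_len(n), full)
  if (rest > 0) idx <- c(idx, with_seed(seed, sample(n, rest)))
  labels <- real_fold$labels[idx, , drop = FALSE]
  out <- list(real_idx = idx, labels = labels,
              real = real_fold$images[idx, , , drop = FALSE])
  if (!is.null(sampler))
    out$synthetic <- sampler(labels, fanout_seed(seed, 1L))
  out
}

#' Compute the FID between a real fold and a conditional sampler
#'
#' @param embedder A [fid_embedder()].
#' @param real_fold A `dataset_store`.
#' @param sampler Conditional sampler `(labels, seed) -> images` in [0,1].
#' @param N Evaluation sample size.
#' @param seed Integer seed.
#' @return Scalar FID (squared Frechet distance in embedder feature space).
#' @export
compute_fid <- function(embedder, real_fold, sampler, N = 10000L, seed = 1L) {
  s <- assemble_fid_sample(real_fold, N = N, seed = seed, sampler = sampler)
  fr <- embed_images(embedder, s$real)
  fs <- embed_images(embedder, s$synthetic)
  frechet_distance(summarize_features(fs), summarize_features(fr))
}

# ---- convergence controller --------------------------------------------------

#' Two-strike FID convergence check
#'
#' Training stops exactly when the last `patience` evaluations each failed to
#' improve on the running best FID. Evaluations taken before the minimum
#' image budget do not count.
#'
#' @param trace Data frame with columns `real_images_seen` and `fid` in
#'   evaluation order.
#' @param protocol A [fid_protocol()].
#' @return `"stop"` or `"continue"`.
#' @export
convergence_check <- function(trace, protocol) {
  eligible <- trace[trace$real_images_seen >= protocol$min_images, , drop = FALSE]
  k <- nrow(eligible)
  if (k < protocol$patience + 1L) return("continue")
  fid <- eligible$fid
  strikes <- 0L
  best <- fid[1]
  for (i in 2:k) {
    if (fid[i] < best) {
      best <- fid[i]
      strikes <- 0L
    } else {
      strikes <- strikes + 1L
    }
  }
  if (strikes >= protocol$patience) "stop" else "continue"
}
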