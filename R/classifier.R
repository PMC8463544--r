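# Downstream predictive model: multi-label CNN classifier with sigmoid
# outputs and per-label binary cross-entropy, the epoch/LR/early-stop
# protocol, per-label AUROC evaluation, and penultimate-feature extraction
# for the privacy audit.

#' Classifier configuration
#'
#' Defaults follow the published training protocol: at most 5000 images per
#' epoch, batch size 48, initial learning rate 1e-4 reduced by a factor of 10
#' after 2 consecutive epochs without validation improvement, and early stop
#' after 3.
#'
#' @param architecture `"small_cnn"` (seeded desk-scale CNN, default) or
#'   `"densenet121_style"` (dense blocks (6,12,24,16), growth 32, 1024-dim
#'   final features; no external weights).
#' @param input_size Model input side length (default 224; images are resized
#'   by power-of-two average pooling / nearest-neighbour upsampling).
#' @param batch_size Minibatch size (default 48).
#' @param images_per_epoch Cap on images per epoch (default 5000).
#' @param lr Initial learning rate (default 1e-4).
#' @param lr_factor LR reduction factor (default 10).
#' @param lr_patience Consecutive non-improving epochs before LR reduction
#'   (default 2).
#' @param stop_patience Consecutive non-improving epochs before stopping
#'   (default 3; must exceed `lr_patience`).
#' @param max_epochs Safety cap on epochs (default 50).
#' @param channels Channel widths of the small CNN (default 8, 16, 32; the
#'   last is the penultimate feature dimension).
#' @param seed Integer seed for initialisation and batch order.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("small_cnn", "densenet121_style"),
                              input_size = 224L, batch_size = 48L,
                              images_per_epoch = 5000L, lr = 1e-4,
                              lr_factor = 10, lr_patience = 2L,
                              stop_patience = 3L, max_epochs = 50L,
                              channels = c(8L, 16L, 32L), seed = 1L) {
  architecture <- match.arg(architecture)
  check_that(stop_patience > lr_patience,
             "stop_patience must exceed lr_patience")
  check_that(batch_size > 0 && images_per_epoch > 0 && max_epochs > 0,
             "all counts must be positive")
  structure(list(architecture = architecture, input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 images_per_epoch = as.integer(images_per_epoch), lr = lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 max_epochs = as.integer(max_epochs),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "classifier_config")
}

# resize an (n,h,w,1) stack to `size` by power-of-two pooling / upsampling
resize_input <- function(x, size) {
  r <- dim(x)[2]
  if (r == size) return(x)
  ratio <- if (r > size) r / size else size / r
  check_that(is_power_of_two(ratio), "resize ratio must be a power of two")
  if (r > size) downsample_to(x, size)
  else {
    while (dim(x)[2] < size) x <- up2_fw(x)
    x
  }
}

# ---- model construction ------------------------------------------------------

build_classifier <- function(config, n_labels) {
  if (config$architecture == "small_cnn") build_small_cnn(config, n_labels)
  else build_densenet_style(config, n_labels)
}

build_small_cnn <- function(config, n_labels) {
  ch <- config$channels
  params <- list()
  cin <- 1L
  for (l in seq_along(ch)) {
    params[[paste0("c", l)]] <- nn_init_w(9 * cin, ch[l], eqlr = FALSE,
                                          fan_in = 9 * cin)
    params[[paste0("c", l, ".b")]] <- rep(0, ch[l])
    cin <- ch[l]
  }
  fdim <- ch[length(ch)]
  params$head <- nn_init_w(fdim, n_labels, eqlr = FALSE, fan_in = fdim, gain = 1)
  params$head.b <- rep(0, n_labels)
  structure(list(architecture = "small_cnn", params = params,
                 n_blocks = length(ch), feature_dim = fdim,
                 n_labels = n_labels, input_size = config$input_size),
            class = "synthrad_classifier")
}

# dense connectivity: blocks of (1x1 bottleneck -> 3x3 growth) layers whose
# outputs are concatenated channel-wise; 1x1 + avgpool transitions between
build_densenet_style <- function(config, n_labels,
                                 blocks = c(6L, 12L, 24L, 16L),
                                 growth = 32L, init_ch = 64L) {
  params <- list()
  params$stem <- nn_init_w(9, init_ch, eqlr = FALSE, fan_in = 9)
  params$stem.b <- rep(0, init_ch)
  cc <- init_ch
  for (bi in seq_along(blocks)) {
    for (li in seq_len(blocks[bi])) {
      nm <- paste0("b", bi, ".l", li)
      params[[paste0(nm, ".c1")]] <- nn_init_w(cc, 4 * growth, eqlr = FALSE,
                                               fan_in = cc)
      params[[paste0(nm, ".c1.b")]] <- rep(0, 4 * growth)
      params[[paste0(nm, ".c2")]] <- nn_init_w(9 * 4 * growth, growth,
                                               eqlr = FALSE,
                                               fan_in = 9 * 4 * growth)
      params[[paste0(nm, ".c2.b")]] <- rep(0, growth)
      cc <- cc + growth
    }
    if (bi < length(blocks)) {
      params[[paste0("t", bi)]] <- nn_init_w(cc, cc %/% 2L, eqlr = FALSE,
                                             fan_in = cc, gain = 1)
      params[[paste0("t", bi, ".b")]] <- rep(0, cc %/% 2L)
      cc <- cc %/% 2L
    }
  }
  params$head <- nn_init_w(cc, n_labels, eqlr = FALSE, fan_in = cc, gain = 1)
  params$head.b <- rep(0, n_labels)
  structure(list(architecture = "densenet121_style", params = params,
                 blocks = blocks, growth = growth, init_ch = init_ch,
                 feature_dim = cc, n_labels = n_labels,
                 input_size = config$input_size),
            class = "synthrad_classifier")
}

#' @export
print.synthrad_classifier <- function(x, ...) {
  cat(sprintf("synthrad_classifier: %s, input %d px, %d labels, %d-dim penultimate features\n",
              x$architecture, x$input_size, x$n_labels, x$feature_dim))
  invisible(x)
}

# ---- forward / backward ------------------------------------------------------

clf_forward <- function(model, x, keep_cache = FALSE) {
  if (model$architecture == "small_cnn") small_cnn_fw(model, x, keep_cache)
  else densenet_fw(model, x, keep_cache)
}

small_cnn_fw <- function(model, x, keep_cache) {
  p <- model$params
  caches <- list()
  h <- x
  for (l in seq_len(model$n_blocks)) {
    cv <- conv3_fw(h, p[[paste0("c", l)]], p[[paste0("c", l, ".b")]])
    ac <- lrelu_fw(cv$out)
    h <- ac$out
    if (l < model$n_blocks) h <- avgpool2_fw(h)
    if (keep_cache) caches[[l]] <- list(c = cv$cache, a = ac$cache)
  }
  gp <- gpool_fw(h, "avg")
  hd <- dense_fw(gp$out, p$head, p$head.b)
  sg <- sigmoid_fw(hd$out)
  list(logits = hd$out, probs = sg$out, features = gp$out,
       cache = if (keep_cache) list(blocks = caches, gpool = gp$cache,
                                    head = hd$cache, sig = sg$cache))
}

small_cnn_bw <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list()
  hb <- dense_bw(dlogits, cache$head, p$head)
  grads$head <- hb$dW; grads$head.b <- hb$db
  dh <- gpool_bw(hb$dx, cache$gpool)
  for (l in rev(seq_len(model$n_blocks))) {
    if (l < model$n_blocks) dh <- avgpool2_bw(dh)
    dh <- lrelu_bw(dh, cache$blocks[[l]]$a)
    cb <- conv3_bw(dh, cache$blocks[[l]]$c, p[[paste0("c", l)]])
    grads[[paste0("c", l)]] <- cb$dW
    grads[[paste0("c", l, ".b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

densenet_fw <- function(model, x, keep_cache) {
  p <- model$params
  caches <- list()
  st <- conv3_fw(x, p$stem, p$stem.b)
  sa <- lrelu_fw(st$out)
  h <- avgpool2_fw(avgpool2_fw(sa$out))
  if (keep_cache) caches$stem <- list(c = st$cache, a = sa$cache,
                                      hdim = dim(sa$out))
  for (bi in seq_along(model$blocks)) {
    bc <- list()
    for (li in seq_len(model$blocks[bi])) {
      nm <- paste0("b", bi, ".l", li)
      c1 <- conv1_fw(h, p[[paste0(nm, ".c1")]], p[[paste0(nm, ".c1.b")]])
      a1 <- lrelu_fw(c1$out)
      c2 <- conv3_fw(a1$out, p[[paste0(nm, ".c2")]], p[[paste0(nm, ".c2.b")]])
      a2 <- lrelu_fw(c2$out)
      d <- dim(h)
      hn <- array(0, c(d[1], d[2], d[3], d[4] + model$growth))
      hn[, , , seq_len(d[4])] <- h
      hn[, , , d[4] + seq_len(model$growth)] <- a2$out
      if (keep_cache) bc[[li]] <- list(c1 = c1$cache, a1 = a1$cache,
                                       c2 = c2$cache, a2 = a2$cache,
                                       cin = d[4])
      h <- hn
    }
    if (bi < length(model$blocks)) {
      tn <- paste0("t", bi)
      tc <- conv1_fw(h, p[[tn]], p[[paste0(tn, ".b")]])
      ta <- lrelu_fw(tc$out)
      h <- avgpool2_fw(ta$out)
      if (keep_cache) bc$trans <- list(c = tc$cache, a = ta$cache)
    }
    if (keep_cache) caches[[paste0("b", bi)]] <- bc
  }
  gp <- gpool_fw(h, "avg")
  hd <- dense_fw(gp$out, p$head, p$head.b)
  sg <- sigmoid_fw(hd$out)
  list(logits = hd$out, probs = sg$out, features = gp$out,
       cache = if (keep_cache) list(dense = caches, gpool = gp$cache,
                                    head = hd$cache, sig = sg$cache))
}

densenet_bw <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list()
  hb <- dense_bw(dlogits, cache$head, p$head)
  grads$head <- hb$dW; grads$head.b <- hb$db
  dh <- gpool_bw(hb$dx, cache$gpool)
  for (bi in rev(seq_along(model$blocks))) {
    bc <- cache$dense[[paste0("b", bi)]]
    if (bi < length(model$blocks)) {
      dh <- avgpool2_bw(dh)
      dh <- lrelu_bw(dh, bc$trans$a)
      tn <- paste0("t", bi)
      tb <- conv1_bw(dh, bc$trans$c, p[[tn]])
      grads[[tn]] <- tb$dW; grads[[paste0(tn, ".b")]] <- tb$db
      dh <- tb$dx
    }
    for (li in rev(seq_len(model$blocks[bi]))) {
      lc <- bc[[li]]
      nm <- paste0("b", bi, ".l", li)
      cin <- lc$cin
      d_prev <- dh[, , , seq_len(cin), drop = FALSE]
      d_new <- dh[, , , cin + seq_len(model$growth), drop = FALSE]
      d_new <- lrelu_bw(d_new, lc$a2)
      c2b <- conv3_bw(d_new, lc$c2, p[[paste0(nm, ".c2")]])
      grads[[paste0(nm, ".c2")]] <- c2b$dW
      grads[[paste0(nm, ".c2.b")]] <- c2b$db
      da1 <- lrelu_bw(c2b$dx, lc$a1)
      c1b <- conv1_bw(da1, lc$c1, p[[paste0(nm, ".c1")]])
      grads[[paste0(nm, ".c1")]] <- c1b$dW
      grads[[paste0(nm, ".c1.b")]] <- c1b$db
      dh <- d_prev + c1b$dx
    }
  }
  dh <- up2_fw(up2_fw(dh)) / 16   # backward of the two stem average pools
  dh <- lrelu_bw(dh, cache$stem$a)
  sb <- conv3_bw(dh, cache$stem$c, p$stem)
  grads$stem <- sb$dW; grads$stem.b <- sb$db
  grads
}

clf_backward <- function(model, cache, dlogits) {
  if (model$architecture == "small_cnn") small_cnn_bw(model, cache, dlogits)
  else densenet_bw(model, cache, dlogits)
}

# ---- prediction / evaluation -------------------------------------------------

#' Predict label probabilities for a dataset store or image stack
#'
#' @param model A trained `synthrad_classifier`.
#' @param data A `dataset_store` or an image array (n, res, res) in [0,1].
#' @param chunk Images per forward chunk (memory bound).
#' @return Matrix (n x n_labels) of sigmoid probabilities.
#' @export
predict_proba <- function(model, data, chunk = 256L) {
  imgs <- if (inherits(data, "dataset_store")) data$images else data
  n <- dim(imgs)[1]
  out <- matrix(0, n, model$n_labels)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    x <- resize_input(as_model_input(imgs[i:j, , , drop = FALSE]),
                      model$input_size)
    out[i:j, ] <- clf_forward(model, x)$probs
    i <- j + 1L
  }
  out
}

#' Per-label AUROC with tie handling
#'
#' Rank-statistic AUROC: tied scores contribute 1/2 per positive-negative
#' pair. Returns NA for degenerate label vectors (all 0 or all 1).
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector.
#' @return AUROC in [0,1], or NA if degenerate.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean AUROC of a classifier on a fold
#'
#' Computes per-label AUROC on the fold and their mean over non-degenerate
#' labels; degenerate labels (all-positive or all-negative in the fold) are
#' excluded from the mean and reported.
#'
#' @param model A trained `synthrad_classifier`.
#' @param fold A `dataset_store` with ground-truth labels.
#' @return Object of class `auc_report` with `per_label`, `mean_auc` and
#'   `excluded`.
#' @export
evaluate_mean_auc <- function(model, fold) {
  probs <- predict_proba(model, fold)
  per_label <- vapply(seq_len(ncol(fold$labels)),
                      function(j) auroc(probs[, j], fold$labels[, j]),
                      numeric(1))
  names(per_label) <- fold$label_names
  ok <- !is.na(per_label)
  check_that(any(ok), "all labels are degenerate in this fold")
  structure(list(per_label = per_label, mean_auc = mean(per_label[ok]),
                 excluded = fold$label_names[!ok]),
            class = "auc_report")
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("auc_report: mean AUC %.4f over %d labels",
              x$mean_auc, sum(!is.na(x$per_label))))
  if (length(x$excluded))
    cat(sprintf(" (%d degenerate excluded: %s)", length(x$excluded),
                paste(x$excluded, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Extract penultimate-layer features
#'
#' Deterministic per (model, image): the global-average-pooled representation
#' feeding the sigmoid head (1024-dimensional for the densenet-style
#' architecture).
#'
#' @param model A trained `synthrad_classifier`.
#' @param images Image array (n, res, res) in [0,1] or a `dataset_store`.
#' @param chunk Images per forward chunk.
#' @return Feature matrix (n x feature_dim).
#' @export
penultimate_features <- function(model, images, chunk = 256L) {
  imgs <- if (inherits(images, "dataset_store")) images$images else images
  n <- dim(imgs)[1]
  out <- matrix(0, n, model$feature_dim)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    x <- resize_input(as_model_input(imgs[i:j, , , drop = FALSE]),
                      model$input_size)
    out[i:j, ] <- clf_forward(model, x)$features
    i <- j + 1L
  }
  out
}

# ---- training ----------------------------------------------------------------

#' Train a multi-label classifier with the benchmark protocol
#'
#' Per-label binary cross-entropy with sigmoid outputs, Adam; an epoch is
#' `min(|train|, images_per_epoch)` images; after every epoch the mean
#' validation AUROC is computed; the learning rate is divided by `lr_factor`
#' after `lr_patience` consecutive non-improvements and training stops after
#' `stop_patience`; the best-validation weights are retained.
#'
#' @param train_fold,val_fold Non-empty `dataset_store` folds.
#' @param config A [classifier_config()].
#' @return List: `model` (best weights), `log` (per-epoch data frame with
#'   `epoch`, `lr`, `val_mean_auc`), `best_val_auc`, `epochs_run`.
#' @export
train_classifier <- function(train_fold, val_fold, config = classifier_config()) {
  check_that(store_size(train_fold) > 0 && store_size(val_fold) > 0,
             "folds must be non-empty")
  n_labels <- ncol(train_fold$labels)
  deg <- vapply(seq_len(n_labels), function(j) {
    v <- val_fold$labels[, j]; all(v == 0) || all(v == 1)
  }, logical(1))
  check_that(!all(deg), "every label is single-class in the validation fold")
  model <- with_seed(fanout_seed(config$seed, 1L),
                     build_classifier(config, n_labels))
  opt <- adam_new(model$params, lr = config$lr, beta1 = 0.9, beta2 = 0.999)
  n <- store_size(train_fold)
  epoch_images <- min(n, config$images_per_epoch)
  lr <- config$lr
  best <- -Inf; best_params <- model$params
  bad_lr <- 0L; bad_stop <- 0L
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    val_mean_auc = numeric(0))
  x_all <- resize_input(as_model_input(train_fold$images), config$input_size)
  with_seed(fanout_seed(config$seed, 2L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n, epoch_images, replace = epoch_images > n)
      i <- 1L
      while (i <= epoch_images) {
        j <- min(epoch_images, i + config$batch_size - 1L)
        idx <- ord[i:j]
        x <- x_all[idx, , , , drop = FALSE]
        yb <- train_fold$labels[idx, , drop = FALSE]
        fw <- clf_forward(model, x, keep_cache = TRUE)
        dlogits <- (fw$probs - yb) / length(yb)   # BCE-with-sigmoid gradient
        grads <- clf_backward(model, fw$cache, dlogits)
        opt$lr <- lr
        upd <- adam_step(opt, model$params, grads)
        opt <- upd$opt; model$params <- upd$params
        i <- j + 1L
      }
      val_auc <- evaluate_mean_auc(model, val_fold)$mean_auc
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   val_mean_auc = val_auc))
      if (val_auc > best) {
        best <- val_auc
        best_params <- model$params
        bad_lr <- 0L; bad_stop <- 0L
      } else {
        bad_lr <- bad_lr + 1L
        bad_stop <- bad_stop + 1L
        if (bad_stop >= config$stop_patience) break
        if (bad_lr >= config$lr_patience) {
          lr <- lr / config$lr_factor
          bad_lr <- 0L
        }
      }
    }
  })
  model$params <- best_params
  list(model = model, log = log, best_val_auc = best, epochs_run = nrow(log))
}
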