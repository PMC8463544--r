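# Benchmark orchestration: GAN training (or an injected generator),
# label-equivalent fold synthesis, paired real/synthetic classifier training,
# the utility gap AUC_real - AUC_syn, the label-overfitting diagnostic
# Delta_syn, and the one-sided Mann-Whitney U extrema test.

#' Run one benchmark setting end to end
#'
#' Per seed: the conditional GAN is trained to FID convergence on the real
#' train fold (unless a `generator_factory` is injected), synthetic folds
#' label-equivalent to the real folds are pre-computed (never resampled per
#' batch), one classifier is trained on the real train fold and one on the
#' synthetic train fold, and both are evaluated on the real test fold.
#'
#' @param store A split real `dataset_store`.
#' @param setting A [benchmark_setting()] buildable from the store.
#' @param gan_cfg A [gan_config()] (ignored when `generator_factory` given).
#' @param clf_cfg A [classifier_config()].
#' @param protocol A [fid_protocol()].
#' @param seeds Integer vector of master seeds (the protocol repeats every
#'   experiment with at least four random initialisations; default 1:4).
#' @param generator_factory Optional function `(real_store, seed)` returning a
#'   conditional sampler `(labels, seed) -> images in [0,1]` — used to inject
#'   oracle or adversarial generators instead of GAN training.
#' @return Object of class `benchmark_result`: per-seed `auc_real`,
#'   `auc_syn`, `delta_auc = auc_real - auc_syn`, `delta_syn`, and FID traces
#'   (NULL for injected generators). Failed seeds are recorded with an error
#'   message and flagged via `partial`.
#' @export
run_benchmark_setting <- function(store, setting, gan_cfg = NULL,
                                  clf_cfg = classifier_config(),
                                  protocol = fid_protocol(),
                                  seeds = 1:4, generator_factory = NULL) {
  check_that(length(seeds) >= 1, "need at least one seed")
  rows <- list()
  traces <- list()
  for (seed in seeds) {
    res <- tryCatch({
      bstore <- build_benchmark_setting(store, setting,
                                        seed = fanout_seed(seed, 11L))
      if (is.null(generator_factory)) {
        check_that(!is.null(gan_cfg), "need a gan_config or a generator_factory")
        gan <- train_gan(store_fold(bstore, "train"), gan_cfg, protocol,
                         seed = fanout_seed(seed, 12L))
        sampler <- as_conditional_sampler(gan)
        trace <- gan$state$fid_trace
      } else {
        sampler <- generator_factory(bstore, seed)
        trace <- NULL
      }
      syn <- make_equivalent_synthetic_folds(sampler, bstore,
                                             seed = fanout_seed(seed, 13L))
      cfg_r <- clf_cfg; cfg_r$seed <- fanout_seed(seed, 14L)
      cfg_s <- clf_cfg; cfg_s$seed <- fanout_seed(seed, 15L)
      fit_r <- train_classifier(store_fold(bstore, "train"),
                                store_fold(bstore, "val"), cfg_r)
      fit_s <- train_classifier(store_fold(syn, "train"),
                                store_fold(syn, "val"), cfg_s)
      auc_real <- evaluate_mean_auc(fit_r$model, store_fold(bstore, "test"))$mean_auc
      auc_syn <- evaluate_mean_auc(fit_s$model, store_fold(bstore, "test"))$mean_auc
      dsyn <- delta_syn(fit_s$model, store_fold(syn, "test"),
                        store_fold(bstore, "test"))
      list(row = data.frame(seed = seed, auc_real = auc_real,
                            auc_syn = auc_syn,
                            delta_auc = auc_real - auc_syn,
                            delta_syn = dsyn, error = NA_character_),
           trace = trace)
    }, error = function(e) {
      list(row = data.frame(seed = seed, auc_real = NA_real_,
                            auc_syn = NA_real_, delta_auc = NA_real_,
                            delta_syn = NA_real_,
                            error = conditionMessage(e)),
           trace = NULL)
    })
    rows[[length(rows) + 1L]] <- res$row
    traces[[as.character(seed)]] <- res$trace
  }
  per_seed <- do.call(rbind, rows)
  structure(list(setting = setting, per_seed = per_seed,
                 fid_traces = traces,
                 partial = anyNA(per_seed$delta_auc),
                 seeds = seeds),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  ok <- !is.na(x$per_seed$delta_auc)
  cat(sprintf("benchmark_result: %d/%d seeds complete\n", sum(ok), nrow(x$per_seed)))
  if (any(ok))
    cat(sprintf("  mean AUC_real %.4f, AUC_syn %.4f, dAUC %+.4f, Delta_syn %+.4f\n",
                mean(x$per_seed$auc_real[ok]), mean(x$per_seed$auc_syn[ok]),
                mean(x$per_seed$delta_auc[ok]), mean(x$per_seed$delta_syn[ok])))
  invisible(x)
}

#' Label-overfitting diagnostic Delta_syn
#'
#' For a classifier trained on synthetic data, the difference in mean AUROC
#' when testing on the synthetic versus the real test fold:
#' \eqn{\Delta_{syn} = AUC_{syn}(X_{syn}) - AUC_{syn}(X_{real})}. In the
#' ideal case of a generator that captured the real class-conditional
#' distribution, Delta_syn tends to 0; large positive values indicate the
#' generator encodes class identity in unrealistic image features.
#'
#' @param model Classifier trained on synthetic data.
#' @param syn_test,real_test Label-equivalent test folds.
#' @return Signed difference in [-1, 1].
#' @export
delta_syn <- function(model, syn_test, real_test) {
  check_that(store_size(syn_test) == store_size(real_test) &&
               identical(sort(combo_key(syn_test$labels)),
                         sort(combo_key(real_test$labels))),
             "test folds are not label-equivalent")
  evaluate_mean_auc(model, syn_test)$mean_auc -
    evaluate_mean_auc(model, real_test)$mean_auc
}

# ---- Mann-Whitney U ----------------------------------------------------------

# exact null distribution of U for sample sizes (m, n) without ties:
# counts[u + 1] = number of arrangements with U = u (standard DP recursion)
mwu_count_dist <- function(m, n) {
  # f(m, n, u) = f(m-1, n, u-n) + f(m, n-1, u); f(0, n, 0) = f(m, 0, 0) = 1
  maxu <- m * n
  g <- matrix(0, n + 1L, maxu + 1L)
  g[, 1L] <- 1                                  # m = 0 baseline
  for (mi in seq_len(m)) {
    h <- matrix(0, n + 1L, maxu + 1L)
    h[1L, 1L] <- 1                              # n = 0
    for (ni in seq_len(n)) {
      for (u in 0:maxu) {
        h[ni + 1L, u + 1L] <- h[ni, u + 1L] +
          (if (u >= ni) g[ni + 1L, u - ni + 1L] else 0)
      }
    }
    g <- h
  }
  g[n + 1L, ]
}

#' One-sided Mann-Whitney U test
#'
#' U counts pairs (a, b) with a > b (ties count 1/2). For `n + m <= 12`
#' without ties the p-value is exact via the count-distribution recursion;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Applied in the benchmark to compare
#' AUC_real - AUC_syn distributions between extrema settings.
#'
#' @param a,b Numeric samples.
#' @param alternative `"greater"` (a tends larger, default) or `"less"`.
#' @param method `"auto"` (exact when n + m <= 12 and tie-free), `"exact"`,
#'   or `"normal"`.
#' @return List with `U` (statistic for sample `a`), `p`, and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney_extrema <- function(a, b, alternative = c("greater", "less"),
                                 method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  check_that(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  if (alternative == "less") {
    sw <- a; a <- b; b <- sw
    alternative <- "greater"
  }
  m <- length(a); n <- length(b)
  U <- sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1)))
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(method,
                      auto = m + n <= 12 && !has_ties,
                      exact = {
                        check_that(!has_ties, "exact branch requires tie-free data")
                        TRUE
                      },
                      normal = FALSE)
  if (use_exact) {
    cnt <- mwu_count_dist(m, n)
    p <- sum(cnt[(U + 1):(m * n + 1)]) / choose(m + n, m)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- m * n / 2
    ranks <- rank(c(a, b))
    tie_sizes <- table(c(a, b))
    N <- m + n
    tiecor <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
    sig2 <- m * n / 12 * (N + 1 - tiecor)
    z <- (U - mu - 0.5) / sqrt(sig2)
    list(U = U, p = stats::pnorm(z, lower.tail = FALSE), method = "normal")
  }
}
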