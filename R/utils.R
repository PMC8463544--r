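#' @keywords internal
"_PACKAGE"

# -- argument checking helpers -------------------------------------------------

stop_input <- function(...) {
  stop(structure(class = c("synthrad_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_input(...)
  invisible(TRUE)
}

is_power_of_two <- function(x) {
  x > 0 && abs(x - 2^round(log2(x))) < 1e-9
}

# -- seed management -----------------------------------------------------------

#' Derive an independent child seed from a master seed
#'
#' A benchmark run fans a single master seed out into per-stage seeds (data
#' generation, GAN training, synthesis noise, classifier training) so stages
#' are reproducible yet independently seeded. The fan-out is a fixed integer
#' hash kept below 2^31.
#'
#' @param seed Master seed (integer).
#' @param stream Stream index (integer >= 0) selecting the child stream.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
fanout_seed <- function(seed, stream = 0L) {
  m <- 2147483647                       # 2^31 - 1 (Mersenne prime, Lehmer modulus)
  s <- (as.numeric(seed) %% m + m) %% m
  st <- as.numeric(stream) %% m
  # two rounds of a multiplicative congruential mix; products stay < 2^53
  v <- (s * 48271 + st * 16807 + 12345) %% m
  v <- (v * 69621 + 1) %% m
  as.integer(v)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# -- small numeric helpers -----------------------------------------------------

# multi-hot matrix -> one string key per row ("0110...")
combo_key <- function(y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  apply(y, 1, function(r) paste0(as.integer(r), collapse = ""))
}

key_to_combo <- function(key) {
  as.integer(strsplit(key, "")[[1]])
}

# largest-remainder apportionment of n units to fractions f (sum 1)
largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    # ties broken by position order (train > val > test priority)
    idx <- order(-frac, seq_along(f))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
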