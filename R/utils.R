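# Internal helpers: seeded RNG management and small assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Hierarchical seed splitting: child streams are a pure function of
# (parent seed, integer key), so adding a receptor or trial never perturbs
# the streams of the others. Arithmetic stays below 2^53, result in
# [1, 2147483646] (a valid 32-bit seed).
split_seed <- function(parent, key) {
  stopifnot(is.numeric(parent), is.numeric(key))
  m <- 2147483647
  h <- (48271 * (parent %% m) + 69621 * (key %% m) + 12345) %% m
  h <- (69621 * h + 48271) %% m
  as.integer(h %% (m - 1) + 1)
}

stop_ <- function(...) stop(..., call. = FALSE)

assert_sorted <- function(x, what = "spike_times") {
  if (is.unsorted(x, strictly = FALSE)) {
    stop_(what, " must be sorted in increasing order")
  }
  invisible(x)
}
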