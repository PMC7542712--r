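## internal helpers shared across modules

copol_stop <- function(..., class = "copol_error") {
  stop(structure(
    class = c(class, "copol_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

copol_usage_stop <- function(...) copol_stop(..., class = "copol_usage_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

## population count of a non-negative 32-bit integer (vectorised)
popcount <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x != 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

## all permutations of 1..n as a list of integer vectors, lexicographic order
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations(n - 1L)
    for (p in rest) {
      q <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, q[p])
    }
  }
  out
}

## deterministic stream of sub-seeds derived from one master seed
seed_stream <- function(master, n) {
  stopifnot(is_count(n))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
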