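# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds below 2^31 derived from a master seed
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  x
}

# nearest sample index for a time (seconds) on a regular axis
time_index <- function(times, t) {
  i <- which.min(abs(times - t))
  i[1]
}

window_indices <- function(times, window) {
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         "] contains no samples", call. = FALSE)
  idx
}
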