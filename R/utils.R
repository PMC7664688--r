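#' Derive a child seed from a master seed
#'
#' The generator and evaluation stages draw all randomness from seeds derived
#' with this splitting rule, so any subset of the experiment (one subject, one
#' question, one fold) can be re-simulated independently of the rest. The rule
#' is a Lehmer-style mix kept strictly below 2^31 so the result is always a
#' valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (e.g. subject index,
#'   question index), mixed in order.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master %% 2147483647)
  for (k in seq_along(idx)) {
    # 69069 * 2^31 < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.double(idx[k]) * 2654435761 %% 2147483647 + k) %%
      2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# shared argument checks
stop_if_not_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
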