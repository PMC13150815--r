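# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' Deterministically hashes the master seed together with arbitrary tags
#' (character or numeric) into an integer seed in `[0, 2^31 - 2]`. Used to
#' give every independent random stream (noise, preconcentration error,
#' split sequences) its own seed so that streams can be replayed in
#' isolation.
#'
#' @param seed integer master seed.
#' @param ... stream tags (coerced to character).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  x <- paste(c(format(seed, scientific = FALSE), as.character(unlist(list(...)))),
             collapse = "|")
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
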