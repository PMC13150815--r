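# Wavenumber axis: the common grid every spectrum lives on.

#' Construct a wavenumber axis
#'
#' Builds a uniformly spaced, strictly ascending wavenumber grid covering
#' `[lo, hi]` (inclusive of `lo`; `hi` is included when `(hi - lo)` is a
#' multiple of `step`). An FT-IR instrument quoting a nominal resolution of
#' 4 cm-1 typically stores points every 2 cm-1, hence the default.
#'
#' @param lo,hi range in cm-1, `lo < hi`, `lo >= 0`.
#' @param step point spacing in cm-1 (> 0).
#' @return object of class `wn_axis`: a numeric vector of wavenumbers with a
#'   `step` attribute.
#' @examples
#' length(make_axis(450, 4000, 2)) # 1776
#' @export
make_axis <- function(lo, hi, step = 2) {
  stopifnot_scalar_number(lo, "lo")
  stopifnot_scalar_number(hi, "hi")
  stopifnot_scalar_number(step, "step")
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (lo >= hi) stop("`lo` must be strictly less than `hi`", call. = FALSE)
  if (lo < 0) stop("wavenumbers must be non-negative", call. = FALSE)
  values <- seq(lo, hi, by = step)
  structure(values, step = step, class = "wn_axis")
}

#' Coerce/validate a wavenumber axis
#'
#' Accepts a `wn_axis` or a plain numeric vector; checks strict monotonicity,
#' uniform spacing (within 1e-9 cm-1) and non-negativity. Descending input is
#' reversed to the canonical ascending order.
#'
#' @param x numeric vector or `wn_axis`.
#' @return a `wn_axis` in ascending order.
#' @export
as_wn_axis <- function(x) {
  v <- as.numeric(x)
  if (length(v) < 2L) stop("an axis needs at least 2 points", call. = FALSE)
  if (any(!is.finite(v))) stop("axis values must be finite", call. = FALSE)
  d <- diff(v)
  if (all(d < 0)) { v <- rev(v); d <- diff(v) }
  if (any(d <= 0)) stop("axis must be strictly monotone", call. = FALSE)
  if (max(d) - min(d) > 1e-9) stop("axis must be uniformly spaced", call. = FALSE)
  if (v[1] < 0) stop("wavenumbers must be non-negative", call. = FALSE)
  structure(v, step = mean(d), class = "wn_axis")
}

axis_step <- function(axis) attr(axis, "step") %||% mean(diff(as.numeric(axis)))

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d points, %.6g-%.6g cm-1, step %.6g cm-1\n",
              length(x), min(x), max(x), axis_step(x)))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(as.numeric(a) - as.numeric(b))) <= tol
}
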