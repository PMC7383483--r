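# Small 3-vector helpers used throughout the geometry code. All coordinates are
# millimetres in a right-handed patient frame: +x patient left, +y anterior,
# +z cranial.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop("degenerate ", what, ": zero or non-finite length", call. = FALSE)
  }
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.dot <- function(a, b) sum(a * b)

.is_point3 <- function(p) {
  is.numeric(p) && length(p) == 3L
}

.finite_point3 <- function(p) {
  .is_point3(p) && all(is.finite(p))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
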