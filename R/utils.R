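# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a classed condition so callers can discriminate error kinds
cap_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "capscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    cap_stop("capscan_argument_error",
             "`%s` must be a single finite number in [%s, %s]", name, lo, hi)
  invisible(x)
}

# Euclidean norms of rows of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# dihedral angle (degrees, signed) defined by four points (rows)
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# quasi-uniform points on the unit sphere (spherical Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

run_lengths <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, value = r$values,
             length = r$lengths)
}
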