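# Small 3-D linear-algebra helpers shared by the droplet generator and the
# orientation analysis.  All angles are in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors
#'
#' @param u,v numeric length-3 vectors (need not be unit length).
#' @return angle in degrees on \[0, 180\].
#' @keywords internal
angle_deg <- function(u, v) {
  cth <- sum(unit3(u) * unit3(v))
  acos(min(1, max(-1, cth))) * 180 / pi
}

# Rodrigues rotation matrix about `axis` by `theta` degrees.
rot_axis <- function(axis, theta) {
  a <- unit3(axis)
  th <- theta * pi / 180
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Orthonormal basis with e3 = unit(r); e1, e2 span the perpendicular plane.
onb_from <- function(r) {
  e3 <- unit3(r)
  seed <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(seed - sum(seed * e3) * e3)
  e2 <- cross3(e3, e1)
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Rotation mapping the body-frame pair (a1, b1) onto the world pair (a2, b2),
# assuming angle(a1, b1) == angle(a2, b2).  Triad construction.
triad_rotation <- function(a1, b1, a2, b2) {
  f <- function(a, b) {
    a <- unit3(a)
    u <- b - sum(a * b) * a
    u <- unit3(u)
    cbind(a, u, cross3(a, u))
  }
  f(a2, b2) %*% t(f(a1, b1))
}

# Uniform random rotation matrix (random unit quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q * q))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}
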