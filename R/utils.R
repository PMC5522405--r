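# Small 3-vector helpers shared across modules. All lengths in Angstrom,
# all angles in degrees at the interfaces; radians only inside formulas.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v, tol = 1e-12) {
  n <- .norm3(v)
  if (n < tol) stop("degenerate near-zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#'
#' Plain arccos angle between two 3-vectors, in degrees. Used for the
#' inter-chain sn angles and for the protein bending angle alike.
#'
#' @param a,b numeric 3-vectors.
#' @param tol vectors with norm below `tol` raise a degenerate-geometry error.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_between <- function(a, b, tol = 1e-12) {
  na <- .norm3(a)
  nb <- .norm3(b)
  if (na < tol || nb < tol) {
    stop("degenerate geometry: zero-length vector in angle computation",
         call. = FALSE)
  }
  .deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}

# Rodrigues rotation matrix: rotate by theta_deg about (unnormalised) axis.
.rotmat <- function(axis, theta_deg) {
  u <- .unit(axis)
  t <- .rad(theta_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# A unit vector perpendicular to d, deterministic given d.
.any_perp <- function(d) {
  u <- .unit(d)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross3(u, ref))
}

# A uniformly random unit vector perpendicular to d (uses the RNG stream).
.random_perp <- function(d) {
  p <- .any_perp(d)
  q <- .cross3(.unit(d), p)
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * p + sin(phi) * q
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
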