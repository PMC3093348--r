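# Small numerical helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for display of efficiency metrics;
#' `base::round()` rounds half to even, which would flip entries such as
#' 0.235 -> 0.24 vs 0.23 depending on binary representation.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against binary representation artefacts
  # (e.g. 1.005 * 100 == 100.49999...)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Rotation matrix for angle `theta` (radians) about unit axis `ax`
# (Rodrigues form).
rotation_matrix <- function(ax, theta) {
  ax <- unit(ax)
  ct <- cos(theta); st <- sin(theta)
  x <- ax[1]; y <- ax[2]; z <- ax[3]
  K <- matrix(c(0, -z, y, z, 0, -x, -y, x, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(ax)
}

# Rotate points (n x 3) about the axis through `origin` with direction `ax`.
rotate_about_axis <- function(pts, origin, ax, theta_deg) {
  R <- rotation_matrix(ax, theta_deg * pi / 180)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, `+`)
}

# Angle at vertex b of the triangle a-b-c, in degrees.
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# All pairwise Euclidean distances between rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == as.integer(x)
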