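#' Spherocylindrical particle
#'
#' Constructs a rigid spherocylinder (capsule): a cylinder of length `l` and
#' diameter `d` capped by two hemispheres, total length `l + d`, aspect ratio
#' `f = 1 + l/d`. All lengths are in channel-width units (the channel diameter
#' is the unit of length), so `d` must lie in (0, 1) for the particle to fit.
#'
#' Masses are assigned assuming uniform density, which fixes the ratio of the
#' cylinder mass `m1` to the mass `m2` of a single hemispherical cap at
#' `m1/m2 = 3l/(2r)`; the total mass is normalised to `m1 + 2*m2 = 1` so that
#' the rotational step scale depends on shape only. The body-frame inertia
#' tensor (z along the particle axis) is diagonal with
#' \deqn{M_{xx} = M_{yy} = m_1(l^2/12 + r^2/4) + 2 m_2 (2r^2/5 + l^2/4 + 3lr/8)}
#' \deqn{M_{zz} = (m_1/2 + 4 m_2/5)\, r^2.}
#' For `l = 0` the particle is a solid sphere and the tensor is isotropic,
#' `(2/5) r^2` for unit mass.
#'
#' @param l Length of the cylindrical core, `>= 0`. Exactly one of `l` and `f`
#'   may be given; `l = 0` (the default) is a sphere.
#' @param d Particle diameter, in (0, 1).
#' @param f Aspect ratio `1 + l/d`, `>= 1`; if supplied, `l = d * (f - 1)`.
#' @return An object of class `"spherocylinder"`: a list with elements `l`,
#'   `d`, `r`, `f`, `m1`, `m2` and the 3x3 diagonal `M_body`.
#' @examples
#' p <- spherocylinder(d = 0.45, f = 2.9)
#' p$l              # 0.855
#' inertia_tensor(spherocylinder(l = 0, d = 0.9))  # isotropic, 0.081
#' @export
spherocylinder <- function(l = 0, d, f = NULL) {
  if (!is.null(f)) {
    if (!missing(l) && l != 0)
      stop("give either `l` or `f`, not both")
    if (!is.numeric(f) || length(f) != 1L || f < 1)
      stop("`f` must be a single number >= 1")
    l <- d * (f - 1)
  }
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d >= 1)
    stop("`d` must be a single number in (0, 1)")
  if (!is.numeric(l) || length(l) != 1L || l < 0)
    stop("`l` must be a single number >= 0")
  r <- d / 2
  q <- 3 * l / (2 * r)           # m1 / m2 for uniform density
  m2 <- 1 / (q + 2)              # total mass m1 + 2 m2 == 1
  m1 <- q * m2
  Mxx <- m1 * (l^2 / 12 + r^2 / 4) +
    2 * m2 * (2 * r^2 / 5 + l^2 / 4 + 3 * l * r / 8)
  Mzz <- (m1 / 2 + 4 * m2 / 5) * r^2
  structure(
    list(l = l, d = d, r = r, f = 1 + l / d, m1 = m1, m2 = m2,
         M_body = diag(c(Mxx, Mxx, Mzz))),
    class = "spherocylinder"
  )
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf("Spherocylinder: l = %.4g, d = %.4g (f = %.4g)\n", x$l, x$d, x$f))
  cat(sprintf("  masses: m1 = %.4g (core), m2 = %.4g (each cap)\n", x$m1, x$m2))
  cat(sprintf("  inertia (body frame): Mxx = Myy = %.6g, Mzz = %.6g\n",
              x$M_body[1, 1], x$M_body[3, 3]))
  invisible(x)
}

#' Cylindrical channel
#'
#' The channel is a cylinder of length `L` about the z-axis whose diameter is
#' the unit of length, so its radius is fixed at 0.5. The entrance sits at
#' `z = 0` (reflecting for the particle centre) and the exit at `z = L`
#' (absorbing). The radial wall is treated as infinite in z: the particle's
#' caps may protrude past the ends so long as its centre stays inside.
#'
#' @param L Channel length in channel-width units, `> 0`. Default 14.3.
#' @return An object of class `"pore_channel"` with elements `L` and `radius`.
#' @export
channel <- function(L = 14.3) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("`L` must be a single number > 0")
  structure(list(L = L, radius = 0.5), class = "pore_channel")
}

#' @export
print.pore_channel <- function(x, ...) {
  cat(sprintf("Cylindrical channel: length L = %.4g, radius %.2g (unit diameter)\n",
              x$L, x$radius))
  invisible(x)
}

#' Body-frame inertia tensor
#'
#' @param p A [spherocylinder()].
#' @return The 3x3 diagonal inertia tensor in the body frame (z along the
#'   particle axis), total mass 1.
#' @export
inertia_tensor <- function(p) {
  stopifnot(inherits(p, "spherocylinder"))
  p$M_body
}

#' Moment of inertia about an arbitrary lab-frame axis
#'
#' Computes \eqn{\hat A^T M \hat A} for the particle's inertia tensor expressed
#' in the lab frame, where the particle axis points along `u`. Because the
#' transverse moments are equal (`Mxx == Myy`), the result depends only on the
#' angle between `A` and `u`:
#' `Mxx + (Mzz - Mxx) * (A . u)^2`, independent of the roll angle about `u`.
#'
#' @param p A [spherocylinder()].
#' @param u Unit 3-vector, particle axis direction.
#' @param A Unit 3-vector, rotation axis.
#' @return Positive scalar moment of inertia.
#' @export
axial_moment <- function(p, u, A) {
  stopifnot(inherits(p, "spherocylinder"))
  ca <- sum(A * u)
  Mxx <- p$M_body[1, 1]
  Mzz <- p$M_body[3, 3]
  Mxx + (Mzz - Mxx) * ca^2
}

#' Rotational step scale from energy equipartition
#'
#' The standard deviation of the random rotation angle about axis `A` is tied
#' to the translational step scale so that energy is shared equally among the
#' degrees of freedom: \eqn{\sigma_\varphi(\hat A) = \sigma_x (\hat A^T M
#' \hat A)^{-1/2}}.
#'
#' @inheritParams axial_moment
#' @param sigma_x Translational step scale, `> 0`.
#' @return Positive scalar, the rotation-angle standard deviation in radians.
#' @export
sigma_phi <- function(p, u, A, sigma_x) {
  sigma_x / sqrt(axial_moment(p, u, A))
}

#' Capsule-wall collision predicate
#'
#' Tests whether the capsule (the segment from `x - (l/2) u` to `x + (l/2) u`
#' inflated by radius `r`) pokes outside the channel's cylindrical wall of
#' radius 0.5 about the z-axis. The radial distance from the axis is convex
#' along the core segment, so the exact test reduces to checking the two
#' segment endpoints: collision iff
#' `max(endpoint radial distance) + r > 0.5`. The channel ends impose no wall;
#' only the radial boundary is material.
#'
#' @param p A [spherocylinder()].
#' @param x 3-vector centre position.
#' @param u Unit 3-vector axis direction.
#' @param ch A [channel()].
#' @return `TRUE` if the particle intersects the wall.
#' @export
collides <- function(p, x, u, ch) {
  h <- p$l / 2
  e1 <- x[1:2] + h * u[1:2]
  e2 <- x[1:2] - h * u[1:2]
  rad <- sqrt(max(sum(e1^2), sum(e2^2)))
  rad + p$r > ch$radius
}

#' Rotate a unit vector about an axis
#'
#' Rodrigues rotation of `u` about the unit axis `A` by `dphi` radians
#' (right-handed). The rotation axis passes through the particle centre, so
#' rotating the orientation leaves the centre unchanged. The result is
#' renormalised to guard against floating-point drift over long step
#' sequences.
#'
#' @param u Unit 3-vector to rotate.
#' @param A Unit 3-vector rotation axis.
#' @param dphi Rotation angle in radians.
#' @return Rotated unit 3-vector.
#' @export
rotate_axis <- function(u, A, dphi) {
  c_ <- cos(dphi)
  s_ <- sin(dphi)
  v <- u * c_ + cross3(A, u) * s_ + A * sum(A * u) * (1 - c_)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Uniform random unit vectors on the sphere
#'
#' Draws axis directions uniformly on the two-dimensional sphere by
#' normalising standard-normal 3-vectors. Uses R's global RNG stream, so
#' results are reproducible under [set.seed()].
#'
#' @param n Number of draws.
#' @return For `n = 1` a unit 3-vector; otherwise an `n x 3` matrix whose rows
#'   are unit vectors.
#' @export
random_unit_axis <- function(n = 1) {
  if (n == 1L) {
    repeat {
      a <- stats::rnorm(3)
      nr <- sqrt(sum(a^2))
      if (nr >= 1e-12) return(a / nr)
    }
  }
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  nr <- sqrt(rowSums(m^2))
  bad <- nr < 1e-12
  while (any(bad)) {   # astronomically rare; kept for exactness
    m[bad, ] <- stats::rnorm(3 * sum(bad))
    nr[bad] <- sqrt(rowSums(m[bad, , drop = FALSE]^2))
    bad <- nr < 1e-12
  }
  m / nr
}
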