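# Small 3D geometry toolkit used by perception and the fixture builders.
# All lengths in Angstrom, all angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle (degrees) at vertex b of a-b-c
angle_deg <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# deterministic unit vector perpendicular to v
perp_unit <- function(v) {
  ref <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
         else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  unitv(vcross(v, ref))
}

# Rotation matrix (det +1) taking unit vector a onto unit vector b.
rot_align <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- vcross(a, b); s <- vnorm(v); c0 <- sum(a * b)
  if (s < 1e-10) {
    if (c0 > 0) return(diag(3))
    p <- perp_unit(a)                       # 180 degrees about any perpendicular
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

# Rotation by theta (deg) about unit axis u (Rodrigues).
rot_axis <- function(u, theta) {
  u <- unitv(u); t <- theta * pi / 180
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * cos(t) + ux * sin(t) + outer(u, u) * (1 - cos(t))
}

# NeRF atom placement: position of d bonded to c, with |cd| = len,
# angle(b,c,d) = ang and dihedral(a,b,c,d) = dih.
nerf_place <- function(a, b, c, len, ang = 109.471, dih = 180) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)                        # bc, m, n orthonormal
  ang <- ang * pi / 180; dih <- dih * pi / 180
  d2 <- c(-len * cos(ang),
          len * sin(ang) * cos(dih),
          len * sin(ang) * sin(dih))
  as.vector(c + cbind(bc, m, n) %*% d2)
}

# The two remaining tetrahedral directions at a center whose bonds point
# along unit vectors d1 and d2.
tet_dirs2 <- function(d1, d2) {
  d1 <- unitv(d1); d2 <- unitv(d2)
  b <- -unitv(d1 + d2)
  p <- unitv(vcross(d1, d2))
  half <- 54.7356 * pi / 180                # half the d3-d4 angle
  list(cos(half) * b + sin(half) * p,
       cos(half) * b - sin(half) * p)
}

# The fourth tetrahedral direction given three bond directions.
tet_dir3 <- function(d1, d2, d3) -unitv(unitv(d1) + unitv(d2) + unitv(d3))

# Three further tetrahedral directions at a center with one known bond
# direction d1 (orientation fixed by the deterministic perpendicular),
# spread 120 degrees apart around the d1 axis.
tet_dirs1 <- function(d1) {
  d1 <- unitv(d1)
  p <- perp_unit(d1)
  a <- 109.471 * pi / 180
  lapply(c(0, 120, 240), function(t) {
    r <- as.vector(rot_axis(d1, t) %*% p)
    unitv(cos(a) * d1 + sin(a) * r)
  })
}

# The two remaining trigonal (120 deg) directions at an sp2 center with one
# known bond direction d1; ref fixes the plane.
trig_dirs1 <- function(d1, ref) {
  d1 <- unitv(d1)
  n <- vcross(d1, ref)
  if (vnorm(n) < 1e-8) n <- vcross(d1, perp_unit(d1)) else n <- unitv(n)
  list(as.vector(rot_axis(n, 120) %*% d1),
       as.vector(rot_axis(n, -120) %*% d1))
}

# The third trigonal direction given two bond directions.
trig_dir2 <- function(d1, d2) -unitv(unitv(d1) + unitv(d2))

# Planar regular n-ring in the xy-plane with the given edge length; first
# vertex on the +x axis.
ring_flat <- function(n, edge) {
  r <- edge / (2 * sin(pi / n))
  t(sapply(seq_len(n) - 1, function(k) {
    th <- 2 * pi * k / n
    c(r * cos(th), r * sin(th), 0)
  }))
}

# Ideal chair six-ring with uniform edge length and tetrahedral internal
# angles: vertices (a cos(60k), a sin(60k), (-1)^k b).
ring_chair <- function(edge = 1.53) {
  f <- function(t) {
    p <- sapply(0:2, function(k) c(cos(pi * k / 3), sin(pi * k / 3),
                                   (-1)^k * t))
    angle_deg(p[, 1], p[, 2], p[, 3]) - 109.471
  }
  t0 <- stats::uniroot(f, c(0.05, 1))$root
  a <- edge / sqrt(1 + 4 * t0^2); b <- a * t0
  t(sapply(0:5, function(k) {
    th <- pi * k / 3
    c(a * cos(th), a * sin(th), (-1)^k * b)
  }))
}

# Project point p onto the plane through q with unit normal n.
plane_project <- function(p, q, n) p - sum((p - q) * n) * n

# Unit normal of the plane through three points.
plane_normal <- function(p1, p2, p3) unitv(vcross(p2 - p1, p3 - p1))
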