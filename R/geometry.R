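# Internal 3D geometry helpers. All coordinates are in Angstrom; vectors are
# plain numeric length-3, point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# angle at vertex b (degrees)
angle_deg <- function(a, b, c) {
  u <- unitv(a - b); w <- unitv(c - b)
  acos(max(-1, min(1, sum(u * w)))) * 180 / pi
}

# signed dihedral a-b-c-d (degrees)
torsion_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# rotation matrix about unit axis by theta degrees (Rodrigues)
rotation_about_axis <- function(axis, theta_deg) {
  u <- unitv(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

# proper rotation taking unit vector a onto unit vector b (minimal rotation)
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- vcross(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3L))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(vcross(a, p))
    return(rotation_about_axis(axis, 180))
  }
  K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + K + K %*% K * ((1 - c_) / s^2)
}

# an arbitrary unit vector perpendicular to u (deterministic)
perp_vector <- function(u) {
  u <- unitv(u)
  p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(vcross(u, p))
}

# NeRF-style placement: position of atom d with |cd| = len, angle b-c-d =
# ang_deg, dihedral a-b-c-d = tor_deg.
nerf_place <- function(a, b, c, len, ang_deg, tor_deg) {
  th <- ang_deg * pi / 180
  ph <- tor_deg * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-len * cos(th), len * sin(th) * cos(ph), len * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# The two unit directions d from a centre atom that make equal angles with
# both of its (unit) neighbour directions uA, uB, completing a tetrahedral
# centre: d . uA = d . uB = cos(109.47 deg).
tetrahedral_directions <- function(uA, uB) {
  ct <- cos(109.47 * pi / 180)
  s <- uA + uB
  w <- vcross(uA, uB)
  sw <- sum(w * w)
  if (sw < 1e-12) stop("degenerate (collinear) neighbour geometry", call. = FALSE)
  # d = alpha * s + beta * w ; d.uA = alpha * (1 + uA.uB) = ct
  dot <- sum(uA * uB)
  alpha <- ct / (1 + dot)
  rem <- 1 - alpha^2 * sum(s * s)
  if (rem < 0) rem <- 0
  beta <- sqrt(rem / sw)
  list(alpha * s + beta * w, alpha * s - beta * w)
}
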