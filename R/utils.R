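# Small internal helpers: 3-vector algebra, quaternions, angle metrology,
# and a dependency-free config fingerprint.

vnorm <- function(v) sqrt(sum(v * v))

vhat <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two 3-vectors in degrees
#' @noRd
vangle_deg <- function(a, b) {
  ca <- sum(vhat(a) * vhat(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

## Angle between two undirected lines (folded to [0, 90] degrees).
line_angle_deg <- function(a, b) {
  ang <- vangle_deg(a, b)
  min(ang, 180 - ang)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Rotation matrix about the +y (craniocaudal) axis, degrees.
rot_y <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), 0, sin(t),
           0, 1, 0,
           -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

## Random rotation matrix (for rigid-invariance property tests).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-6) break
  }
  quat_to_matrix(q / n)
}

## Quaternions stored as c(w, x, y, z).
quat_normalize <- function(q) q / vnorm(q)

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## FNV-1a 64-bit over the deparsed object; used to fingerprint resolved
## configurations in run metadata. Arithmetic is done in two 32-bit halves
## to stay inside double precision.
fnv1a_hex <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x, control = "exact"), collapse = "\n"))
  hi <- 0xcbf29ce4; lo <- 0x84222325
  for (b in bytes) {
    ## xor the incoming byte into the low 16-bit limb (values kept < 2^16,
    ## so base R's 32-bit bitwXor is safe)
    low16 <- lo %% 65536
    lo <- (lo - low16) + bitwXor(as.integer(low16), as.integer(b))
    ## 64-bit multiply by the FNV prime, split into 16-bit limbs
    a0 <- lo %% 65536; a1 <- (lo %/% 65536) %% 65536
    a2 <- hi %% 65536; a3 <- (hi %/% 65536) %% 65536
    ## prime = 0x00000100_000001b3 -> limbs (b0=0x01b3, b1=0, b2=0x0100, b3=0)
    r0 <- a0 * 0x01b3
    r1 <- a1 * 0x01b3
    r2 <- a2 * 0x01b3 + a0 * 0x0100
    r3 <- a3 * 0x01b3 + a1 * 0x0100
    c0 <- r0 %% 65536; k <- r0 %/% 65536
    c1 <- (r1 + k) %% 65536; k <- (r1 + k) %/% 65536
    c2 <- (r2 + k) %% 65536; k <- (r2 + k) %/% 65536
    c3 <- (r3 + k) %% 65536
    lo <- c0 + 65536 * c1
    hi <- c2 + 65536 * c3
  }
  sprintf("%04x%04x%04x%04x",
          as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}

## Format a numeric with 9 significant digits (file outputs).
fmt9 <- function(x) trimws(formatC(x, digits = 9, format = "g"))

`%||%` <- function(a, b) if (is.null(a)) b else a
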