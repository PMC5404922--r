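# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Angle in degrees between two vectors.
vec_angle <- function(u, v) {
  cu <- sum(u * v) / (vnorm(u) * vnorm(v))
  cu <- max(-1, min(1, cu))
  acos(cu) * 180 / pi
}

deg2rad <- function(d) d * pi / 180

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation carrying unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis for the half-turn
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(p - sum(p * u) * u)
    return(rotation_about_axis(ax, 180))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  rotation_about_axis(ax, acos(max(-1, min(1, c_))) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Residue key string used for map-like lookups: "chain:resnum:icode"
res_key <- function(chain, resnum, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resnum, icode, sep = ":")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
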