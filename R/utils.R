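# Small vector helpers shared across the geometry code.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x == -180, 180, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Rotation matrix for angle theta (degrees) about unit axis u (Rodrigues).
rotation_about <- function(u, theta_deg) {
  u <- unit(u)
  th <- deg2rad(theta_deg)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
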