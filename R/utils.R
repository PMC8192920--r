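# Small numeric helpers shared across the package. All lengths are mm,
# all angles radians unless a function name says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# wrap an angle into [0, 2*pi)
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

# signed minimal angular difference a - b in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# shortest wrapped distance between angles (non-negative)
angle_dist <- function(a, b) abs(angle_diff(a, b))

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# rotate an n x 2 matrix counterclockwise by theta
rotate2 <- function(xy, theta) {
  xy <- as_xy_matrix(xy)
  xy %*% t(rot2(theta))
}

as_xy_matrix <- function(xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) stop("expected a two-column coordinate matrix", call. = FALSE)
  dimnames(xy) <- NULL
  xy
}

as_xyz_matrix <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("expected a three-column coordinate matrix", call. = FALSE)
  dimnames(p) <- NULL
  p
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-12)) stop("cannot normalize near-zero rows", call. = FALSE)
  m / n
}

# linear interpolation of matrix rows at fractional index positions
lerp_rows <- function(m, i0, frac) {
  m[i0, , drop = FALSE] * (1 - frac) + m[pmin(i0 + 1L, nrow(m)), , drop = FALSE] * frac
}

# unwrap a sequence of angles (remove 2*pi jumps), NA entries carried through
unwrap_angles <- function(a) {
  idx <- which(!is.na(a))
  if (length(idx) < 2L) return(a)
  v <- a[idx]
  d <- angle_diff(v[-1L], v[-length(v)])
  a[idx] <- v[1L] + c(0, cumsum(d))
  a
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
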