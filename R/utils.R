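# Internal helpers shared across modules.

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform random rotation matrix (det +1).
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d + (d == 0)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) abort("cannot normalise a zero vector")
  v / n
}

# Any unit vector orthogonal to `v`.
orthonormal_to <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * v) * v)
  e2 <- c(
    v[2] * e1[3] - v[3] * e1[2],
    v[3] * e1[1] - v[1] * e1[3],
    v[1] * e1[2] - v[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Binary dilation of a logical matrix by a (2r+1) square structuring element.
binary_dilate <- function(m, r) {
  if (r <= 0) return(m)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -r:r) {
    rows_src <- max(1, 1 - di):min(nr, nr - di)
    rows_dst <- rows_src + di
    for (dj in -r:r) {
      cols_src <- max(1, 1 - dj):min(nc, nc - dj)
      cols_dst <- cols_src + dj
      out[rows_dst, cols_dst] <- out[rows_dst, cols_dst] | m[rows_src, cols_src]
    }
  }
  out
}

binary_erode <- function(m, r) {
  if (r <= 0) return(m)
  !binary_dilate(!m, r)
}

# Morphological closing: fills gaps narrower than ~2r cells.
binary_close <- function(m, r) binary_erode(binary_dilate(m, r), r)

# Distance from 2D points to a polyline segment set (vectorised over points).
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  out <- matrix(NA_real_, length(px), length(x1))
  for (s in seq_along(x1)) {
    if (len2[s] < .Machine$double.eps) {
      out[, s] <- sqrt((px - x1[s])^2 + (py - y1[s])^2)
    } else {
      t_ <- ((px - x1[s]) * dx[s] + (py - y1[s]) * dy[s]) / len2[s]
      t_ <- pmin(1, pmax(0, t_))
      out[, s] <- sqrt((px - (x1[s] + t_ * dx[s]))^2 + (py - (y1[s] + t_ * dy[s]))^2)
    }
  }
  apply(out, 1, min)
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  0.5 * sum(x[j] * y - x * y[j])
}
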