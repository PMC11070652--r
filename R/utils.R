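# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# one-hot vector of length `width`, hot at `idx` (idx = 0 -> all zeros)
one_hot <- function(idx, width) {
  v <- numeric(width)
  if (idx > 0L) v[idx] <- 1
  v
}

# pairwise Euclidean distances between rows of two coordinate matrices
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# random unit 3-vector
runif_unit3 <- function(n = 1L) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

# random 3x3 rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

is_finite_coords <- function(x) all(is.finite(as.matrix(x)))
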