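# Internal numerical helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise L2 norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize rows of an n x 3 matrix to unit length; zero rows trigger an
# error when .strict, otherwise stay zero.
unit_rows <- function(m, strict = TRUE, what = "vector") {
  nrm <- row_norms(m)
  if (strict && any(nrm < 1e-10)) {
    stop("degenerate geometry: zero-length ", what)
  }
  nrm[nrm < 1e-10] <- 1
  m / nrm
}

# Uniform random proper rotation matrix (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  d <- sign(diag(qr.R(qr_res)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion (rotation r, translation t) to a protein structure.
transform_structure <- function(structure, r, t = c(0, 0, 0)) {
  for (f in c("N", "CA", "C")) {
    structure[[f]] <- sweep(structure[[f]] %*% t(r), 2, t, "+")
  }
  structure
}

# Derive a reproducible child seed (kept below 2^31) from a base seed.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 1009 + 12345) %% 2147483647)
}

logistic <- function(x) 1 / (1 + exp(-x))
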