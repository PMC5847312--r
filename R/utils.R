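# Internal numeric helpers.
#
# The elementary-mode tableau works on integer-valued doubles: exact as long
# as every intermediate stays below 2^53. We reduce rows by their gcd after
# every combination step and guard against overflow explicitly.

.INT_GUARD <- 2^50

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

.gcd <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0) return(1)
  Reduce(.gcd2, x)
}

.lcm2 <- function(a, b) a / .gcd2(a, b) * b

# Continued-fraction rational approximation of a double.
# Returns c(num, den) with den <= max_den, exact within tol.
.as_fraction <- function(x, tol = 1e-9, max_den = 1e6) {
  if (abs(x - round(x)) < tol) return(c(round(x), 1))
  sign_x <- sign(x)
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) stop("cannot represent coefficient ", sign_x * x,
                          " as a rational with denominator <= ", max_den)
    if (abs(x - h / k) < tol) return(c(sign_x * h, k))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(b - a) < .Machine$double.eps) return(c(sign_x * h, k))
    b <- 1 / (b - a)
  }
}

# Scale each row of a matrix to integer entries (clearing denominators).
# Row scaling by a positive constant leaves the nullspace untouched.
.integerize_rows <- function(m, tol = 1e-9) {
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    nz <- row[row != 0]
    if (length(nz) == 0) next
    dens <- vapply(nz, function(v) .as_fraction(v, tol)[2], numeric(1))
    mult <- Reduce(.lcm2, dens, accumulate = FALSE)
    row <- round(row * mult)
    g <- .gcd(row)
    if (g > 1) row <- row / g
    m[i, ] <- row
  }
  m
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Rank of a numeric matrix via QR (tolerance-based).
.mat_rank <- function(m, tol = 1e-9) {
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) return(0L)
  qr(m, tol = tol)$rank
}

# Orthonormal basis of the (right) nullspace of m.
.nullspace <- function(m, tol = 1e-9) {
  if (nrow(m) == 0) return(diag(ncol(m)))
  s <- svd(m, nu = 0, nv = ncol(m))
  keep <- s$d < tol * max(s$d[1], 1)
  r <- sum(s$d >= tol * max(s$d[1], 1))
  if (r == ncol(m)) return(matrix(0, ncol(m), 0))
  s$v[, seq(r + 1, ncol(m)), drop = FALSE]
}
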