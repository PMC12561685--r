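# Exact arithmetic over GF(p).
#
# Generic rank is a yes/no algebraic property; deciding it with floating SVD
# fails once singular values span more than ~16 orders of magnitude, which
# happens for the larger catalogue models. Instead, matrices are evaluated at
# random points of a prime field and ranked by exact Gaussian elimination: at
# a random point the rank equals the structural (generic) rank with
# probability 1 - O(deg/p) (Schwartz-Zippel). p fits in 31 bits; products are
# formed by 16-bit splitting so every intermediate stays an exact double.

MOD_P <- 2147483629

mod_mul <- function(a, b) {
  a <- a %% MOD_P; b <- b %% MOD_P
  (((a %/% 65536) * b) %% MOD_P * 65536 + (a %% 65536) * b) %% MOD_P
}

mod_inv <- function(a) {
  a <- a %% MOD_P
  if (a == 0) stop("modular inverse of zero", call. = FALSE)
  t0 <- 0; t1 <- 1; r0 <- MOD_P; r1 <- a
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  if (r0 != 1) stop("not invertible", call. = FALSE)
  t0 %% MOD_P
}

mod_pow <- function(a, n) {
  a <- a %% MOD_P
  out <- 1
  while (n > 0) {
    if (n %% 2 == 1) out <- mod_mul(out, a)
    a <- mod_mul(a, a)
    n <- n %/% 2
  }
  out
}

# rational reconstruction of a double that is an exact small rational
mod_rational <- function(x) {
  if (x == round(x)) return(x %% MOD_P)
  for (den in 2:10080) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) {
      return(mod_mul(round(num) %% MOD_P, mod_inv(den)))
    }
  }
  stop("constant ", x, " is not a small rational; use a rational literal",
       call. = FALSE)
}

#' Exact rank of an integer matrix over GF(p)
#' @keywords internal
rank_modp <- function(M) {
  M <- M %% MOD_P
  n <- nrow(M); m <- ncol(M); r <- 0L
  if (n == 0L || m == 0L) return(0L)
  for (j in seq_len(m)) {
    piv <- which(M[, j] != 0)
    piv <- piv[piv > r]
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    M[r, ] <- mod_mul(M[r, ], mod_inv(M[r, j]))
    rows <- which(M[, j] != 0)
    rows <- rows[rows != r]
    if (length(rows)) {
      M[rows, ] <- (M[rows, , drop = FALSE] - outer(M[rows, j], M[r, ], mod_mul)) %% MOD_P
    }
    if (r == n) break
  }
  r
}

mod_mat_mul <- function(A, B) {
  n <- nrow(A); l <- ncol(B)
  out <- matrix(0, n, l)
  for (r in seq_len(n)) {
    prod <- mod_mul(A[r, ], B)
    out[r, ] <- colSums(matrix(prod, nrow = ncol(A))) %% MOD_P
  }
  out
}
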