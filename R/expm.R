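# Matrix exponential via Pade (13,13) approximation with scaling and
# squaring (Higham 2005).  Compartment matrices here are small (<= ~30x30),
# Metzler, and have zero column sums, so exp(M*dt) is a non-negative,
# mass-conserving propagator; exponential stepping is exact for the linear
# systems in this package and sidesteps stiffness entirely.
expm_dense <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1L, 1L]), 1L, 1L))
  b <- c(
    64764752532480000, 32382376266240000, 7771770303897600,
    1187353796428800, 129060195264000, 10559470521600,
    670442572800, 33522128640, 1323241920,
    40840800, 960960, 16380, 182, 1
  )
  theta13 <- 5.371920351148152
  nrmA <- max(colSums(abs(A)))
  s <- 0L
  if (is.finite(nrmA) && nrmA > theta13) {
    s <- as.integer(ceiling(log2(nrmA / theta13)))
    A <- A / 2^s
  } else if (!is.finite(nrmA)) {
    stop("non-finite entries in rate matrix")
  }
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
    b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  if (s > 0L) for (k in seq_len(s)) E <- E %*% E
  E
}
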