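# Shared fixtures, built in code.

# A tiny hand-written panel: 4 lines and 2 hybrids with known counts.
tiny_panel <- function() {
  df <- data.frame(
    entry_id = c("L1", "L2", "L3", "L4", "H1", "H2"),
    entry_type = c(rep("line", 4), rep("hybrid", 2)),
    parent1 = c(NA, NA, NA, NA, "L1", "L2"),
    parent2 = c(NA, NA, NA, NA, "L2", "L3"),
    K3L = c(2L, 0L, 2L, 0L, 1L, 1L),
    K5L = c(2L, 2L, 0L, 0L, 2L, 1L),
    K7S = c(0L, 0L, 2L, 2L, 0L, 1L),
    K9S = c(2L, 0L, 0L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  class(df) <- c("knob_panel", "data.frame")
  df
}

# Generator parameters with every locus effect switched off.
null_params <- function(seed, ...) {
  generator_params(seed = seed, a_mf = 0, a_ff = 0, d_mf = 0, d_ff = 0,
                   gs_knob_effect = 0, ...)
}

# Random genotype matrix for property-style loops.
random_knob_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(sample(0:2, n * 4, replace = TRUE), n,
              dimnames = list(sprintf("E%03d", seq_len(n)), knob_loci()$locus))
  knob_matrix(m)
}

# Brute-force restricted log-likelihood by dense linear algebra, independent
# of the package's eigendecomposition path (constant log|X'X| omitted, as in
# the implementation).
bruteforce_reml_ll <- function(lambda, y, X, K) {
  n <- length(y)
  p <- ncol(X)
  H <- lambda * K + (1 - lambda) * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Hi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                       determinant(H)$modulus +
                       determinant(XtHiX)$modulus))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
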