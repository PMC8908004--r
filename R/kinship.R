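#' Marker-derived kinship matrix
#'
#' VanRaden method-1 genomic relationship matrix from the knob counts:
#' `G = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z` the count matrix centered
#' by twice the allele frequency. Monomorphic loci carry no information and
#' are dropped. A small ridge (`1e-6` times the mean diagonal) is added so
#' the result is positive semi-definite to working precision. An identity
#' mode is provided for sensitivity analysis.
#'
#' @param m A knob matrix or panel.
#' @param method `"vanraden"` (default) or `"identity"`.
#' @return Symmetric numeric matrix with entry ids as dimnames.
#' @examples
#' K <- compute_kinship(generate_panel(generator_params(seed = 1)))
#' @export
compute_kinship <- function(m, method = c("vanraden", "identity")) {
  method <- match.arg(method)
  m <- knob_matrix(m)
  if (method == "identity") {
    K <- diag(nrow(m))
    dimnames(K) <- list(rownames(m), rownames(m))
    return(K)
  }
  f <- presence_freq(m)
  poly <- f > 0 & f < 1
  if (!any(poly))
    stop("all loci are monomorphic; kinship is undefined")
  Z <- sweep(unclass(m)[, poly, drop = FALSE], 2L, 2 * f[poly])
  denom <- 2 * sum(f[poly] * (1 - f[poly]))
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  eps <- 1e-6 * mean(diag(K))
  K <- K + diag(eps, nrow(K))
  dimnames(K) <- list(rownames(m), rownames(m))
  K
}

#' Principal components of the knob count matrix
#'
#' PCs of the column-centered counts, for use as population-structure
#' covariates. Each component's sign is fixed by making its
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param m A knob matrix or panel.
#' @param n_pcs Number of components (0 gives an empty covariate block).
#' @return Numeric matrix, entries x `n_pcs`.
#' @export
compute_pcs <- function(m, n_pcs) {
  m <- knob_matrix(m)
  if (n_pcs < 0) stop("`n_pcs` must be >= 0")
  if (n_pcs == 0L) {
    out <- matrix(numeric(0), nrow = nrow(m), ncol = 0)
    rownames(out) <- rownames(m)
    return(out)
  }
  X <- scale(unclass(m), center = TRUE, scale = FALSE)
  rk <- qr(X)$rank
  if (n_pcs > rk)
    stop(sprintf("`n_pcs` = %d exceeds the genotype matrix rank (%d)", n_pcs, rk))
  pc <- stats::prcomp(X, center = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(m)
  scores
}
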