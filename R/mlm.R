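# Mixed-linear-model machinery: y = X beta + g + e, g ~ N(0, sigma_g^2 K),
# e ~ N(0, sigma_e^2 I). The variance structure is profiled through
# H(lambda) = lambda K + (1 - lambda) I with lambda = sigma_g^2 / (sigma_g^2
# + sigma_e^2), so that V = sigma^2 H and the total sigma^2 has a closed-form
# REML profile. All computations run in the eigenbasis of K, which is
# decomposed once per scan.

kinship_eigen <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-10)) stop("kinship matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("kinship matrix is not positive semi-definite")
  e$values <- pmax(e$values, 0)
  e
}

# Restricted log-likelihood (up to the constant log|X'X|) of lambda, with the
# total variance profiled out. Inputs are pre-rotated: yt = U'y, Xt = U'X,
# d = eigenvalues of K. Returns the components needed downstream.
reml_profile <- function(lambda, yt, Xt, d) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- lambda * d + (1 - lambda)
  if (any(v <= 0)) return(list(ll = -Inf))
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yt - Xt %*% beta
  q <- sum(w * r^2)
  sigma2 <- q / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
                  sum(log(v)) + 2 * sum(log(diag(ch))))
  list(ll = as.numeric(ll), sigma2 = sigma2, beta = beta, XtWX = XtWX,
       v = v, lambda = lambda)
}

# REML over lambda in [0, 1): coarse log-spaced grid on the variance ratio
# delta = sigma_g^2/sigma_e^2, refined by Brent around the grid optimum.
reml_optimize <- function(yt, Xt, d) {
  delta_grid <- c(0, 10^seq(-6, 6, length.out = 49))
  lambda_grid <- delta_grid / (1 + delta_grid)
  ll <- vapply(lambda_grid, function(l) reml_profile(l, yt, Xt, d)$ll, 0)
  flat <- diff(range(ll[is.finite(ll)])) < 1e-8
  i <- which.max(ll)
  lo <- lambda_grid[max(1L, i - 1L)]
  hi <- min(lambda_grid[min(length(lambda_grid), i + 1L)], 1 - 1e-8)
  if (hi > lo && !flat) {
    opt <- stats::optimize(function(l) reml_profile(l, yt, Xt, d)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective >= ll[i]) {
      lambda <- opt$maximum
    } else {
      lambda <- lambda_grid[i]
    }
  } else {
    lambda <- lambda_grid[i]
  }
  if (flat) lambda <- 0
  fit <- reml_profile(lambda, yt, Xt, d)
  fit$flat <- flat
  fit
}

#' Fit the null mixed linear model by REML
#'
#' Estimates the polygenic and residual variance components of
#' `y = X beta + g + e`, `g ~ N(0, sigma_g^2 K)`, `e ~ N(0, sigma_e^2 I)`,
#' by restricted maximum likelihood. The kinship matrix is eigendecomposed
#' once and the variance ratio is optimized in one dimension on a log-spaced
#' grid refined by Brent's method, so the fit is deterministic. A flat
#' profile (e.g. `K` proportional to the identity, where only the total
#' variance is identifiable) is flagged, not silently returned.
#'
#' @param y Numeric response (entry BLUEs).
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always added).
#' @param K Kinship matrix from [compute_kinship()].
#' @return Object of class `knob_mlm`: list with `sigma_g2`, `sigma_e2`,
#'   `lambda` (= sigma_g2 / total), `loglik` (restricted, up to a constant),
#'   `beta`, `flat`, `n`, `p`.
#' @examples
#' s <- simulate_knob_study(generator_params(seed = 1))
#' b <- compute_blues(s$records, "mf", entries = s$panel$entry_id)
#' K <- compute_kinship(s$panel)
#' fit_mlm_null(b$blue, K = K)
#' @export
fit_mlm_null <- function(y, covariates = NULL, K) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  check_mlm_dims(y, X)
  eig <- kinship_eigen(K)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  fit <- reml_optimize(yt, Xt, eig$values)
  if (fit$flat)
    warning("REML profile is flat in the variance ratio; ",
            "only the total variance is identifiable (kinship ~ identity?)")
  structure(
    list(sigma_g2 = fit$lambda * fit$sigma2,
         sigma_e2 = (1 - fit$lambda) * fit$sigma2,
         lambda = fit$lambda, sigma2 = fit$sigma2,
         loglik = fit$ll, beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
         flat = fit$flat, n = length(y), p = ncol(X)),
    class = "knob_mlm"
  )
}

check_mlm_dims <- function(y, X) {
  if (any(!is.finite(y))) stop("`y` contains non-finite values")
  if (nrow(X) != length(y)) stop("covariates and y have different lengths")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (length(y) <= ncol(X) + 2L)
    stop("too few entries for the number of covariates")
  invisible(TRUE)
}

#' @export
print.knob_mlm <- function(x, ...) {
  cat("Null mixed linear model (REML)\n")
  cat(sprintf("  sigma_g2 = %.5g, sigma_e2 = %.5g (lambda = %.4f)%s\n",
              x$sigma_g2, x$sigma_e2, x$lambda,
              if (x$flat) " [flat profile]" else ""))
  cat(sprintf("  restricted log-likelihood: %.4f (n = %d, p = %d)\n",
              x$loglik, x$n, x$p))
  invisible(x)
}

#' @export
logLik.knob_mlm <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, class = "logLik")
}

# Single-marker generalized least squares test. If lambda is NULL the
# variance ratio is re-estimated by REML with the marker in the design
# ("exact" mode); otherwise the supplied ratio is held fixed and only the
# total variance is re-profiled (P3D-style "null_once" mode, which reduces
# exactly to OLS when lambda = 0). Returns effect on the code scale plus the
# Wald t test with n - p residual degrees of freedom.
marker_gls <- function(yt, Xt0, code_t, d, lambda = NULL) {
  Xt <- cbind(Xt0, marker = code_t)
  n <- nrow(Xt)
  p <- ncol(Xt)
  fit <- if (is.null(lambda)) reml_optimize(yt, Xt, d) else
    reml_profile(lambda, yt, Xt, d)
  if (!is.finite(fit$ll)) stop("marker design is rank deficient")
  cov_beta <- fit$sigma2 * chol2inv(chol(fit$XtWX))
  effect <- fit$beta[p]
  se <- sqrt(cov_beta[p, p])
  tval <- effect / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(effect = as.numeric(effect), se = as.numeric(se),
       t = as.numeric(tval), p_value = max(pval, .Machine$double.xmin),
       df = n - p, lambda = fit$lambda,
       sigma_g2 = fit$lambda * fit$sigma2,
       sigma_e2 = (1 - fit$lambda) * fit$sigma2)
}

#' Test a single marker in the mixed linear model
#'
#' Generalized least squares estimate and Wald t-test of a marker effect
#' under `V = sigma_g^2 K + sigma_e^2 I`. By default (`lambda = NULL`) the
#' variance components are re-estimated by REML with the marker in the model
#' (exact single-locus MLM); passing a fixed `lambda` (e.g. from
#' [fit_mlm_null()]) gives the faster P3D-style test, and `lambda = 0`
#' reproduces the ordinary least squares t-test exactly. The reported effect
#' is sign-normalized to the knob-presence scale: when the additive encoding
#' counted the absence allele the coefficient is negated.
#'
#' @param y Numeric response (entry BLUEs).
#' @param covariates Optional fixed covariates (intercept added).
#' @param K Kinship matrix.
#' @param code Numeric marker codes (additive 0/1/2 or dominance 0/1).
#' @param lambda `NULL` for exact per-marker REML, or a fixed variance ratio
#'   `sigma_g2 / (sigma_g2 + sigma_e2)` in `[0, 1)`.
#' @param counted_allele `"presence"`, `"absence"` or `NA`; used for sign
#'   normalization of additive effects.
#' @return List with `effect`, `se`, `t`, `p_value`, `df`, `lambda`,
#'   `sigma_g2`, `sigma_e2`, `marker_h2`.
#' @export
test_marker <- function(y, covariates = NULL, K, code, lambda = NULL,
                        counted_allele = NA_character_) {
  if (stats::var(code) == 0) {
    warning("zero-variance marker code; marker skipped")
    return(NULL)
  }
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  check_mlm_dims(y, cbind(X0, code))
  eig <- kinship_eigen(K)
  yt <- crossprod(eig$vectors, y)
  Xt0 <- crossprod(eig$vectors, X0)
  ct <- as.numeric(crossprod(eig$vectors, code))
  res <- marker_gls(yt, Xt0, ct, eig$values, lambda = lambda)
  res$marker_h2 <- stats::var(code) * res$effect^2 / stats::var(y)
  if (identical(counted_allele, "absence")) res$effect <- -res$effect
  res
}
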