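test_that("VanRaden kinship matches the hand-computed single-locus case", {
  g <- knob_matrix(matrix(c(0L, 2L), 2, 1, dimnames = list(c("A", "B"), "K9S")))
  K <- compute_kinship(g)
  # p = 0.5: centered codes (-1, +1), denominator 2 * 0.25 = 0.5
  ridge <- 1e-6 * 2
  expect_equal(unname(diag(K)), rep(2 + ridge, 2), tolerance = 1e-9)
  expect_equal(K["A", "B"], -2, tolerance = 1e-9)
  expect_equal(K, t(K))

  # duplicate entries: off-diagonal equals the shared diagonal (pre-ridge)
  g2 <- random_knob_matrix(6, seed = 2)
  g2[2, ] <- g2[1, ]
  K2 <- compute_kinship(knob_matrix(unclass(g2)))
  eps <- 1e-6 * mean(diag(K2))
  expect_equal(K2[1, 2], K2[1, 1] - eps, tolerance = 1e-9)

  expect_error(compute_kinship(knob_matrix(matrix(2L, 4, 2,
    dimnames = list(paste0("E", 1:4), c("K3L", "K9S"))))), "monomorphic")
  # PSD after ridge
  K3 <- compute_kinship(random_knob_matrix(15, seed = 3))
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("genotype principal components are deterministic and recover low-rank structure", {
  m <- random_knob_matrix(10, seed = 5)
  expect_equal(ncol(compute_pcs(m, 0)), 0)
  p1 <- compute_pcs(m, 2)
  expect_identical(compute_pcs(m, 2), p1)

  # rank-1 matrix: PC1 reproduces the single direction
  base <- c(0L, 2L, 0L, 2L)
  m1 <- matrix(rep(c(0L, 0L, 2L, 2L, 2L, 0L), each = 4), 6, 4, byrow = FALSE)
  m1 <- outer(c(0, 0, 1, 1, 1, 0), c(2, 2, 0, 2)) # rank 1 in centered space
  storage.mode(m1) <- "integer"
  dimnames(m1) <- list(sprintf("E%d", 1:6), knob_loci()$locus)
  pcs <- compute_pcs(knob_matrix(m1), 1)
  expect_equal(abs(cor(pcs[, 1], c(0, 0, 1, 1, 1, 0))), 1, tolerance = 1e-10)
  expect_error(compute_pcs(knob_matrix(m1), 3), "rank")

  # duplicated entries get identical PC rows
  md <- unclass(random_knob_matrix(8, seed = 6))
  md[2, ] <- md[1, ]
  pd <- compute_pcs(knob_matrix(md), 2)
  expect_equal(pd[1, ], pd[2, ], tolerance = 1e-12)
})

test_that("REML optimum dominates the restricted likelihood over random ratios", {
  set.seed(17)
  panel <- generate_panel(generator_params(seed = 17))
  K <- compute_kinship(panel)
  n <- nrow(panel)
  grp <- as.numeric(panel$entry_type == "line")
  X <- cbind(1, grp)
  y <- 65 + 3 * grp + as.numeric(t(chol(K + diag(0.01, n))) %*% rnorm(n)) +
    rnorm(n, 0, 1.5)
  fit <- fit_mlm_null(y, covariates = cbind(grp = grp), K = K)
  lam_hat <- fit$lambda
  ll_hat <- bruteforce_reml_ll(lam_hat, y, X, K)
  # implementation and dense-algebra likelihoods agree at the optimum
  expect_equal(fit$loglik, ll_hat, tolerance = 1e-6)
  for (lam in runif(20, 0, 0.999)) {
    expect_gte(ll_hat + 1e-6, bruteforce_reml_ll(lam, y, X, K))
  }
})

test_that("null variance ratio is recovered when there is no polygenic signal", {
  panel <- generate_panel(generator_params(n_lines = 30, n_hybrids = 70, seed = 23))
  K <- compute_kinship(panel)
  set.seed(23)
  ratios <- replicate(200, {
    y <- rnorm(nrow(panel), 65, 2)
    f <- fit_mlm_null(y, K = K)
    f$sigma_g2 / f$sigma_e2
  })
  expect_gte(mean(ratios < 0.05), 0.95)
})

test_that("identity kinship flags a flat profile and reduces the test to OLS", {
  set.seed(31)
  n <- 20
  m <- random_knob_matrix(n, seed = 31)
  K <- compute_kinship(m, "identity")
  y <- rnorm(n, 60, 2)
  expect_warning(f <- fit_mlm_null(y, K = K), "flat")
  expect_true(f$flat)
  expect_equal(f$sigma_g2, 0)

  code <- suppressWarnings(encode_additive(m))$values[, "K9S"]
  res <- test_marker(y, K = K, code = code)
  ols <- summary(lm(y ~ code))$coefficients["code", ]
  expect_equal(res$effect, unname(ols["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(ols["Std. Error"]), tolerance = 1e-10)
  expect_lt(abs(res$p_value - ols["Pr(>|t|)"]), 1e-10)
})

test_that("a marker identical to the response gives effect 1 and a vanishing p-value", {
  set.seed(37)
  m <- random_knob_matrix(24, seed = 37)
  K <- compute_kinship(m)
  code <- unclass(m)[, "K5L"]
  y <- 50 + as.numeric(code)
  res <- test_marker(y, K = K, code = code)
  expect_equal(res$effect, 1, tolerance = 1e-6)
  expect_lt(res$p_value, 1e-12)
  expect_warning(test_marker(y, K = K, code = rep(1, 24)), "zero-variance")
})

test_that("reported effects are sign-normalized to the knob-presence allele", {
  set.seed(41)
  for (presence_major in c(TRUE, FALSE)) {
    # build a panel where presence is major or minor, inject a negative
    # per-presence-allele effect, and check the reported sign
    counts <- if (presence_major) c(2L, 2L, 2L, 2L, 1L, 1L, 0L, 2L, 2L, 1L,
                                    2L, 2L, 1L, 2L, 0L, 2L)
    else c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 2L, 0L)
    n <- length(counts)
    m <- unclass(random_knob_matrix(n, seed = 43 + presence_major))
    m[, "K9S"] <- counts
    m <- knob_matrix(m)
    enc <- suppressWarnings(encode_additive(m))
    y <- 70 - 0.8 * counts + rnorm(n, 0, 0.3)
    res <- test_marker(y, K = compute_kinship(m),
                       code = enc$values[, "K9S"],
                       counted_allele = enc$counted_allele[["K9S"]])
    expect_lt(res$effect, 0)
    expect_equal(res$effect, -0.8, tolerance = 0.4)
  }
})

test_that("dominance effect equals an indicator regression on hybrid panels", {
  for (seed in c(3, 5, 9)) {
    s <- simulate_knob_study(generator_params(seed = seed))
    b <- compute_blues(s$records, "mf", entries = s$panel$entry_id)
    m <- knob_matrix(s$panel)
    grp <- stats::model.matrix(~factor(s$panel$entry_type))[, -1, drop = FALSE]
    K <- compute_kinship(m, "identity")
    dom <- suppressWarnings(encode_dominance(m))
    j <- which(!dom$excluded)[1]
    res <- test_marker(b$blue, covariates = grp, K = K,
                       code = dom$values[, j])
    ind <- as.numeric(unclass(m)[, j] == 1L)
    fit <- lm(b$blue ~ grp + ind)
    expect_equal(res$effect, unname(coef(fit)["ind"]), tolerance = 1e-10)
  }
})

test_that("scan statistics are invariant to joint row permutation", {
  s <- simulate_knob_study(generator_params(seed = 47))
  b <- compute_blues(s$records, "ff", entries = s$panel$entry_id)
  sc <- suppressWarnings(knob_scan(s$panel, b, trait = "ff"))
  set.seed(1)
  perm <- sample(nrow(s$panel))
  panel_p <- s$panel[perm, ]
  b_p <- b[perm, ]
  sc_p <- suppressWarnings(knob_scan(panel_p, b_p, trait = "ff"))
  # invariance holds to the precision of the 1-D variance-ratio optimizer
  expect_equal(sc_p$results$effect, sc$results$effect, tolerance = 1e-6)
  expect_equal(sc_p$results$p_value, sc$results$p_value, tolerance = 1e-6)
  # with a fixed variance ratio the statistics are invariant to eigen-basis
  # differences at near machine precision
  sc0 <- suppressWarnings(knob_scan(s$panel, b, trait = "ff",
                                    kinship = "identity"))
  sc0_p <- suppressWarnings(knob_scan(panel_p, b_p, trait = "ff",
                                      kinship = "identity"))
  expect_equal(sc0_p$results$p_value, sc0$results$p_value, tolerance = 1e-10)
})

test_that("GLS residuals are orthogonal to the covariates under the fitted V", {
  s <- simulate_knob_study(generator_params(seed = 53))
  b <- compute_blues(s$records, "mf", entries = s$panel$entry_id)
  m <- knob_matrix(s$panel)
  K <- compute_kinship(m)
  grp <- stats::model.matrix(~factor(s$panel$entry_type))[, -1, drop = FALSE]
  enc <- suppressWarnings(encode_additive(m))
  j <- which(!enc$excluded)[1]
  code <- enc$values[, j]
  res <- test_marker(b$blue, covariates = grp, K = K, code = code)
  X <- cbind(1, grp, code)
  V <- res$sigma_g2 * K + res$sigma_e2 * diag(nrow(K))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% b$blue)
  r <- b$blue - X %*% beta
  expect_lt(max(abs(t(X) %*% Vi %*% r)), 1e-8 * max(abs(b$blue)))
})

test_that("the scan orders results and flags uninformative loci", {
  s <- simulate_knob_study(generator_params(seed = 59))
  b <- compute_blues(s$records, "mf", entries = s$panel$entry_id)
  sc <- suppressWarnings(knob_scan(s$panel, b, trait = "mf"))
  expect_s3_class(sc, "knob_scan")
  expect_lte(nrow(sc$results), 8)
  expect_false(is.unsorted(sc$results$chrom[sc$results$encoding == "additive"]))
  expect_named(coef(sc))
  # entry mismatch errors name the offender
  b_bad <- b[-1, ]
  expect_error(suppressWarnings(knob_scan(s$panel, b_bad, trait = "mf")),
               s$panel$entry_id[1])
  # dominance on a line-only panel: no testable marker rows
  p2 <- generator_params(assay = 2, seed = 59)
  s2 <- simulate_knob_study(p2)
  b2 <- compute_blues(s2$records, "mf", entries = s2$panel$entry_id)
  sc2 <- suppressWarnings(knob_scan(s2$panel, b2, trait = "mf",
                                    encoding = "dominance"))
  expect_true(is.null(sc2$results) || nrow(sc2$results) == 0)
})
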