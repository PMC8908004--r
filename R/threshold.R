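#' Phenotype-permutation significance threshold
#'
#' The resampling rule used to declare marker-trait associations: the vector
#' of entry BLUEs is shuffled against the fixed genotype/kinship/covariate
#' structure, the full single-locus scan is re-run, and the best marker score
#' (minimum p-value across markers) is recorded; after `n_perm` rounds the
#' empirical `(1 - level)` quantile of the minimum p-values (equivalently the
#' `level` quantile of the best -log10 p scores) becomes the threshold.
#' Variance components are re-estimated for every permutation. Quantiles use
#' R's type-7 (linear interpolation) convention.
#'
#' @inheritParams knob_scan
#' @param n_perm Number of permutations (>= 10). The classical default of 50
#'   gives a noisy 5% quantile; a warning says so.
#' @param level Quantile level of the best scores (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return Object of class `perm_threshold`: list with `trait`, `encoding`,
#'   `n_perm`, `level`, `best_scores` (per-permutation minimum p-values),
#'   `threshold_p` and `seed`.
#' @examples
#' s <- simulate_knob_study(generator_params(seed = 1))
#' b <- compute_blues(s$records, "ff", entries = s$panel$entry_id)
#' thr <- suppressWarnings(
#'   permutation_threshold(s$panel, b, trait = "ff", encoding = "additive",
#'                         n_perm = 20, seed = 1)
#' )
#' @export
permutation_threshold <- function(genotypes, blues, trait = NULL,
                                  encoding = c("additive", "dominance"),
                                  kinship = c("vanraden", "identity"),
                                  n_pcs = 0, structure = c("auto", "none"),
                                  vc_mode = c("exact", "null_once"),
                                  n_perm = 50, level = 0.95, seed = 1L) {
  vc_mode <- match.arg(vc_mode)
  if (n_perm < 10) stop("`n_perm` must be >= 10")
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  if (n_perm < 100)
    warning(sprintf(
      "n_perm = %d gives a noisy %.0f%% quantile; consider n_perm >= 200",
      n_perm, 100 * (1 - level)))
  prep <- scan_prep(genotypes, blues, trait = trait, encoding = encoding,
                    kinship = kinship, n_pcs = n_pcs, structure = structure)
  n_markers <- sum(vapply(prep$enc, function(e) sum(!e$excluded), 0L))
  if (n_markers < 1L) stop("no polymorphic marker to permute")

  n <- length(prep$y)
  set.seed(substream_seed(seed, "permutation"))
  best <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- prep$y[sample.int(n)]
    ypt <- crossprod(prep$eig$vectors, yp)
    res <- scan_core(prep, ypt, yp, vc_mode = vc_mode)
    best[b] <- min(res$p_value)
  }
  structure(
    list(trait = prep$trait, encoding = names(prep$enc),
         n_perm = as.integer(n_perm), level = level,
         best_scores = best,
         threshold_p = stats::quantile(best, probs = 1 - level, type = 7,
                                       names = FALSE),
         seed = as.integer(seed)),
    class = "perm_threshold"
  )
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation threshold (%s; %s): p <= %.4g\n  %d permutations, %.0f%% quantile of best scores, seed %d\n",
    if (is.na(x$trait)) "trait?" else x$trait,
    paste(x$encoding, collapse = "+"),
    x$threshold_p, x$n_perm, 100 * x$level, x$seed))
  invisible(x)
}

#' Annotate scan results with a permutation threshold
#'
#' Fills the `significant` column: a marker is declared significant when its
#' p-value is less than or equal to the threshold (boundary ties count as
#' significant). The report must match the scan's trait and cover its
#' encodings.
#'
#' @param results A `knob_scan` object or its `results` data frame.
#' @param report A [permutation_threshold()] report.
#' @return The input, with `significant` filled (and the report attached when
#'   a `knob_scan` object was given).
#' @export
apply_threshold <- function(results, report) {
  stopifnot(inherits(report, "perm_threshold"))
  is_scan <- inherits(results, "knob_scan")
  df <- if (is_scan) results$results else results
  if (is.null(df) || nrow(df) == 0L) {
    if (is_scan) {
      results$threshold <- report
      return(results)
    }
    return(df)
  }
  if (is_scan && !is.na(results$trait) && !is.na(report$trait) &&
      !identical(results$trait, report$trait))
    stop(sprintf("trait mismatch: scan is %s, threshold is %s",
                 results$trait, report$trait))
  if (!all(unique(df$encoding) %in% report$encoding))
    stop("threshold report does not cover encodings: ",
         paste(setdiff(unique(df$encoding), report$encoding), collapse = ", "))
  df$significant <- df$p_value <= report$threshold_p
  if (is_scan) {
    results$results <- df
    results$threshold <- report
    return(results)
  }
  df
}
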