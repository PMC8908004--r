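trait_column <- function(trait) {
  trait <- match.arg(tolower(trait), c("mf", "ff", "gs"))
  c(mf = "mf_days", ff = "ff_days", gs = "gs_pg")[[trait]]
}

#' Entry BLUEs from replicate-level records
#'
#' Under a completely randomized design with homoscedastic errors the best
#' linear unbiased estimate of an entry mean is its arithmetic replicate
#' mean; that design is assumed here.
#'
#' @param records Plant-record data frame (`entry_id`, `replicate`, trait
#'   columns `mf_days`, `ff_days`, `gs_pg`).
#' @param trait One of `"mf"`, `"ff"`, `"gs"`.
#' @param entries Optional entry ordering (e.g. the genotype panel's
#'   `entry_id`); every requested entry must have records.
#' @return Data frame `entry_id`, `trait`, `blue`, `n_reps`.
#' @examples
#' s <- simulate_knob_study(generator_params(seed = 1))
#' head(compute_blues(s$records, "mf", entries = s$panel$entry_id))
#' @export
compute_blues <- function(records, trait, entries = NULL) {
  col <- trait_column(trait)
  if (!col %in% names(records)) stop("records lack column ", col)
  y <- records[[col]]
  if (any(!is.finite(y))) stop("non-finite phenotypes in column ", col)
  means <- tapply(y, records$entry_id, mean)
  reps <- tapply(y, records$entry_id, length)
  ids <- names(means)
  if (!is.null(entries)) {
    miss <- setdiff(entries, ids)
    if (length(miss))
      stop("entries without phenotype records: ", paste(miss, collapse = ", "))
    ids <- entries
  }
  data.frame(
    entry_id = ids,
    trait = toupper(trait),
    blue = as.numeric(means[ids]),
    n_reps = as.integer(reps[ids]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Entry-mean heritability by one-way random-effects REML
#'
#' Fits `phenotype ~ (group +) (1 | entry)` by restricted maximum likelihood
#' and reports the entry-mean heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / r_eff)`, with `r_eff` the
#' harmonic mean of the per-entry replicate counts. An optional group fixed
#' effect (typically line vs hybrid) keeps heterosis — a group mean shift,
#' not variance among entries — out of the genetic variance.
#'
#' @param records Plant-record data frame.
#' @param trait One of `"mf"`, `"ff"`, `"gs"`.
#' @param groups Optional group fixed effect: a `knob_panel` (its
#'   `entry_type` is used) or a named vector mapping entry ids to groups.
#' @return Object of class `knob_h2`: list with `h2`, `sigma_g2`, `sigma_e2`,
#'   `r_eff`, `n_entries`, `n_records`, `trait`.
#' @examples
#' s <- simulate_knob_study(generator_params(seed = 1))
#' estimate_heritability(s$records, "mf", groups = s$panel)
#' @export
estimate_heritability <- function(records, trait, groups = NULL) {
  col <- trait_column(trait)
  y <- records[[col]]
  entry <- factor(records$entry_id)
  reps <- table(entry)
  if (nlevels(entry) < 2L) stop("need at least 2 entries")
  if (all(reps == 1L))
    stop("all entries have a single replicate; residual variance is unidentifiable")

  r_eff <- length(reps) / sum(1 / as.numeric(reps))
  # Degenerate case lmer cannot fit: replicates identical within every entry.
  within_ss <- sum(tapply(y, entry, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    means <- tapply(y, entry, mean)
    sg <- stats::var(as.numeric(means))
    return(structure(
      list(h2 = if (sg > 0) 1 else 0, sigma_g2 = sg, sigma_e2 = 0,
           r_eff = r_eff, n_entries = nlevels(entry), n_records = length(y),
           trait = toupper(trait)),
      class = "knob_h2"
    ))
  }

  df <- data.frame(y = y, entry = entry)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      map <- stats::setNames(groups$entry_type, groups$entry_id)
    } else {
      map <- groups
    }
    df$grp <- factor(map[as.character(df$entry)])
    if (anyNA(df$grp)) stop("`groups` does not cover all entries")
    form <- if (nlevels(droplevels(df$grp)) > 1L)
      y ~ grp + (1 | entry) else y ~ (1 | entry)
  } else {
    form <- y ~ (1 | entry)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = TRUE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_g2 <- vc$vcov[vc$grp == "entry"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  denom <- sigma_g2 + sigma_e2 / r_eff
  h2 <- if (denom > 0) sigma_g2 / denom else 0
  structure(
    list(h2 = h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, r_eff = r_eff,
         n_entries = nlevels(entry), n_records = length(y),
         trait = toupper(trait)),
    class = "knob_h2"
  )
}

#' @export
print.knob_h2 <- function(x, ...) {
  cat(sprintf(
    "Entry-mean heritability (%s): h2 = %.3f\n  sigma_g2 = %.4g, sigma_e2 = %.4g, r_eff = %.2f (%d entries, %d plants)\n",
    x$trait, x$h2, x$sigma_g2, x$sigma_e2, x$r_eff, x$n_entries, x$n_records))
  invisible(x)
}

#' 2C genome size from flow-cytometry peak means
#'
#' Ratio of the sample and internal-standard G0/G1 fluorescence peak means,
#' scaled by the standard's known 2C DNA content. The standard's 2C value
#' (e.g. for the maize reference line CE-777) must be supplied by the user.
#'
#' @param sample_peak_mean,standard_peak_mean Fluorescence peak means (a.u.).
#' @param standard_2c_pg 2C DNA content of the internal standard, pg.
#' @return Sample 2C genome size in pg.
#' @examples
#' genome_size_from_peaks(206, 200, 5.43)
#' @export
genome_size_from_peaks <- function(sample_peak_mean, standard_peak_mean,
                                   standard_2c_pg) {
  if (any(!is.finite(sample_peak_mean)) || any(sample_peak_mean <= 0) ||
      any(!is.finite(standard_peak_mean)) || any(standard_peak_mean <= 0) ||
      any(!is.finite(standard_2c_pg)) || any(standard_2c_pg <= 0))
    stop("peak means and the standard 2C value must all be positive")
  sample_peak_mean / standard_peak_mean * standard_2c_pg
}

#' Convert a 2C DNA mass to megabase pairs
#'
#' Uses the standard conversion 1 pg = 978 Mbp and rounds half up to the
#' nearest integer megabase (5.6 pg -> 5477 Mbp, 5.4 pg -> 5281 Mbp).
#'
#' @param pg DNA content in picograms (>= 0).
#' @return Integer Mbp.
#' @examples
#' pg_to_mbp(c(5.6, 5.4))
#' @export
pg_to_mbp <- function(pg) {
  if (any(is.na(pg)) || any(pg < 0)) stop("`pg` must be non-negative")
  as.integer(floor(pg * 978 + 0.5))
}

#' Pairwise trait/dosage Pearson correlations
#'
#' Correlations among female flowering, male flowering, genome size and knob
#' dosage class on entry-level values, in the layout of the classical
#' trait-by-knob correlation table. Pairs involving a zero-variance vector
#' are reported as `NA`, not 0.
#'
#' @param ff,mf,gs Entry-level BLUEs (same ordering).
#' @param dosage Entry dosage classes (same ordering).
#' @return A 4x4 symmetric correlation matrix with dimnames
#'   `FF`, `MF`, `GS`, `dosage`.
#' @export
trait_correlations <- function(ff, mf, gs, dosage) {
  v <- list(FF = ff, MF = mf, GS = gs, dosage = as.numeric(dosage))
  n <- lengths(v)
  if (length(unique(n)) != 1L) stop("all vectors must have the same length")
  if (n[1] < 3L) stop("need at least 3 entries")
  k <- length(v)
  out <- matrix(NA_real_, k, k, dimnames = list(names(v), names(v)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (stats::sd(v[[i]]) == 0 || stats::sd(v[[j]]) == 0) {
      out[i, j] <- if (i == j) NA_real_ else NA_real_
    } else {
      out[i, j] <- stats::cor(v[[i]], v[[j]])
    }
  }
  out
}

#' Per-group summary statistics
#'
#' Mean, SD and quartiles per group and trait. Quartiles use the
#' inclusive-median convention (R's default type-7 quantiles), so the median
#' of 1..5 is 3.
#'
#' @param records Plant-record data frame.
#' @param groups Named vector mapping entry ids to groups, or a `knob_panel`
#'   (its `entry_type` is used).
#' @return Data frame: `group`, `trait`, `n`, `mean`, `sd`, `q1`, `median`, `q3`.
#' @export
group_summaries <- function(records, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$entry_type, groups$entry_id)
  grp <- groups[as.character(records$entry_id)]
  if (anyNA(grp)) stop("`groups` does not cover all entries in `records`")
  out <- list()
  for (tr in c("mf", "ff", "gs")) {
    y <- records[[trait_column(tr)]]
    for (g in sort(unique(grp))) {
      yy <- y[grp == g]
      q <- stats::quantile(yy, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, trait = toupper(tr), n = length(yy),
        mean = mean(yy), sd = if (length(yy) > 1L) stats::sd(yy) else 0,
        q1 = q[1], median = q[2], q3 = q[3],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
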