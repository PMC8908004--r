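#' Default knob locus panel
#'
#' The four variable heterochromatic knob loci used throughout the package,
#' named by the field convention K + chromosome + arm (S short, L long).
#'
#' @return A data frame with columns `locus`, `chrom` (integer 1-10) and
#'   `arm` (`"short"` or `"long"`).
#' @examples
#' knob_loci()
#' @export
knob_loci <- function() {
  data.frame(
    locus = c("K3L", "K5L", "K7S", "K9S"),
    chrom = c(3L, 5L, 7L, 9L),
    arm = c("long", "long", "short", "short"),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters for a knob panel study
#'
#' Bundles every knob of the synthetic-data generator: panel composition,
#' replicate design, group means, causal-locus effects, heritabilities and
#' noise structure. Defaults reproduce the assay-1 study conditions: 8 inbred
#' lines (3 replicates) plus 35 hybrids (5 replicates), hybrids flowering
#' about a week earlier than lines, a single causal locus at K9S with additive
#' effects of -0.45 (MF) and -0.51 (FF) days per knob-presence allele and
#' heterozygote effects of -1.40/-1.53 days, entry-mean heritabilities of
#' 0.51 (MF), 0.41 (FF) and 0.26 (genome size), and a null knob effect on
#' genome size. `assay = 2` switches to 20 lines with 5 replicates and no
#' hybrids.
#'
#' @param assay Preset, 1 or 2; fills `n_lines`, `n_hybrids`, `reps_line`
#'   unless given explicitly.
#' @param n_lines,n_hybrids Panel composition (entries).
#' @param reps_line,reps_hybrid Replicate plants per entry.
#' @param n_self_generations Selfing depth used to fix line genotypes.
#' @param mu_mf_line,mu_ff_line,mu_mf_hybrid,mu_ff_hybrid Group mean flowering
#'   times, days from planting.
#' @param a_mf,a_ff Additive effect per knob-presence allele at the causal
#'   locus, days.
#' @param d_mf,d_ff Extra effect of heterozygosity at the causal locus, days.
#' @param h2_mf,h2_ff,h2_gs Target entry-mean heritabilities in `[0, 1)`.
#' @param rho_g Genetic correlation between the MF and FF entry effects.
#' @param rho_e Residual (within-plant) correlation between MF and FF.
#' @param sigma_e_mf,sigma_e_ff Plant-level residual SD, days.
#' @param sigma_e_gs Plant-level residual SD for genome size, pg.
#' @param mu_gs_line,mu_gs_hybrid Group mean 2C genome sizes, pg.
#' @param gs_knob_effect Genome-size effect per knob-presence allele, pg
#'   (default 0: knobs do not move genome size).
#' @param causal_locus Locus carrying the flowering-time effects.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `generator_params` (a validated named list).
#' @examples
#' p <- generator_params()
#' p2 <- generator_params(assay = 2)
#' @export
generator_params <- function(assay = 1,
                             n_lines = NULL,
                             n_hybrids = NULL,
                             reps_line = NULL,
                             reps_hybrid = 5,
                             n_self_generations = 9,
                             mu_mf_line = 70, mu_ff_line = 72,
                             mu_mf_hybrid = 63, mu_ff_hybrid = 64,
                             a_mf = -0.45, a_ff = -0.51,
                             d_mf = -1.40, d_ff = -1.53,
                             h2_mf = 0.51, h2_ff = 0.41, h2_gs = 0.26,
                             rho_g = 0.95, rho_e = 0.70,
                             sigma_e_mf = 2.5, sigma_e_ff = 2.5,
                             sigma_e_gs = 0.10,
                             mu_gs_line = 5.4, mu_gs_hybrid = 5.6,
                             gs_knob_effect = 0,
                             causal_locus = "K9S",
                             seed = 1L) {
  if (!assay %in% c(1, 2)) stop("`assay` must be 1 or 2")
  if (is.null(n_lines)) n_lines <- if (assay == 1) 8L else 20L
  if (is.null(n_hybrids)) n_hybrids <- if (assay == 1) 35L else 0L
  if (is.null(reps_line)) reps_line <- if (assay == 1) 3L else 5L

  p <- list(
    assay = as.integer(assay),
    n_lines = as.integer(n_lines), n_hybrids = as.integer(n_hybrids),
    reps_line = as.integer(reps_line), reps_hybrid = as.integer(reps_hybrid),
    n_self_generations = as.integer(n_self_generations),
    mu_mf_line = mu_mf_line, mu_ff_line = mu_ff_line,
    mu_mf_hybrid = mu_mf_hybrid, mu_ff_hybrid = mu_ff_hybrid,
    a_mf = a_mf, a_ff = a_ff, d_mf = d_mf, d_ff = d_ff,
    h2_mf = h2_mf, h2_ff = h2_ff, h2_gs = h2_gs,
    rho_g = rho_g, rho_e = rho_e,
    sigma_e_mf = sigma_e_mf, sigma_e_ff = sigma_e_ff,
    sigma_e_gs = sigma_e_gs,
    mu_gs_line = mu_gs_line, mu_gs_hybrid = mu_gs_hybrid,
    gs_knob_effect = gs_knob_effect,
    causal_locus = causal_locus,
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  class(p) <- "generator_params"
  p
}

validate_generator_params <- function(p) {
  stopifnot(is.list(p))
  if (p$n_lines < 1L) stop("`n_lines` must be >= 1")
  if (p$n_hybrids < 0L) stop("`n_hybrids` must be >= 0")
  if (p$reps_line < 1L || p$reps_hybrid < 1L)
    stop("replicate counts must be >= 1")
  if (p$n_self_generations < 1L) stop("`n_self_generations` must be >= 1")
  for (h in c("h2_mf", "h2_ff", "h2_gs")) {
    v <- p[[h]]
    if (!is.finite(v) || v < 0 || v >= 1)
      stop(sprintf("`%s` must lie in [0, 1); got %s", h, format(v)))
  }
  for (r in c("rho_g", "rho_e")) {
    v <- p[[r]]
    if (!is.finite(v) || abs(v) > 1)
      stop(sprintf("`%s` must lie in [-1, 1]", r))
  }
  for (s in c("sigma_e_mf", "sigma_e_ff", "sigma_e_gs")) {
    if (!is.finite(p[[s]]) || p[[s]] <= 0)
      stop(sprintf("`%s` must be positive", s))
  }
  if (!p$causal_locus %in% knob_loci()$locus)
    stop("`causal_locus` must be one of ", paste(knob_loci()$locus, collapse = ", "))
  if (is.na(p$seed) || p$seed < 0L) stop("`seed` must be a non-negative integer")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Knob panel generator parameters (assay ", x$assay, ")\n", sep = "")
  cat(sprintf("  panel: %d lines x %d reps, %d hybrids x %d reps\n",
              x$n_lines, x$reps_line, x$n_hybrids, x$reps_hybrid))
  cat(sprintf("  causal locus %s: additive %.2f/%.2f d, dominance %.2f/%.2f d (MF/FF)\n",
              x$causal_locus, x$a_mf, x$a_ff, x$d_mf, x$d_ff))
  cat(sprintf("  h2 MF/FF/GS: %.2f/%.2f/%.2f; rho_g %.2f, rho_e %.2f\n",
              x$h2_mf, x$h2_ff, x$h2_gs, x$rho_g, x$rho_e))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic per-stage seed derived from the single top-level seed, so that
# no stage consumes another stage's stream.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
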