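#' Simulate descendants of a selfing pedigree
#'
#' Propagates a founder genotype through `n_generations` of self-fertilization
#' with independent Mendelian segregation per locus: a heterozygous locus
#' transmits 0, 1 or 2 knob-presence alleles with probability 1/4, 1/2, 1/4;
#' homozygous loci are absorbing. Each lineage follows single-seed descent.
#'
#' @param founder Integer vector of knob-presence allele counts (0/1/2), one
#'   per locus; names are kept as locus labels.
#' @param n_generations Number of selfing generations (>= 1).
#' @param n_lineages Number of independent lineages to simulate.
#' @return Integer matrix, `n_lineages` x `length(founder)`.
#' @examples
#' set.seed(1)
#' g <- simulate_selfing(c(K3L = 1, K9S = 1), n_generations = 9, n_lineages = 10)
#' @export
simulate_selfing <- function(founder, n_generations, n_lineages = 1L) {
  founder <- check_counts(founder, "founder")
  if (length(n_generations) != 1L || is.na(n_generations) || n_generations < 1)
    stop("`n_generations` must be a single integer >= 1")
  if (n_lineages < 1) stop("`n_lineages` must be >= 1")
  G <- matrix(rep(as.integer(founder), each = n_lineages),
              nrow = n_lineages,
              dimnames = list(NULL, names(founder)))
  for (g in seq_len(n_generations)) {
    het <- which(G == 1L)
    if (length(het) == 0L) break
    G[het] <- sample(c(0L, 1L, 2L), length(het), replace = TRUE,
                     prob = c(0.25, 0.5, 0.25))
  }
  G
}

#' Cross two fixed inbred lines
#'
#' Offspring receive one gamete per parent; because both parents are required
#' to be fully homozygous, the offspring count at each locus is simply the
#' mean of the parental counts (opposite homozygotes give a heterozygote).
#'
#' @param parent1,parent2 Integer vectors of counts in \{0, 2\} (no
#'   heterozygous loci allowed).
#' @return Integer vector of offspring counts.
#' @examples
#' make_hybrid(c(K9S = 2), c(K9S = 0))  # heterozygous knob
#' @export
make_hybrid <- function(parent1, parent2) {
  parent1 <- check_counts(parent1, "parent1")
  parent2 <- check_counts(parent2, "parent2")
  if (length(parent1) != length(parent2))
    stop("parents must cover the same loci")
  if (any(parent1 == 1L) || any(parent2 == 1L))
    stop("parents must be fixed (no heterozygous locus); self the lines first")
  as.integer((parent1 + parent2) / 2L)
}

check_counts <- function(x, what) {
  if (is.null(x) || length(x) == 0L)
    stop(sprintf("`%s` must contain at least one locus", what))
  if (any(is.na(x)) || !all(x %in% c(0, 1, 2)))
    stop(sprintf("`%s` must contain allele counts in {0, 1, 2}", what))
  storage.mode(x) <- "integer"
  x
}

#' Generate a knob genotype panel
#'
#' Draws inbred-line genotypes by selfing a fully heterozygous founder for
#' `n_self_generations` generations and sampling fixed lineages without
#' replacement, then derives hybrids by crossing sampled ordered pairs of
#' distinct lines (reciprocal crosses count as distinct pairs). Reproducible
#' from `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return A `knob_panel` data frame with columns `entry_id`, `entry_type`
#'   (`"line"`/`"hybrid"`), `parent1`, `parent2`, and one 0/1/2 column per
#'   knob locus.
#' @examples
#' panel <- generate_panel(generator_params(seed = 42))
#' table(panel$entry_type)
#' @export
generate_panel <- function(params) {
  validate_generator_params(params)
  set.seed(substream_seed(params$seed, "panel"))
  loci <- knob_loci()
  founder <- stats::setNames(rep(1L, nrow(loci)), loci$locus)

  n_lines <- params$n_lines
  pool <- max(8L * n_lines, 128L)
  lineages <- simulate_selfing(founder, params$n_self_generations, pool)
  fixed <- which(rowSums(lineages == 1L) == 0L)
  if (length(fixed) < n_lines)
    stop(sprintf(paste0("could not obtain %d fixed lines after %d selfing ",
                        "generations; increase `n_self_generations`"),
                 n_lines, params$n_self_generations))
  line_geno <- lineages[sample(fixed, n_lines), , drop = FALSE]
  line_ids <- sprintf("L%02d", seq_len(n_lines))

  panel <- data.frame(
    entry_id = line_ids,
    entry_type = "line",
    parent1 = NA_character_,
    parent2 = NA_character_,
    stringsAsFactors = FALSE
  )
  panel <- cbind(panel, as.data.frame(line_geno))

  if (params$n_hybrids > 0L) {
    pairs <- expand.grid(p1 = seq_len(n_lines), p2 = seq_len(n_lines))
    pairs <- pairs[pairs$p1 != pairs$p2, , drop = FALSE]
    if (params$n_hybrids > nrow(pairs))
      stop(sprintf("cannot draw %d hybrids from %d distinct ordered line pairs",
                   params$n_hybrids, nrow(pairs)))
    take <- pairs[sample(nrow(pairs), params$n_hybrids), , drop = FALSE]
    hyb_geno <- t(mapply(function(i, j) make_hybrid(line_geno[i, ], line_geno[j, ]),
                         take$p1, take$p2))
    colnames(hyb_geno) <- colnames(line_geno)
    hyb <- data.frame(
      entry_id = sprintf("H%02d", seq_len(params$n_hybrids)),
      entry_type = "hybrid",
      parent1 = line_ids[take$p1],
      parent2 = line_ids[take$p2],
      stringsAsFactors = FALSE
    )
    panel <- rbind(panel, cbind(hyb, as.data.frame(hyb_geno)))
  }
  rownames(panel) <- NULL
  class(panel) <- c("knob_panel", "data.frame")
  panel
}

# Pooled within-group variance of a vector of entry-level values; the genetic
# variance a one-way model with a group fixed effect would see.
within_group_var <- function(x, group) {
  group <- as.factor(group)
  n <- length(x)
  g <- nlevels(droplevels(group))
  if (n <= g) return(0)
  ss <- sum(tapply(x, group, function(v) sum((v - mean(v))^2)))
  ss / (n - g)
}

#' Simulate replicate-level phenotypes for a panel
#'
#' For each entry, a genetic value per trait is built from the group mean
#' (line vs hybrid), the causal-locus contribution (additive + heterozygote
#' effect at `params$causal_locus` for flowering; dosage effect for genome
#' size), and a polygenic deviate. The polygenic variance is calibrated so
#' that the total within-group genetic variance (polygenic + realized
#' causal-marker variance) yields the target entry-mean heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / r_eff)` with `r_eff` the
#' harmonic-mean replicate count; the marker share is floored at the target.
#' MF/FF polygenic deviates are bivariate with correlation `rho_g`; plant
#' residuals for MF/FF are bivariate with correlation `rho_e` (both traits
#' are scored on the same plant).
#'
#' @param panel A `knob_panel` data frame from [generate_panel()].
#' @param params A [generator_params()] object.
#' @return A data frame of plant records: `plant_id`, `entry_id`, `replicate`,
#'   `mf_days`, `ff_days`, `gs_pg`.
#' @examples
#' p <- generator_params(seed = 7)
#' recs <- simulate_phenotypes(generate_panel(p), p)
#' nrow(recs)  # 8*3 + 35*5 = 199
#' @export
simulate_phenotypes <- function(panel, params) {
  validate_generator_params(params)
  if (nrow(panel) == 0L) stop("`panel` must be non-empty")
  set.seed(substream_seed(params$seed, "phenotypes"))

  type <- panel$entry_type
  reps <- ifelse(type == "line", params$reps_line, params$reps_hybrid)
  r_eff <- length(reps) / sum(1 / reps)

  x <- panel[[params$causal_locus]]
  if (is.null(x)) stop("panel lacks the causal locus column ", params$causal_locus)
  z <- as.numeric(x == 1L)
  dosage <- rowSums(panel[, intersect(knob_loci()$locus, names(panel)), drop = FALSE])

  m_mf <- params$a_mf * x + params$d_mf * z
  m_ff <- params$a_ff * x + params$d_ff * z
  m_gs <- params$gs_knob_effect * dosage

  sigma_u <- function(h2, sigma_e, m) {
    target <- if (h2 > 0) h2 / (1 - h2) * sigma_e^2 / r_eff else 0
    sqrt(max(0, target - within_group_var(m, type)))
  }
  su_mf <- sigma_u(params$h2_mf, params$sigma_e_mf, m_mf)
  su_ff <- sigma_u(params$h2_ff, params$sigma_e_ff, m_ff)
  su_gs <- sigma_u(params$h2_gs, params$sigma_e_gs, m_gs)

  n <- nrow(panel)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  u_mf <- su_mf * z1
  u_ff <- su_ff * (params$rho_g * z1 + sqrt(1 - params$rho_g^2) * z2)
  u_gs <- su_gs * stats::rnorm(n)

  mu_mf <- ifelse(type == "line", params$mu_mf_line, params$mu_mf_hybrid)
  mu_ff <- ifelse(type == "line", params$mu_ff_line, params$mu_ff_hybrid)
  mu_gs <- ifelse(type == "line", params$mu_gs_line, params$mu_gs_hybrid)

  g_mf <- mu_mf + m_mf + u_mf
  g_ff <- mu_ff + m_ff + u_ff
  g_gs <- mu_gs + m_gs + u_gs

  idx <- rep(seq_len(n), times = reps)
  nrec <- length(idx)
  e1 <- stats::rnorm(nrec); e2 <- stats::rnorm(nrec)
  e_mf <- params$sigma_e_mf * e1
  e_ff <- params$sigma_e_ff * (params$rho_e * e1 + sqrt(1 - params$rho_e^2) * e2)
  e_gs <- params$sigma_e_gs * stats::rnorm(nrec)

  replicate <- unlist(lapply(reps, seq_len), use.names = FALSE)
  out <- data.frame(
    plant_id = sprintf("%s_r%d", panel$entry_id[idx], replicate),
    entry_id = panel$entry_id[idx],
    replicate = replicate,
    mf_days = g_mf[idx] + e_mf,
    ff_days = g_ff[idx] + e_ff,
    gs_pg = g_gs[idx] + e_gs,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate a complete knob study
#'
#' Convenience wrapper: genotype panel plus replicate-level phenotypes.
#'
#' @param params A [generator_params()] object.
#' @return List with elements `panel` and `records`.
#' @export
simulate_knob_study <- function(params = generator_params()) {
  panel <- generate_panel(params)
  list(panel = panel, records = simulate_phenotypes(panel, params))
}
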