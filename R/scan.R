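# Shared preparation for scans and permutation thresholds: aligned response,
# fixed covariate block, kinship eigendecomposition and per-encoding codes.
scan_prep <- function(genotypes, blues, trait = NULL,
                      encoding = c("additive", "dominance"),
                      kinship = c("vanraden", "identity"),
                      n_pcs = 0, structure = c("auto", "none")) {
  kinship <- match.arg(kinship)
  structure <- match.arg(structure)
  encoding <- match.arg(encoding, several.ok = TRUE)

  m <- knob_matrix(genotypes)
  entry_type <- NULL
  if (is.data.frame(genotypes) && "entry_type" %in% names(genotypes))
    entry_type <- stats::setNames(genotypes$entry_type, genotypes$entry_id)

  # Response: named vector, or an EntryMeans data frame (optionally filtered
  # by trait).
  if (is.data.frame(blues)) {
    b <- blues
    if (!is.null(trait) && "trait" %in% names(b))
      b <- b[b$trait == toupper(trait), , drop = FALSE]
    if (is.null(trait) && "trait" %in% names(b) && length(unique(b$trait)) > 1L)
      stop("`blues` contains several traits; pass `trait`")
    if (is.null(trait) && "trait" %in% names(b)) trait <- unique(b$trait)
    y <- stats::setNames(b$blue, b$entry_id)
  } else {
    y <- blues
    if (is.null(names(y))) {
      if (length(y) != nrow(m)) stop("unnamed `blues` must match the panel length")
      names(y) <- rownames(m)
    }
  }
  miss <- setdiff(rownames(m), names(y))
  extra <- setdiff(names(y), rownames(m))
  if (length(miss) || length(extra))
    stop("entry mismatch between genotypes and BLUEs; missing BLUEs: [",
         paste(miss, collapse = ", "), "]; unknown entries: [",
         paste(extra, collapse = ", "), "]")
  y <- as.numeric(y[rownames(m)])

  covariates <- NULL
  if (structure == "auto" && !is.null(entry_type)) {
    grp <- factor(entry_type[rownames(m)])
    if (nlevels(droplevels(grp)) > 1L) {
      covariates <- stats::model.matrix(~grp)[, -1, drop = FALSE]
      colnames(covariates) <- paste0("type_", levels(grp)[-1])
    }
  }
  if (n_pcs > 0) covariates <- cbind(covariates, compute_pcs(m, n_pcs))

  K <- compute_kinship(m, method = kinship)
  eig <- kinship_eigen(K)
  X0 <- cbind(`(Intercept)` = rep(1, nrow(m)), covariates)
  check_mlm_dims(y, X0)

  enc <- list()
  if ("additive" %in% encoding) enc$additive <- encode_additive(m)
  if ("dominance" %in% encoding) enc$dominance <- encode_dominance(m)

  list(m = m, y = y, trait = if (is.null(trait)) NA_character_ else toupper(trait),
       X0 = X0, K = K, eig = eig, enc = enc,
       yt = crossprod(eig$vectors, y),
       Xt0 = crossprod(eig$vectors, X0),
       enc_t = lapply(enc, function(e) crossprod(eig$vectors, e$values)),
       kinship_mode = kinship, n_pcs = n_pcs, structure = structure)
}

# Run all marker tests for a prepared scan on (possibly permuted) rotated y.
scan_core <- function(prep, yt, y, vc_mode = c("exact", "null_once")) {
  vc_mode <- match.arg(vc_mode)
  d <- prep$eig$values
  lambda_fix <- NULL
  if (vc_mode == "null_once")
    lambda_fix <- reml_optimize(yt, prep$Xt0, d)$lambda
  loci_tab <- attr(prep$m, "loci")
  var_y <- stats::var(y)
  rows <- list()
  for (model in names(prep$enc)) {
    e <- prep$enc[[model]]
    for (j in seq_len(ncol(e$values))) {
      if (e$excluded[j]) next
      res <- marker_gls(yt, prep$Xt0, prep$enc_t[[model]][, j], d,
                        lambda = lambda_fix)
      eff <- res$effect
      if (identical(unname(e$counted_allele[j]), "absence")) eff <- -eff
      rows[[length(rows) + 1L]] <- data.frame(
        locus = colnames(e$values)[j],
        chrom = loci_tab$chrom[j],
        arm = loci_tab$arm[j],
        encoding = model,
        freq = unname(e$freq[j]),
        freq_type = if (model == "additive") "maf" else "het",
        effect = eff,
        se = res$se,
        p_value = res$p_value,
        marker_h2 = stats::var(e$values[, j]) * res$effect^2 / var_y,
        lambda = res$lambda,
        significant = NA,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$encoding, out$chrom), , drop = FALSE]
}

#' Single-locus mixed-model scan of the knob panel
#'
#' Fits the mixed linear model `y = S alpha + P beta + K u + e` marker by
#' marker: the response is the vector of entry BLUEs, `S` the encoded marker
#' column, `P` optional structure covariates (a line-vs-hybrid indicator by
#' default when the panel contains both, plus optional genotype PCs), and
#' `u ~ N(0, K sigma_g^2)` a polygenic effect with marker-derived kinship.
#' Effects are reported per knob-presence allele (additive) or per
#' heterozygote (dominance), with Wald t tests on `n - p` residual degrees
#' of freedom. Monomorphic (or heterozygote-free, for dominance) loci are
#' excluded with a warning.
#'
#' @param genotypes A `knob_panel` data frame or knob matrix.
#' @param blues Named numeric vector of entry BLUEs, or a [compute_blues()]
#'   data frame.
#' @param trait Trait label (`"mf"`, `"ff"`, `"gs"`); required when `blues`
#'   holds several traits.
#' @param encoding Character vector, subset of
#'   `c("additive", "dominance")`.
#' @param kinship `"vanraden"` or `"identity"`.
#' @param n_pcs Number of genotype principal components to include.
#' @param structure `"auto"` (line-vs-hybrid indicator when available) or
#'   `"none"`.
#' @param vc_mode `"exact"` re-estimates variance components per marker;
#'   `"null_once"` fixes the variance ratio at the null-model REML estimate
#'   and re-profiles only the total variance (P3D-style).
#' @return Object of class `knob_scan` with a `results` data frame
#'   (locus, chrom, arm, encoding, freq, effect, se, p_value, marker_h2,
#'   significant), the null-model variance components, and the model
#'   specification. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' s <- simulate_knob_study(generator_params(seed = 1))
#' b <- compute_blues(s$records, "ff", entries = s$panel$entry_id)
#' sc <- knob_scan(s$panel, b, trait = "ff", encoding = "additive")
#' sc
#' @export
knob_scan <- function(genotypes, blues, trait = NULL,
                      encoding = c("additive", "dominance"),
                      kinship = c("vanraden", "identity"),
                      n_pcs = 0, structure = c("auto", "none"),
                      vc_mode = c("exact", "null_once")) {
  vc_mode <- match.arg(vc_mode)
  prep <- scan_prep(genotypes, blues, trait = trait, encoding = encoding,
                    kinship = kinship, n_pcs = n_pcs, structure = structure)
  null_fit <- reml_optimize(prep$yt, prep$Xt0, prep$eig$values)
  results <- scan_core(prep, prep$yt, prep$y, vc_mode = vc_mode)
  structure(
    list(results = results,
         trait = prep$trait,
         encoding = names(prep$enc),
         vc_null = list(sigma_g2 = null_fit$lambda * null_fit$sigma2,
                        sigma_e2 = (1 - null_fit$lambda) * null_fit$sigma2,
                        lambda = null_fit$lambda, flat = null_fit$flat),
         n_entries = length(prep$y),
         spec = list(kinship = prep$kinship_mode, n_pcs = n_pcs,
                     structure = prep$structure, vc_mode = vc_mode),
         threshold = NULL,
         call = match.call()),
    class = "knob_scan"
  )
}

#' @export
print.knob_scan <- function(x, digits = 4, ...) {
  cat(sprintf("Knob marker scan%s: %d entries, encodings: %s\n",
              if (is.na(x$trait)) "" else paste0(" (", x$trait, ")"),
              x$n_entries, paste(x$encoding, collapse = ", ")))
  if (is.null(x$results)) {
    cat("  no testable markers\n")
    return(invisible(x))
  }
  df <- x$results
  df$p_value <- signif(df$p_value, 3)
  for (cc in c("freq", "effect", "se", "marker_h2"))
    df[[cc]] <- round(df[[cc]], digits)
  print(df[, c("locus", "chrom", "arm", "encoding", "freq", "effect", "se",
               "p_value", "marker_h2", "significant")], row.names = FALSE)
  if (!is.null(x$threshold))
    cat(sprintf("  permutation threshold: p <= %.4g\n", x$threshold$threshold_p))
  invisible(x)
}

#' @export
summary.knob_scan <- function(object, ...) {
  print(object, ...)
  v <- object$vc_null
  cat(sprintf("Null model: sigma_g2 = %.4g, sigma_e2 = %.4g (lambda = %.3f)%s\n",
              v$sigma_g2, v$sigma_e2, v$lambda,
              if (isTRUE(v$flat)) " [flat]" else ""))
  cat(sprintf("Spec: kinship = %s, n_pcs = %d, structure = %s, vc_mode = %s\n",
              object$spec$kinship, object$spec$n_pcs, object$spec$structure,
              object$spec$vc_mode))
  invisible(object)
}

#' @export
coef.knob_scan <- function(object, ...) {
  if (is.null(object$results)) return(numeric(0))
  stats::setNames(object$results$effect,
                  paste(object$results$locus, object$results$encoding, sep = ":"))
}

#' @export
plot.knob_scan <- function(x, ...) {
  if (is.null(x$results)) stop("nothing to plot: no testable markers")
  df <- x$results
  pch <- ifelse(df$encoding == "additive", 19, 17)
  graphics::plot(df$chrom, -log10(df$p_value), pch = pch,
       xlab = "chromosome", ylab = expression(-log[10](italic(p))),
       xlim = c(1, 10),
       main = if (is.na(x$trait)) "Knob marker scan" else
         paste("Knob marker scan,", x$trait), ...)
  graphics::text(df$chrom, -log10(df$p_value), labels = df$locus, pos = 3,
                 cex = 0.7)
  if (!is.null(x$threshold))
    graphics::abline(h = -log10(x$threshold$threshold_p), col = "darkgreen",
                     lty = 2)
  graphics::legend("topleft", legend = unique(df$encoding),
                   pch = unique(pch), bty = "n")
  invisible(x)
}
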