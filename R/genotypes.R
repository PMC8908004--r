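#' Extract the knob count matrix from a panel
#'
#' @param x A `knob_panel` data frame (or any data frame with an `entry_id`
#'   column and one 0/1/2 column per knob locus), or an entries x loci matrix.
#' @return An integer matrix of class `knob_matrix` (entries x loci, values
#'   0/1/2, rownames = entry ids) with a `loci` attribute describing
#'   chromosome and arm.
#' @examples
#' m <- knob_matrix(generate_panel(generator_params(seed = 1)))
#' @export
knob_matrix <- function(x) {
  if (inherits(x, "knob_matrix")) return(x)
  loci_tab <- knob_loci()
  if (is.data.frame(x)) {
    locus_cols <- intersect(loci_tab$locus, names(x))
    if (length(locus_cols) == 0L)
      locus_cols <- grep("^K[0-9]+[LS][0-9]*$", names(x), value = TRUE)
    if (length(locus_cols) == 0L)
      stop("no knob locus columns found (expected e.g. K3L, K5L, K7S, K9S)")
    if (anyDuplicated(x$entry_id))
      stop("duplicate entry_id: ",
           paste(unique(x$entry_id[duplicated(x$entry_id)]), collapse = ", "))
    m <- as.matrix(x[, locus_cols, drop = FALSE])
    rownames(m) <- x$entry_id
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- sprintf("E%03d", seq_len(nrow(m)))
  } else {
    stop("`x` must be a data frame or matrix")
  }
  if (any(is.na(m)) || !all(m %in% c(0, 1, 2)))
    stop("knob counts must be 0, 1 or 2 with no missing values")
  storage.mode(m) <- "integer"
  attr(m, "loci") <- loci_tab[match(colnames(m), loci_tab$locus), , drop = FALSE]
  class(m) <- c("knob_matrix", class(matrix()))
  m
}

# Frequency of the knob-presence allele per locus.
presence_freq <- function(m) {
  m <- knob_matrix(m)
  colSums(m) / (2 * nrow(m))
}

#' Minor allele frequency per knob locus
#'
#' `min(f, 1 - f)` where `f` is the knob-presence allele frequency.
#'
#' @param m A knob matrix or panel.
#' @return Named numeric vector in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(m) {
  f <- presence_freq(m)
  pmin(f, 1 - f)
}

#' Encode a knob matrix for the allele-substitution (additive) model
#'
#' Each locus is recoded as the number of copies of its minor allele
#' (empirical frequency < 0.5; ties are resolved to the absence allele, the
#' A2 convention). Which allele was counted is recorded so that effect signs
#' can later be normalized to the knob-presence scale. Monomorphic loci are
#' flagged and excluded from scans.
#'
#' @param m A knob matrix or panel.
#' @return A list of class `encoded_matrix` with elements `model`
#'   (`"additive"`), `values` (entries x loci codes, 0/1/2), `counted_allele`
#'   (`"presence"`/`"absence"` per locus), `freq` (frequency of the counted
#'   allele), and `excluded` (logical per locus).
#' @examples
#' enc <- encode_additive(generate_panel(generator_params(seed = 1)))
#' @export
encode_additive <- function(m) {
  m <- knob_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 entries to define a minor allele")
  f <- presence_freq(m)
  counted <- ifelse(f < 0.5, "presence", "absence")
  vals <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  flip <- counted == "absence"
  vals[, flip] <- 2L - vals[, flip, drop = FALSE]
  excluded <- f %in% c(0, 1)
  if (any(excluded))
    warning("monomorphic locus excluded from additive encoding: ",
            paste(colnames(m)[excluded], collapse = ", "))
  structure(
    list(model = "additive", values = vals,
         counted_allele = stats::setNames(counted, colnames(m)),
         freq = stats::setNames(pmin(f, 1 - f), colnames(m)),
         excluded = stats::setNames(excluded, colnames(m))),
    class = "encoded_matrix"
  )
}

#' Encode a knob matrix for the heterozygous-(dis)advantage (dominance) model
#'
#' Heterozygotes are coded 1, both homozygotes 0, so the marker tests a
#' heterozygote-specific shift. Loci with no variation in heterozygosity
#' (no heterozygote, or all entries heterozygous) are flagged and excluded.
#'
#' @param m A knob matrix or panel.
#' @return An `encoded_matrix` list; `freq` holds the heterozygote frequency
#'   (the dominance-model analogue of a MAF) and `counted_allele` is `NA`.
#' @examples
#' enc <- encode_dominance(generate_panel(generator_params(seed = 1)))
#' @export
encode_dominance <- function(m) {
  m <- knob_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 entries")
  vals <- matrix(as.integer(unclass(m) == 1L), nrow(m), ncol(m),
                 dimnames = dimnames(m))
  het <- colMeans(vals)
  excluded <- het %in% c(0, 1)
  if (any(excluded))
    warning("locus without heterozygosity contrast excluded from dominance encoding: ",
            paste(colnames(m)[excluded], collapse = ", "))
  structure(
    list(model = "dominance", values = vals,
         counted_allele = stats::setNames(rep(NA_character_, ncol(m)), colnames(m)),
         freq = stats::setNames(het, colnames(m)),
         excluded = stats::setNames(excluded, colnames(m))),
    class = "encoded_matrix"
  )
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("%s-encoded knob matrix: %d entries x %d loci (%d excluded)\n",
              x$model, nrow(x$values), ncol(x$values), sum(x$excluded)))
  invisible(x)
}

#' Knob dosage class
#'
#' Sum of knob-presence allele counts over the four variable loci
#' (0 to 8): the x-axis of the dosage-class comparisons.
#'
#' @param g A knob matrix/panel, or a single genotype vector covering the
#'   four variable loci.
#' @return Integer vector of dosage classes, one per entry.
#' @examples
#' dosage_class(c(K3L = 2, K5L = 2, K7S = 2, K9S = 2))  # 8
#' @export
dosage_class <- function(g) {
  loci <- knob_loci()$locus
  if (is.null(dim(g)) && !is.data.frame(g)) {
    miss <- setdiff(loci, names(g))
    if (length(miss))
      stop("genotype is missing loci: ", paste(miss, collapse = ", "))
    g <- check_counts(g[loci], "g")
    return(as.integer(sum(g)))
  }
  m <- knob_matrix(g)
  miss <- setdiff(loci, colnames(m))
  if (length(miss))
    stop("matrix is missing loci: ", paste(miss, collapse = ", "))
  as.integer(rowSums(m[, loci, drop = FALSE]))
}
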