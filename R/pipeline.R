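#' Read a pipeline configuration file
#'
#' A flat YAML file whose keys mirror [generator_params()] plus optional
#' `scan` settings (`encoding`, `kinship`, `n_pcs`, `structure`, `vc_mode`,
#' `traits`) and `threshold` settings (`n_perm`, `level`).
#'
#' @param path YAML file path.
#' @return A validated configuration list with elements `params`, `scan`,
#'   `threshold`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw = list()) {
  raw <- as.list(raw)
  scan_cfg <- raw$scan %||% list()
  thr_cfg <- raw$threshold %||% list()
  raw$scan <- NULL
  raw$threshold <- NULL
  known <- names(formals(generator_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  params <- do.call(generator_params, raw)
  list(
    params = params,
    scan = list(
      encoding = scan_cfg$encoding %||% c("additive", "dominance"),
      kinship = scan_cfg$kinship %||% "vanraden",
      n_pcs = scan_cfg$n_pcs %||% 0,
      structure = scan_cfg$structure %||% "auto",
      vc_mode = scan_cfg$vc_mode %||% "exact",
      traits = scan_cfg$traits %||% c("mf", "ff")
    ),
    threshold = list(
      n_perm = thr_cfg$n_perm %||% 50,
      level = thr_cfg$level %||% 0.95
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[knobscan] %s", sprintf(fmt, ...)))
}

#' Run the full knob association pipeline
#'
#' Executes simulate -> BLUEs/heritability -> scans (each trait, requested
#' encodings) -> permutation thresholds -> descriptive summaries, writing all
#' artifacts under `out_dir`. Every output table carries a header comment
#' with the package version, configuration hash and seed; reruns with the
#' same configuration and seed are bit-identical.
#'
#' @param config A configuration list from [read_config()]/[build_config()],
#'   a YAML path, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configured seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`panel`,
#'   `records`, `blues`, `heritability`, `scans`, `thresholds`,
#'   `correlations`, `summaries`) and `files`, the paths written.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) config <- build_config()
  if (!is.null(config$params) && !inherits(config$params, "generator_params"))
    stop("`config$params` must come from generator_params()")
  if (!is.null(seed)) {
    raw <- unclass(config$params)
    raw$assay <- NULL
    raw$seed <- as.integer(seed)
    config$params <- do.call(generator_params, raw)
  }
  params <- config$params
  hash <- config_hash(config)
  stamp <- sprintf("knobscan %s | config %s | seed %d",
                   as.character(utils::packageVersion("knobscan")),
                   hash, params$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  panel <- generate_panel(params)
  records <- simulate_phenotypes(panel, params)
  write_genotypes(panel, file.path(out_dir, "genotypes.csv"), comment = stamp)
  write_phenotypes(records, file.path(out_dir, "phenotypes.csv"), comment = stamp)
  files <- c(files, file.path(out_dir, c("genotypes.csv", "phenotypes.csv")))
  pipeline_log(quiet, "simulate: %d entries, %d plants (%.2fs)",
               nrow(panel), nrow(records), tic() - t0)

  t0 <- tic()
  traits <- config$scan$traits
  blues <- do.call(rbind, lapply(c(traits, "gs"), function(tr)
    compute_blues(records, tr, entries = panel$entry_id)))
  blues <- blues[!duplicated(paste(blues$entry_id, blues$trait)), ]
  herit <- do.call(rbind, lapply(unique(c(traits, "gs")), function(tr) {
    h <- estimate_heritability(records, tr, groups = panel)
    data.frame(trait = h$trait, h2 = h$h2, sigma_g2 = h$sigma_g2,
               sigma_e2 = h$sigma_e2, r_eff = h$r_eff,
               stringsAsFactors = FALSE)
  }))
  write_table_commented(blues, file.path(out_dir, "blues.tsv"), comment = stamp)
  write_table_commented(herit, file.path(out_dir, "heritability.tsv"),
                        comment = stamp)
  files <- c(files, file.path(out_dir, c("blues.tsv", "heritability.tsv")))
  pipeline_log(quiet, "blues/heritability: %d traits (%.2fs)",
               length(unique(blues$trait)), tic() - t0)

  t0 <- tic()
  scans <- list()
  thresholds <- list()
  for (tr in traits) {
    b <- blues[blues$trait == toupper(tr), ]
    sc <- knob_scan(panel, b, trait = tr,
                    encoding = config$scan$encoding,
                    kinship = config$scan$kinship,
                    n_pcs = config$scan$n_pcs,
                    structure = config$scan$structure,
                    vc_mode = config$scan$vc_mode)
    thr <- withCallingHandlers(
      permutation_threshold(panel, b, trait = tr,
                            encoding = config$scan$encoding,
                            kinship = config$scan$kinship,
                            n_pcs = config$scan$n_pcs,
                            structure = config$scan$structure,
                            vc_mode = config$scan$vc_mode,
                            n_perm = config$threshold$n_perm,
                            level = config$threshold$level,
                            seed = substream_seed(params$seed,
                                                  paste0("threshold_", tr))),
      warning = function(w) {
        pipeline_log(quiet, "warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    scans[[tr]] <- apply_threshold(sc, thr)
    thresholds[[tr]] <- thr
  }
  res <- do.call(rbind, lapply(names(scans), function(tr) {
    df <- scans[[tr]]$results
    cbind(trait = toupper(tr), df)
  }))
  thr_df <- do.call(rbind, lapply(names(thresholds), function(tr) {
    t <- thresholds[[tr]]
    data.frame(trait = toupper(tr),
               encoding = paste(t$encoding, collapse = "+"),
               n_perm = t$n_perm, level = t$level,
               threshold_p = t$threshold_p, seed = t$seed,
               stringsAsFactors = FALSE)
  }))
  write_table_commented(res, file.path(out_dir, "scan_results.tsv"),
                        comment = stamp)
  write_table_commented(thr_df, file.path(out_dir, "thresholds.tsv"),
                        comment = stamp)
  files <- c(files, file.path(out_dir, c("scan_results.tsv", "thresholds.tsv")))
  pipeline_log(quiet, "scan + threshold: %d traits x %d markers (%.2fs)",
               length(traits), length(unique(res$locus)), tic() - t0)

  t0 <- tic()
  wide <- Reduce(function(a, b) merge(a, b, by = "entry_id"),
                 lapply(c("mf", "ff", "gs"), function(tr) {
                   b <- compute_blues(records, tr, entries = panel$entry_id)
                   stats::setNames(b[, c("entry_id", "blue")], c("entry_id", tr))
                 }))
  wide <- wide[match(panel$entry_id, wide$entry_id), ]
  cors <- trait_correlations(wide$ff, wide$mf, wide$gs, dosage_class(panel))
  cor_df <- data.frame(trait = rownames(cors), round(cors, 4),
                       stringsAsFactors = FALSE)
  summ <- group_summaries(records, panel)
  write_table_commented(cor_df, file.path(out_dir, "correlations.tsv"),
                        comment = stamp)
  write_table_commented(summ, file.path(out_dir, "group_summaries.tsv"),
                        comment = stamp)
  files <- c(files, file.path(out_dir, c("correlations.tsv", "group_summaries.tsv")))
  pipeline_log(quiet, "summaries written (%.2fs); done.", tic() - t0)

  invisible(list(panel = panel, records = records, blues = blues,
                 heritability = herit, scans = scans, thresholds = thresholds,
                 correlations = cors, summaries = summ,
                 config = config, files = files))
}
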