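# CSV in, TSV out; UTF-8, "." decimal separator, comment lines start with "#".

#' Read a genotype panel CSV
#'
#' Expects columns `entry_id`, `entry_type`, `parent1`, `parent2` and one
#' column per knob locus holding knob-presence allele counts. Codes outside
#' \{0, 1, 2\} are rejected with the offending row and locus named.
#'
#' @param path CSV file path.
#' @return A `knob_panel` data frame.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"entry_id" %in% names(df)) stop("missing required column `entry_id`")
  if (anyDuplicated(df$entry_id))
    stop("duplicate entry_id: ",
         paste(unique(df$entry_id[duplicated(df$entry_id)]), collapse = ", "))
  locus_cols <- intersect(knob_loci()$locus, names(df))
  if (length(locus_cols) == 0L)
    stop("missing knob locus columns (expected K3L, K5L, K7S, K9S)")
  for (lc in locus_cols) {
    v <- df[[lc]]
    bad <- which(is.na(v) | !(v %in% c(0, 1, 2)) | v != as.integer(v))
    if (length(bad))
      stop(sprintf("invalid knob code at row %d, locus %s: %s",
                   bad[1], lc, as.character(df[[lc]][bad[1]])))
    df[[lc]] <- as.integer(v)
  }
  if (!"entry_type" %in% names(df))
    df$entry_type <- ifelse(rowSums(df[, locus_cols, drop = FALSE] == 1L) > 0,
                            "hybrid", "line")
  if (!"parent1" %in% names(df)) df$parent1 <- NA_character_
  if (!"parent2" %in% names(df)) df$parent2 <- NA_character_
  class(df) <- c("knob_panel", "data.frame")
  df
}

#' Write a genotype panel CSV
#' @param panel A `knob_panel` data frame.
#' @param path Output path.
#' @param comment Optional header comment lines (written prefixed with `#`).
#' @export
write_genotypes <- function(panel, path, comment = NULL) {
  write_table_commented(as.data.frame(panel), path, sep = ",", comment = comment)
}

#' Read replicate-level phenotype records
#' @param path CSV with columns `plant_id`, `entry_id`, `replicate`,
#'   `mf_days`, `ff_days`, `gs_pg`.
#' @return Plant-record data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plant_id", "entry_id", "replicate", "mf_days", "ff_days", "gs_pg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (cc in c("mf_days", "ff_days", "gs_pg")) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive or missing %s at row %d", cc, bad[1]))
  }
  df
}

#' Write replicate-level phenotype records
#' @inheritParams write_genotypes
#' @param records Plant-record data frame.
#' @export
write_phenotypes <- function(records, path, comment = NULL) {
  write_table_commented(records, path, sep = ",", comment = comment)
}

write_table_commented <- function(df, path, sep = "\t", comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Short FNV-1a content hash used to stamp output tables with their
# configuration.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
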