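# TSV dialect: tab-separated, UTF-8, header row required, "." decimal
# separator. Readers fail with the file name and offending line so that
# malformed inputs are traceable.

.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop(path, ": missing required column(s) ", paste(miss, collapse = ", "))
  }
  out
}

.check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    suppress <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(trimws(v)) & is.na(suppress))
    if (length(bad)) {
      stop(path, ": line ", bad[1] + 1L, ", column '", col,
           "': not a number ('", v[bad[1]], "')")
    }
    v <- suppress
  }
  v
}

#' Read a biomass-specific rate table
#'
#' Expected columns: `compound`, `value` (mmol per g biomass per h, signed,
#' substrate negative), optional `sd`, `unit`.
#'
#' @param path TSV file path.
#' @param substrate Substrate compound name.
#' @return A `rate_set`.
#' @export
read_rates_tsv <- function(path, substrate = "galacturonate") {
  df <- .read_tsv_checked(path, c("compound", "value"))
  val <- .check_numeric_col(df, "value", path)
  sdv <- if ("sd" %in% names(df)) .check_numeric_col(df, "sd", path) else NULL
  q <- stats::setNames(val, df$compound)
  sd <- if (!is.null(sdv)) stats::setNames(sdv, df$compound) else NULL
  rate_set(q, sd, substrate = substrate)
}

#' Read a yield table
#'
#' Expected columns: `compound`, `value`, optional `sd`, `unit`
#' (`cmol_per_cmol` / `mol_per_cmol`; units are re-derived from the
#' registry's carbon counts and cross-checked when present).
#'
#' @param path TSV file path.
#' @param registry Compound registry.
#' @return A `yield_set`.
#' @export
read_yields_tsv <- function(path, registry = default_registry()) {
  df <- .read_tsv_checked(path, c("compound", "value"))
  val <- .check_numeric_col(df, "value", path)
  sdv <- if ("sd" %in% names(df)) .check_numeric_col(df, "sd", path) else NULL
  ys <- yield_set(stats::setNames(val, df$compound),
                  if (!is.null(sdv)) stats::setNames(sdv, df$compound),
                  registry = registry)
  if ("unit" %in% names(df)) {
    mism <- df$compound[df$unit != ys$unit[match(df$compound, ys$compound)]]
    if (length(mism)) {
      stop(path, ": declared unit conflicts with registry carbon count ",
           "for: ", paste(mism, collapse = ", "))
    }
  }
  ys
}

#' Read position-specific NMR enrichment observations
#'
#' Expected columns: `time_h`, `pct_methyl`, `pct_carbonyl`; an empty cell
#' means the position was not measured at that time.
#'
#' @param path TSV file path.
#' @return An `nmr_observations` table.
#' @export
read_nmr_tsv <- function(path) {
  df <- .read_tsv_checked(path, c("time_h", "pct_methyl", "pct_carbonyl"))
  nmr_observations(.check_numeric_col(df, "time_h", path),
                   .check_numeric_col(df, "pct_methyl", path),
                   .check_numeric_col(df, "pct_carbonyl", path))
}

#' Read a gene counts table
#'
#' Expected columns: `gene_id`, `count`, `cds_length_bp`.
#'
#' @param path TSV file path.
#' @return Data frame suitable for [rpkm_table()].
#' @export
read_counts_tsv <- function(path) {
  df <- .read_tsv_checked(path, c("gene_id", "count", "cds_length_bp"))
  df$count <- .check_numeric_col(df, "count", path)
  df$cds_length_bp <- .check_numeric_col(df, "cds_length_bp", path)
  df
}

#' Write a table as TSV
#'
#' Tab-separated, UTF-8, header row, "." decimal separator; numeric
#' columns are formatted at 6 significant digits so that identical runs
#' produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(signif(out[[nm]], 6), format = "fg",
                                  digits = 15))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Path to a packaged reference data file
#'
#' @param file File name under the package's `extdata`, or nothing to
#'   list them.
#' @return Full file path.
#' @export
acetotrace_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "acetotrace")))
  }
  p <- system.file("extdata", file, package = "acetotrace")
  if (!nzchar(p)) stop("no packaged file called '", file, "'")
  p
}

#' Measured reference tables of the enrichment culture
#'
#' Accessors for the packaged steady-state measurements of the
#' galacturonate-limited chemostat enrichment culture: biomass-specific
#' conversion rates, product yields, the position-specific acetate NMR
#' time course from the 13C-bicarbonate switch, and transcript RPKM
#' levels.
#'
#' @return `chemostat_rates()` a `rate_set`; `chemostat_yields()` a
#'   `yield_set`; `acetate_nmr()` an `nmr_observations` table;
#'   `transcript_rpkm()` a data frame with `gene_id`, `pathway`, `rpkm`.
#' @name reference_data
NULL

#' @rdname reference_data
#' @export
chemostat_rates <- function() {
  read_rates_tsv(acetotrace_example("chemostat_rates.tsv"))
}

#' @rdname reference_data
#' @export
chemostat_yields <- function() {
  read_yields_tsv(acetotrace_example("chemostat_yields.tsv"))
}

#' @rdname reference_data
#' @export
acetate_nmr <- function() {
  read_nmr_tsv(acetotrace_example("acetate_nmr.tsv"))
}

#' @rdname reference_data
#' @export
transcript_rpkm <- function() {
  .read_tsv_checked(acetotrace_example("transcript_rpkm.tsv"),
                    c("gene_id", "pathway", "rpkm"))
}
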