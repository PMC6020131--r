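#' Read a polymer characterisation table
#'
#' Expects a UTF-8 CSV with header `name,mw_kg_per_mol,rh_nm` and an optional
#' `purity` column. Decimal commas are rejected: concentrations and radii must
#' use the dot as decimal separator.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with the validated columns.
#' @export
read_polymer_table <- function(path) {
  stop_unless(is.character(path) && length(path) == 1L && file.exists(path),
              "polymer table file not found")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("name", "mw_kg_per_mol", "rh_nm")
  stop_unless(all(req %in% names(raw)),
              "polymer table must have columns name, mw_kg_per_mol, rh_nm")
  for (col in intersect(c("mw_kg_per_mol", "rh_nm", "purity"), names(raw))) {
    if (!is.numeric(raw[[col]]))
      stop(sprintf(
        "column '%s' is not numeric; check for decimal commas or stray text", col),
        call. = FALSE)
  }
  # constructor re-validates each row (positivity, purity range)
  invisible(as_polymer_list(raw))
  raw
}

#' Write a polymer table in the package CSV schema
#'
#' @param polymers A list of [polymer_spec()] or a polymer table data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_polymer_table <- function(polymers, path) {
  ps <- as_polymer_list(polymers)
  df <- data.frame(
    name = vapply(ps, `[[`, character(1), "name"),
    mw_kg_per_mol = vapply(ps, `[[`, numeric(1), "mw"),
    rh_nm = vapply(ps, `[[`, numeric(1), "rh"),
    purity = vapply(ps, `[[`, numeric(1), "purity"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged characterisation table of the four purified polymers
#'
#' Ships the measured weight-average molecular weights and hydrodynamic radii
#' of guar gum and of three oat beta-glucan fractions of decreasing size
#' (BG1, BG2, BG3), the panel every worked example in this package uses.
#'
#' @return A data.frame with columns `name`, `mw_kg_per_mol`, `rh_nm`, `purity`.
#' @examples
#' reference_polymer_table()
#' @export
reference_polymer_table <- function() {
  read_polymer_table(system.file("extdata", "purified_polymers.csv",
                                 package = "deplstab", mustWork = TRUE))
}

#' Reported critical concentrations accompanying the characterisation table
#'
#' The CVC/CFC values originally reported alongside the purified-polymer
#' panel, used for side-by-side comparison in [reproduction_report()]. The
#' reported BG1 and BG3 values were derived from unrounded instrument data
#' and are not exactly recoverable from the rounded Mw/Rh columns; the report
#' flags these as documented discrepancies rather than reconciling them.
#'
#' @return A data.frame with columns `name`, `cvc_reported_wtpct`,
#'   `cfc_reported_wtpct`.
#' @export
reported_critical_concentrations <- function() {
  utils::read.csv(system.file("extdata", "reported_critical_concentrations.csv",
                              package = "deplstab", mustWork = TRUE),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read qualitative regime observations
#'
#' CSV schema `name,c_wtpct,regime`, where `regime` is one of a1-a4 or
#' `unknown` for cells observed but not classifiable.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of observations.
#' @export
read_observations <- function(path) {
  stop_unless(is.character(path) && length(path) == 1L && file.exists(path),
              "observation file not found")
  obs <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stop_unless(all(c("name", "c_wtpct", "regime") %in% names(obs)),
              "observations must have columns name, c_wtpct, regime")
  stop_unless(is.numeric(obs$c_wtpct) && all(obs$c_wtpct >= 0),
              "observed concentrations must be non-negative numbers")
  bad <- setdiff(unique(obs$regime), c("a1", "a2", "a3", "a4", "unknown"))
  if (length(bad))
    stop("unrecognised regime labels: ", paste(bad, collapse = ", "), call. = FALSE)
  obs
}

#' Truncate numbers at a fixed number of decimals
#'
#' Truncation toward zero, the printing convention of the reference
#' characterisation table (e.g. a computed CVC of 0.2489 wt% is listed as
#' 0.24, not the round-half-up 0.25). Used for the table-precision columns of
#' [reproduction_report()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` truncated toward zero at `digits` decimals.
#' @examples
#' truncate_decimals(0.2489, 2)   # 0.24
#' truncate_decimals(0.03771, 3)  # 0.037
#' @export
truncate_decimals <- function(x, digits) {
  stop_unless(is.numeric(x), "x must be numeric")
  stop_unless(is_scalar_num(digits) && digits >= 0 && digits == round(digits),
              "digits must be a non-negative integer")
  f <- 10^digits
  # guard against binary representation pushing an exact decimal just below itself
  trunc(x * f + sign(x) * 1e-9) / f
}

# pinned numeric formatting so repeated runs give byte-identical files
format_num <- function(x) {
  if (is.numeric(x)) vapply(x, function(v) sprintf("%.10g", v), character(1)) else x
}

#' Write a predictions/report table as TSV
#'
#' Numeric columns are written with a pinned shortest-style format so that
#' repeated runs of the same configuration produce byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output TSV path.
#' @param json Optional path for a JSON mirror of the same table.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, json = NULL) {
  stop_unless(is.data.frame(df), "df must be a data.frame")
  out <- as.data.frame(lapply(df, format_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}
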