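# Preprocessing: cleaning, standardization, code validation, deduplication.
# The first stage of the linkage pipeline. Everything downstream (Bloom
# encoding, tokenization, blocking) assumes cleaned registries.

#' Normalize a person name
#'
#' Uppercases, folds Unicode accents to ASCII, strips punctuation and
#' digits, collapses whitespace runs to single spaces and trims. Name
#' particles (DA, DE, DO, DAS, DOS, E) are retained by default: they carry
#' signal for bigram encodings. Normalization is idempotent.
#'
#' @param x Character vector (empty strings and `NA` allowed).
#' @param strip_particles If `TRUE`, the particles are removed.
#' @return Character vector containing only `A-Z` and single spaces; empty
#'   input maps to empty output, `NA` stays `NA`.
#' @export
#' @examples
#' normalize_name("José da Silva")  # "JOSE DA SILVA"
normalize_name <- function(x, strip_particles = FALSE) {
  out <- stringi::stri_trans_general(x, "Latin-ASCII")
  out <- toupper(out)
  out <- gsub("[^A-Z ]+", " ", out)
  if (strip_particles) {
    out <- gsub("\\b(DA|DE|DO|DAS|DOS|E)\\b", " ", out)
  }
  out <- gsub(" +", " ", out)
  out <- trimws(out)
  out[is.na(x)] <- NA_character_
  out
}

#' Standardize a date field
#'
#' Parses dates declared to be in one dialect -- `DMY` (`DD/MM/YYYY`) or
#' `ISO` (`YYYY-MM-DD`) -- and emits ISO-8601 text. The dialect is declared
#' per input file, never sniffed: silently misparsed dates are the worst
#' linkage failure mode. Invalid or impossible dates are data, not errors:
#' they come back as `NA` and the caller records an `invalid_date` flag.
#'
#' @param x Character vector of raw dates.
#' @param dialect `"DMY"` or `"ISO"`.
#' @return Character vector of `YYYY-MM-DD` dates, `NA` where unparseable.
#' @export
#' @examples
#' standardize_date("01/02/2003", "DMY")   # "2003-02-01"
#' standardize_date("32/13/2003", "DMY")   # NA
standardize_date <- function(x, dialect = c("DMY", "ISO")) {
  dialect <- match.arg(dialect)
  shape <- switch(dialect,
                  DMY = "^[0-9]{1,2}/[0-9]{1,2}/[0-9]{4}$",
                  ISO = "^[0-9]{4}-[0-9]{2}-[0-9]{2}$")
  fmt <- switch(dialect, DMY = "%d/%m/%Y", ISO = "%Y-%m-%d")
  ok <- !is.na(x) & grepl(shape, x)
  out <- rep(NA_character_, length(x))
  d <- as.Date(x[ok], format = fmt)
  # as.Date() rolls nothing over with an explicit format: impossible
  # dates ("31/04/2003") come back NA
  out[ok] <- ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))
  out
}

.add_flag <- function(flags, where, flag) {
  flags[where] <- ifelse(flags[where] == "", flag,
                         paste(flags[where], flag, sep = ";"))
  flags
}

#' Validate municipality and NIS codes
#'
#' Municipality codes must be exactly 7 digits and NIS keys exactly 11
#' digits. Violations set the field to missing and add a quality flag.
#'
#' @param registry A registry `data.table` (modified copy returned).
#' @return The registry with validated codes and an updated `quality_flags`
#'   column.
#' @export
validate_codes <- function(registry) {
  reg <- data.table::copy(data.table::as.data.table(registry))
  if (!"quality_flags" %in% names(reg)) reg[, quality_flags := ""]
  bad_mun <- !is.na(reg$municipality_code) &
    !grepl("^[0-9]{7}$", reg$municipality_code)
  reg[bad_mun, municipality_code := NA_character_]
  reg[, quality_flags := .add_flag(quality_flags, bad_mun,
                                   "invalid_municipality_code")]
  if ("nis" %in% names(reg)) {
    bad_nis <- !is.na(reg$nis) & !grepl("^[0-9]{11}$", reg$nis)
    reg[bad_nis, nis := NA_character_]
    reg[, quality_flags := .add_flag(quality_flags, bad_nis, "invalid_nis")]
  }
  reg[]
}

#' Clean and standardize a registry
#'
#' Applies the full preprocessing stage: name normalization for `full_name`
#' and `mother_name` (and, when present, standardization of the auxiliary
#' `mother_birth_date` column of birth registries), sex harmonization to
#' `{M, F, unknown}`, date standardization under the declared dialect, and
#' code validation. Quality flags (`invalid_date`, `empty_name`,
#' `invalid_municipality_code`, `invalid_nis`) accumulate in a
#' semicolon-separated `quality_flags` column.
#'
#' @param registry Raw registry (`data.table` or `data.frame`).
#' @param date_dialect Declared date dialect of this file, see
#'   [standardize_date()].
#' @param strip_particles Passed to [normalize_name()].
#' @return A cleaned registry `data.table`.
#' @export
#' @examples
#' raw <- generate_population(3, seed = 1)
#' clean_registry(raw)[, .(record_id, full_name, birth_date)]
clean_registry <- function(registry, date_dialect = "DMY",
                           strip_particles = FALSE) {
  reg <- data.table::copy(data.table::as.data.table(registry))
  reg[, quality_flags := ""]
  reg[, full_name := normalize_name(full_name, strip_particles)]
  reg[, mother_name := normalize_name(mother_name, strip_particles)]
  empty_to_na <- function(v) ifelse(!is.na(v) & v == "", NA_character_, v)
  reg[, full_name := empty_to_na(full_name)]
  reg[, mother_name := empty_to_na(mother_name)]
  reg[, quality_flags := .add_flag(quality_flags, is.na(full_name),
                                   "empty_name")]
  sx <- toupper(substr(ifelse(is.na(reg$sex), "", reg$sex), 1, 1))
  reg[, sex := ifelse(sx %in% c("M", "F"), sx, "unknown")]
  raw_date <- reg$birth_date
  reg[, birth_date := standardize_date(raw_date, date_dialect)]
  reg[, quality_flags := .add_flag(quality_flags,
                                   is.na(birth_date) & !is.na(raw_date),
                                   "invalid_date")]
  if ("mother_birth_date" %in% names(reg)) {
    reg[, mother_birth_date := standardize_date(mother_birth_date,
                                                date_dialect)]
  }
  validate_codes(reg)
}

#' Deduplicate a cleaned registry on the full linkage key
#'
#' Records with an identical linkage key `(full_name, sex, mother_name,
#' birth_date, municipality_code)` are collapsed to one, keeping the first
#' in stable input order. Deduplication is exact-key only.
#'
#' @param registry Cleaned registry.
#' @return A list with `registry` (deduplicated) and `removed` (count).
#' @export
deduplicate <- function(registry) {
  reg <- data.table::as.data.table(registry)
  keycols <- c("full_name", "sex", "mother_name", "birth_date",
               "municipality_code")
  dup <- duplicated(reg, by = keycols)
  list(registry = reg[!dup], removed = sum(dup))
}

#' Summarize preprocessing quality
#'
#' Counts quality flags and (optionally) duplicates removed, for the
#' pipeline's JSON preprocessing report.
#'
#' @param registry Cleaned registry.
#' @param removed Number of duplicates removed (from [deduplicate()]).
#' @return A named list of counts.
#' @export
preprocessing_report <- function(registry, removed = 0L) {
  flags <- unlist(strsplit(registry$quality_flags[registry$quality_flags != ""],
                           ";", fixed = TRUE))
  counts <- if (length(flags)) as.list(table(flags)) else list()
  list(n_records = nrow(registry),
       duplicates_removed = as.integer(removed),
       flag_counts = counts)
}
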