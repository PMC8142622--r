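# Dataset extraction with pseudonymization: the post-linkage step that
# turns linked registries into a research-ready table. Record identifiers
# are replaced by keyed pseudonyms (deterministic, so joinability across
# tables survives); direct identifiers never pass through; sensitive
# fields can be aggregated (e.g. birth date -> birth year).

.IDENTIFYING_FIELDS <- c("full_name", "mother_name", "nis")

#' Pseudonymize record identifiers
#'
#' Deterministic keyed pseudonyms: two independent polynomial hashes of
#' `salt + id` concatenated into a 16-hex-digit code. The same `(id, salt)`
#' always yields the same pseudonym, so tables pseudonymized under one
#' salt remain joinable; without the salt the mapping is not recoverable
#' from the output.
#'
#' @param ids Character vector of record identifiers.
#' @param salt Secret salt string (non-empty).
#' @return Character vector of 16-character hexadecimal pseudonyms.
#' @export
#' @examples
#' pseudonymize_ids(c("A1", "A2"), salt = "s3cret")
pseudonymize_ids <- function(ids, salt) {
  .assert(is.character(salt) && nchar(salt) > 0, "`salt` must be non-empty")
  keyed <- paste0(salt, "\r", ids)
  h1 <- .hash_strings(keyed, mult = 33, init = 5381)
  h2 <- .hash_strings(keyed, mult = 57, init = 17)
  sprintf("%08x%08x", as.integer(h1 %% 2^31), as.integer(h2 %% 2^31))
}

#' Extraction specification
#'
#' Declares which variables a research extract retains and how sensitive
#' fields are aggregated. Requests for direct identifiers (`full_name`,
#' `mother_name`, `nis`) are rejected.
#'
#' @param variables Registry columns to retain (besides the pseudonyms
#'   and the linkage score).
#' @param salt Pseudonymization salt.
#' @param aggregate Named character vector of aggregation rules; supported:
#'   `c(birth_date = "year")`.
#' @return An `extraction_spec`.
#' @export
extraction_spec <- function(variables = c("sex", "birth_date",
                                          "municipality_code"),
                            salt, aggregate = c(birth_date = "year")) {
  bad <- intersect(variables, .IDENTIFYING_FIELDS)
  .assert(length(bad) == 0,
          paste("identifying fields may not be extracted:",
                paste(bad, collapse = ", ")))
  .assert(all(aggregate %in% "year"), "unknown aggregation rule")
  structure(list(variables = variables, salt = salt, aggregate = aggregate),
            class = "extraction_spec")
}

.apply_aggregation <- function(dt, spec, cols) {
  for (f in names(spec$aggregate)) {
    for (cn in cols[endsWith(cols, f)]) {
      if (spec$aggregate[[f]] == "year") {
        data.table::set(dt, j = cn,
                        value = substr(dt[[cn]], 1, 4))
      }
    }
  }
  dt
}

#' Extract a research-ready table from a linked dataset
#'
#' Joins the linked pairs with the two cleaned registries, replaces both
#' record ids by keyed pseudonyms, drops all identifying fields, and
#' applies the aggregation rules. Columns from the left registry are
#' prefixed `left_`, from the right `right_`.
#'
#' @param linked Linked pairs (`left_id`, `right_id`, `score`).
#' @param left,right The cleaned registries that were linked.
#' @param spec An [extraction_spec()].
#' @return A `data.table` with `pid_left`, `pid_right`, `score` and the
#'   requested variables; no name, mother's name or NIS column survives.
#' @export
extract_dataset <- function(linked, left, right, spec) {
  .assert(inherits(spec, "extraction_spec"),
          "`spec` must be an extraction_spec")
  linked <- data.table::as.data.table(linked)
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  li <- match(linked$left_id, left$record_id)
  ri <- match(linked$right_id, right$record_id)
  out <- data.table::data.table(
    pid_left = pseudonymize_ids(linked$left_id, spec$salt),
    pid_right = pseudonymize_ids(linked$right_id, spec$salt),
    score = linked$score
  )
  for (v in spec$variables) {
    if (v %in% names(left)) out[, paste0("left_", v) := left[[v]][li]]
    if (v %in% names(right)) out[, paste0("right_", v) := right[[v]][ri]]
  }
  .apply_aggregation(out, spec, setdiff(names(out),
                                        c("pid_left", "pid_right", "score")))
  leak <- intersect(unlist(lapply(.IDENTIFYING_FIELDS, function(f)
    c(f, paste0("left_", f), paste0("right_", f)))), names(out))
  .assert(length(leak) == 0, "identifying column leaked into extract")
  out[]
}
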