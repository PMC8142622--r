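# Synthetic registry generation with known ground truth.
#
# Emulates the linkage scenario of Brazilian administrative data: a large
# social-programme registry (CadUnico-like, carries the NIS unique key) and a
# health registry (SINASC/SIM/SINAN-like, no shared key) containing corrupted
# copies of a subset of the same people. Every derived copy is recorded in a
# gold standard, so linkage quality can be measured exactly.

.REGISTRY_COLS <- c("record_id", "full_name", "sex", "mother_name",
                    "birth_date", "municipality_code", "nis")

.make_person_names <- function(n, sexes, pools) {
  gw_f <- .zipf_weights(length(pools$given_f))
  gw_m <- .zipf_weights(length(pools$given_m))
  sw <- .zipf_weights(length(pools$surnames))
  given <- character(n)
  is_f <- sexes == "F"
  given[is_f] <- sample(pools$given_f, sum(is_f), TRUE, gw_f)
  given[!is_f] <- sample(pools$given_m, sum(!is_f), TRUE, gw_m)
  s1 <- sample(pools$surnames, n, TRUE, sw)
  s2 <- sample(pools$surnames, n, TRUE, sw)
  two_surnames <- stats::runif(n) < 0.6
  p1 <- ifelse(stats::runif(n) < 0.45,
               sample(pools$particles, n, TRUE), "")
  p2 <- ifelse(two_surnames & stats::runif(n) < 0.35,
               sample(pools$particles, n, TRUE), "")
  parts <- cbind(given, p1, ifelse(two_surnames, s1, ""), p2, s2)
  nm <- apply(parts, 1L, function(r) paste(r[r != ""], collapse = " "))
  as.character(nm)
}

.random_dates <- function(n, from = "1940-01-01", to = "2005-12-31") {
  d0 <- as.integer(as.Date(from))
  d1 <- as.integer(as.Date(to))
  d <- as.Date(sample(d0:d1, n, replace = TRUE), origin = "1970-01-01")
  format(d, "%d/%m/%Y")
}

.random_nis <- function(n) {
  # 11-digit keys, unique by construction
  repeat {
    nis <- vapply(seq_len(n), function(i)
      paste0(sample(0:9, 11, replace = TRUE), collapse = ""), character(1))
    if (!anyDuplicated(nis)) return(nis)
  }
}

#' Generate a synthetic person registry
#'
#' Creates `n` records with Brazilian-style full names (given name, optional
#' particles such as DA/DE/DOS, one or two surnames), sex, mother's name,
#' birth date in `DD/MM/YYYY` text form, an IBGE-style 7-digit municipality
#' code and a unique 11-digit NIS key. Names carry accents and natural
#' casing, so downstream cleaning is genuinely exercised. Records are
#' internally deduplicated: no two records share the full linkage key.
#'
#' @param n Number of records (positive integer).
#' @param seed Integer seed; identical `(n, seed, pools)` reproduce
#'   byte-identical output.
#' @param pools Sampling pools, see [default_pools()].
#' @param mother_name_fraction Fraction of records with a populated
#'   mother's name.
#' @param id_prefix Prefix for generated `record_id`s.
#' @return A [data.table::data.table] with columns `record_id`, `full_name`,
#'   `sex`, `mother_name`, `birth_date`, `municipality_code`, `nis`.
#'   Missing values are `NA`.
#' @export
#' @examples
#' reg <- generate_population(5, seed = 1)
#' reg$full_name
generate_population <- function(n, seed, pools = default_pools(),
                                mother_name_fraction = 0.9,
                                id_prefix = "L") {
  .assert(is.numeric(n) && length(n) == 1 && n >= 1,
          "`n` must be a positive integer")
  n <- as.integer(n)
  .assert(length(pools$given_f) > 0 && length(pools$given_m) > 0 &&
            length(pools$surnames) > 0 && length(pools$municipality_codes) > 0,
          "sampling pools must be non-empty")
  .with_seed(seed, {
    sex <- sample(c("F", "M"), n, replace = TRUE)
    full_name <- .make_person_names(n, sex, pools)
    mother_name <- .make_person_names(n, rep("F", n), pools)
    mother_name[stats::runif(n) >= mother_name_fraction] <- NA_character_
    birth_date <- .random_dates(n)
    mun <- sample(pools$municipality_codes, n, replace = TRUE,
                  prob = .zipf_weights(length(pools$municipality_codes)))
    nis <- .random_nis(n)
    reg <- data.table::data.table(
      record_id = sprintf("%s%06d", id_prefix, seq_len(n)),
      full_name = full_name, sex = sex, mother_name = mother_name,
      birth_date = birth_date, municipality_code = mun, nis = nis
    )
    # enforce distinct linkage keys: resample names for colliding records
    key <- paste(reg$full_name, reg$birth_date, reg$municipality_code)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      reg$full_name[dup] <- .make_person_names(length(dup), reg$sex[dup], pools)
      key <- paste(reg$full_name, reg$birth_date, reg$municipality_code)
    }
    reg[]
  })
}

#' Corruption model for derived registries
#'
#' Configures the field-error process applied when deriving a linked
#' registry: single-character edits on names, accent loss, date digit
#' errors and per-field missingness. Probabilities are per field and
#' independent across fields and records.
#'
#' @param field_probs Named probabilities of applying character edits to the
#'   text fields (`full_name`, `mother_name`).
#' @param edit_ops Allowed edit operations, a subset of
#'   `c("substitute", "delete", "insert", "transpose")`.
#' @param max_edits_per_field Maximum number of edits applied to one field.
#' @param accent_loss_prob Probability that a name loses its accents
#'   (folded to plain ASCII), independently of character edits.
#' @param date_digit_swap_prob Probability that a birth date suffers a digit
#'   error (one digit replaced, or two adjacent digits transposed); errors
#'   may yield impossible dates, which preprocessing flags as missing.
#' @param missing_probs Named per-field probabilities of the value being
#'   dropped entirely.
#' @param seed Integer seed driving all corruption randomness.
#' @return An object of class `corruption_config`.
#' @export
#' @examples
#' corruption_config(seed = 1)          # moderate default profile
#' zero_corruption(seed = 1)            # identity (no errors)
corruption_config <- function(field_probs = c(full_name = 0.2,
                                              mother_name = 0.2),
                              edit_ops = c("substitute", "delete",
                                           "insert", "transpose"),
                              max_edits_per_field = 1L,
                              accent_loss_prob = 0.2,
                              date_digit_swap_prob = 0.2,
                              missing_probs = c(full_name = 0,
                                                mother_name = 0.05,
                                                birth_date = 0.05,
                                                sex = 0.05,
                                                municipality_code = 0.05),
                              seed = 1L) {
  probs <- c(field_probs, accent_loss_prob, date_digit_swap_prob,
             missing_probs)
  .assert(all(probs >= 0 & probs <= 1), "all probabilities must be in [0,1]")
  .assert(max_edits_per_field >= 0, "`max_edits_per_field` must be >= 0")
  .assert(all(edit_ops %in% c("substitute", "delete", "insert", "transpose")),
          "unknown edit operation")
  structure(list(field_probs = field_probs, edit_ops = edit_ops,
                 max_edits_per_field = as.integer(max_edits_per_field),
                 accent_loss_prob = accent_loss_prob,
                 date_digit_swap_prob = date_digit_swap_prob,
                 missing_probs = missing_probs, seed = as.integer(seed)),
            class = "corruption_config")
}

#' @rdname corruption_config
#' @export
zero_corruption <- function(seed = 1L) {
  corruption_config(field_probs = c(full_name = 0, mother_name = 0),
                    accent_loss_prob = 0, date_digit_swap_prob = 0,
                    missing_probs = c(full_name = 0, mother_name = 0,
                                      birth_date = 0, sex = 0,
                                      municipality_code = 0),
                    seed = seed)
}

#' @export
print.corruption_config <- function(x, ...) {
  cat("<corruption_config>\n")
  cat("  edit probs:", paste(names(x$field_probs), x$field_probs,
                             sep = "=", collapse = ", "), "\n")
  cat("  ops:", paste(x$edit_ops, collapse = ","),
      " max edits:", x$max_edits_per_field, "\n")
  cat("  accent loss:", x$accent_loss_prob,
      " date digit error:", x$date_digit_swap_prob, "\n")
  cat("  missingness:", paste(names(x$missing_probs), x$missing_probs,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.apply_edits <- function(x, ops, n_edits) {
  for (i in seq_len(n_edits)) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L == 0) break
    op <- if (length(ops) == 1) ops else sample(ops, 1)
    pos <- sample.int(L, 1)
    x <- switch(op,
      substitute = {
        ch[pos] <- sample(letters, 1); paste(ch, collapse = "")
      },
      delete = paste(ch[-pos], collapse = ""),
      insert = paste(c(ch[seq_len(pos)], sample(letters, 1),
                       if (pos < L) ch[(pos + 1):L]), collapse = ""),
      transpose = {
        if (L >= 2) {
          p <- if (pos == L) L - 1 else pos
          tmp <- ch[p]; ch[p] <- ch[p + 1]; ch[p + 1] <- tmp
        }
        paste(ch, collapse = "")
      })
  }
  x
}

.corrupt_names <- function(x, prob, config) {
  hit <- !is.na(x) & stats::runif(length(x)) < prob
  if (any(hit) && config$max_edits_per_field > 0) {
    x[hit] <- vapply(x[hit], .apply_edits, character(1),
                     ops = config$edit_ops,
                     n_edits = config$max_edits_per_field,
                     USE.NAMES = FALSE)
  }
  drop_acc <- !is.na(x) & stats::runif(length(x)) < config$accent_loss_prob
  x[drop_acc] <- stringi::stri_trans_general(x[drop_acc], "Latin-ASCII")
  x
}

.corrupt_dates <- function(x, prob) {
  hit <- which(!is.na(x) & stats::runif(length(x)) < prob)
  x[hit] <- vapply(x[hit], function(d) {
    digits_at <- which(strsplit(d, "")[[1]] %in% as.character(0:9))
    ch <- strsplit(d, "")[[1]]
    if (stats::runif(1) < 0.5) {
      p <- sample(digits_at, 1)
      ch[p] <- as.character(sample(0:9, 1))
    } else {
      adj <- digits_at[which(diff(digits_at) == 1)]
      if (length(adj)) {
        p <- if (length(adj) == 1) adj else sample(adj, 1)
        tmp <- ch[p]; ch[p] <- ch[p + 1]; ch[p + 1] <- tmp
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  x
}

.apply_missingness <- function(reg, missing_probs) {
  for (f in names(missing_probs)) {
    if (!f %in% names(reg)) next
    hit <- stats::runif(nrow(reg)) < missing_probs[[f]]
    data.table::set(reg, which(hit), f, NA_character_)
  }
  reg
}

#' Derive a linked registry with a gold standard
#'
#' Builds a second registry that shares `round(overlap_fraction * nrow(base))`
#' individuals with `base`: those records are copied, given fresh
#' `record_id`s, corrupted according to `config`, and mixed with newly
#' generated non-overlapping people. The returned gold standard lists exactly
#' the copied pairs -- it is bookkeeping from construction, never the result
#' of matching.
#'
#' @param base Registry from [generate_population()].
#' @param overlap_fraction Fraction of `base` copied into the derived
#'   registry, in `[0, 1]`.
#' @param config A [corruption_config()]; its `seed` drives all randomness.
#' @param size Total size of the derived registry (default `nrow(base)`).
#' @param keep_nis If `FALSE` (default, "health registry" mode) the NIS key
#'   is dropped from all derived records.
#' @param id_prefix Prefix for derived `record_id`s.
#' @return A list with elements `registry` (the derived registry) and
#'   `gold` (a `data.table` of true pairs `left_id`, `right_id`).
#' @export
#' @examples
#' base <- generate_population(100, seed = 1)
#' d <- derive_linked_registry(base, 0.5, corruption_config(seed = 2))
#' nrow(d$gold)
derive_linked_registry <- function(base, overlap_fraction, config,
                                   size = nrow(base), keep_nis = FALSE,
                                   id_prefix = "R") {
  .assert(nrow(base) > 0, "`base` must be non-empty")
  .assert(is.numeric(overlap_fraction) && overlap_fraction >= 0 &&
            overlap_fraction <= 1, "`overlap_fraction` must be in [0,1]")
  .assert(inherits(config, "corruption_config"),
          "`config` must be a corruption_config")
  n_overlap <- round(overlap_fraction * nrow(base))
  .assert(size >= n_overlap, "`size` must be at least the overlap count")
  .with_seed(config$seed, {
    src <- sort(sample.int(nrow(base), n_overlap))
    copies <- data.table::copy(base[src])
    left_ids <- copies$record_id
    copies[, record_id := sprintf("%s%06d", id_prefix, seq_len(n_overlap))]
    if (!keep_nis) copies[, nis := NA_character_]
    copies[, full_name := .corrupt_names(full_name,
                                         config$field_probs[["full_name"]],
                                         config)]
    copies[, mother_name := .corrupt_names(mother_name,
                                           config$field_probs[["mother_name"]],
                                           config)]
    copies[, birth_date := .corrupt_dates(birth_date,
                                          config$date_digit_swap_prob)]
    copies <- .apply_missingness(copies, config$missing_probs)
    gold <- data.table::data.table(left_id = left_ids,
                                   right_id = copies$record_id)
    n_fresh <- size - n_overlap
    if (n_fresh > 0) {
      fresh <- generate_population(n_fresh,
                                   seed = .derive_seed(config$seed, "fresh"),
                                   id_prefix = id_prefix)
      fresh[, record_id := sprintf("%s%06d", id_prefix,
                                   n_overlap + seq_len(n_fresh))]
      if (!keep_nis) fresh[, nis := NA_character_]
      out <- data.table::rbindlist(list(copies, fresh))
    } else {
      out <- copies
    }
    out <- out[sample.int(nrow(out))]
    list(registry = out[], gold = gold[order(left_id)])
  })
}

#' Generate a birth-registry scenario with mother-child ground truth
#'
#' Emulates a SINASC-like birth registry derived from a registry of mothers:
#' each birth record carries the mother's attributes (her full name, birth
#' date and municipality) plus the child's own birth date and sex. A
#' configurable fraction of children have no name yet, as newborns often do
#' at registration time. Children of the same mother receive distinct birth
#' dates, so the deterministic second linkage stage has an unambiguous key.
#'
#' @param mothers Registry of mothers (all rows are treated as mothers).
#' @param children_per_mother Either a single non-negative integer (every
#'   mother has that many children) or a function `f(n)` returning an
#'   integer vector of counts.
#' @param seed Integer seed.
#' @param unnamed_fraction Fraction of children with an empty `full_name`.
#' @param birth_years Range of candidate child birth years.
#' @return A list with `registry` (birth records; includes the extra column
#'   `mother_birth_date`) and `gold` (`data.table` of `child_id`,
#'   `mother_id`).
#' @export
#' @examples
#' m <- generate_population(10, seed = 1)
#' b <- generate_birth_scenario(m, children_per_mother = 2, seed = 2)
#' nrow(b$registry)
generate_birth_scenario <- function(mothers, children_per_mother = 1L, seed,
                                    unnamed_fraction = 0.3,
                                    birth_years = c(2015L, 2019L)) {
  .assert(nrow(mothers) > 0, "`mothers` must be non-empty")
  nm <- nrow(mothers)
  counts <- if (is.function(children_per_mother)) {
    .with_seed(.derive_seed(seed, "counts"), children_per_mother(nm))
  } else {
    rep(as.integer(children_per_mother), nm)
  }
  .assert(all(counts >= 0), "children counts must be non-negative")
  .with_seed(seed, {
    midx <- rep(seq_len(nm), counts)
    n <- length(midx)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    full_name <- .make_person_names(n, sex, default_pools())
    full_name[stats::runif(n) < unnamed_fraction] <- NA_character_
    d0 <- as.integer(as.Date(sprintf("%d-01-01", birth_years[1])))
    d1 <- as.integer(as.Date(sprintf("%d-12-31", birth_years[2])))
    bdate <- format(as.Date(sample(d0:d1, n, replace = TRUE),
                            origin = "1970-01-01"), "%d/%m/%Y")
    # distinct birth dates within a mother (no twins by construction)
    repeat {
      clash <- duplicated(data.table::data.table(midx, bdate))
      if (!any(clash)) break
      bdate[clash] <- format(as.Date(sample(d0:d1, sum(clash), TRUE),
                                     origin = "1970-01-01"), "%d/%m/%Y")
    }
    reg <- data.table::data.table(
      record_id = sprintf("B%06d", seq_len(n)),
      full_name = full_name, sex = sex,
      mother_name = mothers$full_name[midx],
      birth_date = bdate,
      municipality_code = mothers$municipality_code[midx],
      nis = NA_character_,
      mother_birth_date = mothers$birth_date[midx]
    )
    gold <- data.table::data.table(child_id = reg$record_id,
                                   mother_id = mothers$record_id[midx])
    list(registry = reg[], gold = gold)
  })
}

#' Read and write registry and gold-standard CSV files
#'
#' Registries are stored as CSV with the fixed header
#' `record_id,full_name,sex,mother_name,birth_date,municipality_code,nis`
#' (extra columns such as `mother_birth_date` are preserved); empty strings
#' on disk denote missing values, which are `NA` in memory. Gold standards
#' are two-column CSVs.
#'
#' @param registry,gold Tables to write.
#' @param path File path.
#' @return `read_registry()` and `read_gold()` return `data.table`s; the
#'   writers return `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  data.table::fwrite(registry, path, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  reg <- data.table::fread(path, colClasses = "character", na.strings = "",
                           encoding = "UTF-8")
  missing_cols <- setdiff(.REGISTRY_COLS, names(reg))
  .assert(length(missing_cols) == 0,
          paste("registry file lacks columns:",
                paste(missing_cols, collapse = ", ")))
  # quality flags are never missing, only empty
  if ("quality_flags" %in% names(reg)) {
    reg[is.na(quality_flags), quality_flags := ""]
  }
  reg
}

#' @rdname write_registry
#' @export
write_gold <- function(gold, path) {
  data.table::fwrite(gold, path, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_gold <- function(path) {
  data.table::fread(path, colClasses = "character", na.strings = "",
                    encoding = "UTF-8")
}
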