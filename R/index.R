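# Inverted-index linkage via information retrieval: word tokens over
# the linkage attributes, TF-IDF weighting with cosine scoring, and a
# fall-through schedule of exact / semi-exact / fuzzy query modes.

.NAME_PREFIX <- "M:"

# Long token table (record_idx, token, tf) over a cleaned registry.
# Name words keep their own namespaces (mother tokens prefixed) and the
# categorical attributes contribute one token each when present. With
# char_bigrams, padded character bigrams of the name words are added as
# further tokens: a single-character typo breaks a whole word token but
# only two of its bigrams, so similarity degrades gracefully.
.tokenize_registry <- function(registry, char_bigrams = FALSE) {
  reg <- data.table::as.data.table(registry)
  n <- nrow(reg)
  toks <- vector("list", n)
  name_sp <- strsplit(ifelse(is.na(reg$full_name), "", reg$full_name), " ",
                      fixed = TRUE)
  mot_sp <- strsplit(ifelse(is.na(reg$mother_name), "", reg$mother_name), " ",
                     fixed = TRUE)
  for (i in seq_len(n)) {
    t <- c(name_sp[[i]][nzchar(name_sp[[i]])],
           paste0(.NAME_PREFIX, mot_sp[[i]][nzchar(mot_sp[[i]])]))
    t <- t[t != .NAME_PREFIX]
    if (char_bigrams) {
      t <- c(t,
             paste0("G:", unlist(lapply(name_sp[[i]][nzchar(name_sp[[i]])],
                                        bigrams), use.names = FALSE)),
             paste0("H:", unlist(lapply(mot_sp[[i]][nzchar(mot_sp[[i]])],
                                        bigrams), use.names = FALSE)))
      t <- t[!t %in% c("G:", "H:")]
    }
    if (!is.na(reg$birth_date[i])) {
      # full date plus its two halves: a single-digit date error breaks
      # the full-date token but leaves either the year or the month-day
      # part intact as partial evidence
      t <- c(t, paste0("D:", reg$birth_date[i]),
             paste0("Y:", substr(reg$birth_date[i], 1, 4)),
             paste0("MD:", substr(reg$birth_date[i], 6, 10)))
    }
    if (reg$sex[i] %in% c("M", "F")) t <- c(t, paste0("S:", reg$sex[i]))
    if (!is.na(reg$municipality_code[i]))
      t <- c(t, paste0("C:", reg$municipality_code[i]))
    toks[[i]] <- t
  }
  long <- data.table::data.table(
    record_idx = rep(seq_len(n), lengths(toks)),
    token = unlist(toks)
  )
  long[, .(tf = .N), by = .(record_idx, token)]
}

#' Tokenize one cleaned record
#'
#' Word tokens from `full_name` and `mother_name` (mother tokens are
#' prefixed `M:` to keep the fields distinct), plus single tokens for
#' `birth_date`, `sex` and `municipality_code` when present. Repeated
#' words keep their multiplicity.
#'
#' @param record A one-row cleaned registry (or a named list with the
#'   linkage attributes).
#' @param char_bigrams Also emit padded character-bigram tokens of the
#'   name words (prefixes `G:`/`H:`), for typo-robust fuzzy retrieval.
#' @return Character vector of tokens (a multiset).
#' @export
#' @examples
#' r <- clean_registry(generate_population(1, seed = 1))
#' tokenize_record(r)
tokenize_record <- function(record, char_bigrams = FALSE) {
  reg <- data.table::as.data.table(record)
  .assert(nrow(reg) == 1, "`record` must be a single record")
  long <- .tokenize_registry(reg, char_bigrams)
  rep(long$token, long$tf)
}

.tfidf_weight <- function(tf, df, N) (1 + log(tf)) * log(1 + N / df)

# Sparse row-normalized TF-IDF matrix over a given vocabulary subset.
.tfidf_matrix <- function(long, vocab, N) {
  long <- long[token %in% vocab$token]
  j <- match(long$token, vocab$token)
  x <- .tfidf_weight(long$tf, vocab$df[j], N)
  M <- Matrix::sparseMatrix(i = long$record_idx, j = j, x = x,
                            dims = c(N, nrow(vocab)))
  nrm <- sqrt(Matrix::rowSums(M^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% M
}

#' Build a TF-IDF inverted index over a registry
#'
#' Indexes a cleaned, deduplicated registry: vocabulary with document
#' frequencies, posting lists (record indices and term frequencies per
#' token), and row-normalized TF-IDF matrices used for cosine scoring.
#' The weight of token `t` in a record is `(1 + ln tf) * ln(1 + N / df)`.
#'
#' @param registry Cleaned registry (non-empty).
#' @param char_bigrams Also index padded character bigrams of the name
#'   words. Word tokens alone are brittle: one typo erases a whole token.
#'   Bigram tokens keep partial credit for near-matching names; queries
#'   tokenize their probes the same way the index was built.
#' @return An object of class `inverted_index`.
#' @export
#' @examples
#' idx <- build_index(clean_registry(generate_population(20, seed = 1)))
#' idx
build_index <- function(registry, char_bigrams = FALSE) {
  reg <- data.table::as.data.table(registry)
  .assert(nrow(reg) > 0, "cannot index an empty registry")
  .assert(!anyDuplicated(reg$record_id), "record_id must be unique")
  long <- .tokenize_registry(reg, char_bigrams)
  vocab <- long[, .(df = data.table::uniqueN(record_idx)), by = token]
  data.table::setorder(vocab, token)
  vocab[, token_id := .I]
  postings <- lapply(split(long[, .(record_idx, tf)],
                           factor(long$token, levels = vocab$token)),
                     function(d) d[order(record_idx)])
  N <- nrow(reg)
  idx <- list(
    vocab = vocab, postings = postings, N = N,
    records = reg, char_bigrams = char_bigrams,
    mat = .tfidf_matrix(long, vocab, N)
  )
  structure(idx, class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index>", x$N, "records,", nrow(x$vocab), "tokens\n")
  invisible(x)
}

# Probe token multiset -> normalized weight vector over a vocabulary.
# Tokens outside the vocabulary are dropped (they can retrieve nothing).
.probe_vector <- function(tokens, vocab, N) {
  tt <- table(tokens)
  keep <- names(tt) %in% vocab$token
  if (!any(keep)) return(NULL)
  tt <- tt[keep]
  j <- match(names(tt), vocab$token)
  x <- .tfidf_weight(as.numeric(tt), vocab$df[j], N)
  x <- x / sqrt(sum(x^2))
  list(j = j, x = x)
}

#' TF-IDF cosine score between a probe and an indexed record
#'
#' Cosine similarity of L2-normalized TF-IDF vectors under the index's
#' weights. Probe tokens absent from the index vocabulary are dropped
#' before normalization.
#'
#' @param probe_tokens Token multiset (character vector, see
#'   [tokenize_record()]).
#' @param record_id Identifier of an indexed record.
#' @param index An [build_index()] object.
#' @return A similarity in `[0, 1]`.
#' @export
tfidf_score <- function(probe_tokens, record_id, index) {
  ri <- match(record_id, index$records$record_id)
  .assert(!is.na(ri), paste("record not in index:", record_id))
  pv <- .probe_vector(probe_tokens, index$vocab, index$N)
  if (is.null(pv)) return(0)
  row <- index$mat[ri, , drop = FALSE]
  min(1, max(0, sum(row[1, pv$j] * pv$x)))
}

# Record indices sharing at least one vocabulary token with the probe,
# gathered through the posting lists.
.gather_candidates <- function(tokens, index) {
  toks <- unique(tokens[tokens %in% index$vocab$token])
  if (!length(toks)) return(integer(0))
  sort(unique(unlist(lapply(index$postings[toks],
                            function(p) p$record_idx), use.names = FALSE)))
}

.attr_agrees <- function(probe, rec, field) {
  p <- probe[[field]]
  if (field == "sex") {
    if (!p %in% c("M", "F")) return(rep(TRUE, nrow(rec)))
    return(!is.na(rec[[field]]) & rec[[field]] == p)
  }
  if (is.na(p)) return(rep(TRUE, nrow(rec)))
  !is.na(rec[[field]]) & rec[[field]] == p
}

#' Query an inverted index
#'
#' Three modes, mirroring the exact / semi-exact / fuzzy query repertoire
#' of indexing-based linkage:
#' \describe{
#'   \item{exact}{candidates must agree on every linkage attribute that is
#'     non-missing in the probe; all results score 1.0.}
#'   \item{semi_exact}{candidates must agree exactly on `birth_date` and
#'     `municipality_code` (both present on both sides); the survivors are
#'     ranked by the same all-token TF-IDF cosine as fuzzy mode, so scores
#'     are comparable across modes and one cut-off can govern the whole
#'     schedule.}
#'   \item{fuzzy}{candidates sharing at least one token are gathered via
#'     the posting lists and ranked by TF-IDF cosine over all tokens.}
#' }
#' Results are sorted by score descending (ties by `record_id`), truncated
#' to `top_n`, and scores below `cutoff` are dropped.
#'
#' @param index An [build_index()] object.
#' @param probe A one-row cleaned registry (the probe record).
#' @param mode `"exact"`, `"semi_exact"` or `"fuzzy"`.
#' @param top_n Maximum number of results (`>= 1`).
#' @param cutoff Minimum score; values above 1 are legal and unreachable
#'   (they yield no results).
#' @return A `data.table` with columns `record_id`, `score`.
#' @export
query_index <- function(index, probe, mode = c("fuzzy", "exact", "semi_exact"),
                        top_n = 10L, cutoff = 0) {
  .assert(inherits(index, "inverted_index"), "`index` must be an inverted_index")
  mode <- match.arg(mode)
  .assert(top_n >= 1, "`top_n` must be >= 1")
  # cutoffs above 1 are legal and simply unreachable (zero results)
  .assert(cutoff >= 0, "`cutoff` must be non-negative")
  probe <- data.table::as.data.table(probe)
  .assert(nrow(probe) == 1, "`probe` must be a single record")
  p <- as.list(probe)
  tokens <- tokenize_record(probe, index$char_bigrams)
  empty <- data.table::data.table(record_id = character(0),
                                  score = numeric(0))
  cand <- .gather_candidates(tokens, index)
  if (!length(cand)) return(empty)
  rec <- index$records[cand]
  if (mode == "exact") {
    ok <- .attr_agrees(p, rec, "full_name") &
      .attr_agrees(p, rec, "mother_name") &
      .attr_agrees(p, rec, "birth_date") &
      .attr_agrees(p, rec, "sex") &
      .attr_agrees(p, rec, "municipality_code")
    res <- data.table::data.table(record_id = rec$record_id[ok], score = 1)
    data.table::setorder(res, record_id)
  } else if (mode == "semi_exact") {
    if (is.na(p$birth_date) || is.na(p$municipality_code)) return(empty)
    ok <- !is.na(rec$birth_date) & rec$birth_date == p$birth_date &
      !is.na(rec$municipality_code) &
      rec$municipality_code == p$municipality_code
    if (!any(ok)) return(empty)
    pv <- .probe_vector(tokens, index$vocab, index$N)
    s <- if (is.null(pv)) rep(0, sum(ok)) else {
      as.vector(index$mat[cand[ok], pv$j, drop = FALSE] %*% pv$x)
    }
    res <- data.table::data.table(record_id = rec$record_id[ok],
                                  score = pmin(1, pmax(0, s)))
  } else {
    pv <- .probe_vector(tokens, index$vocab, index$N)
    if (is.null(pv)) return(empty)
    s <- as.vector(index$mat[cand, pv$j, drop = FALSE] %*% pv$x)
    res <- data.table::data.table(record_id = rec$record_id,
                                  score = pmin(1, pmax(0, s)))
  }
  data.table::setorderv(res, c("score", "record_id"), order = c(-1L, 1L))
  res <- res[score >= cutoff]
  utils::head(res, top_n)
}

#' Link two registries through the inverted index
#'
#' Each left record is probed against the indexed right registry with the
#' mode schedule in order, stopping at the first mode that yields a
#' non-empty result. The retrieved candidates of all probes are then
#' resolved one-to-one greedily in descending score order (ties by
#' `(left_id, right_id)`), exactly as in the Bloom linker: each left
#' record keeps its best candidate that is still free, so a record taken
#' by a higher-scoring probe frees the loser to fall back to its next
#' candidate instead of going unlinked.
#'
#' @param left Cleaned left registry (the probes).
#' @param right Cleaned right registry, or a prebuilt [build_index()] of it.
#' @param schedule Ordered character vector of query modes; the default
#'   `c("exact", "semi_exact", "fuzzy")` tries the cheapest, most
#'   restrictive mode first.
#' @param top_n,cutoff Passed to [query_index()].
#' @param char_bigrams Passed to [build_index()] when `right` is a
#'   registry rather than a prebuilt index.
#' @return A `data.table` of links: `left_id`, `right_id`, `score`, `mode`,
#'   one-to-one resolved.
#' @export
link_by_index <- function(left, right,
                          schedule = c("exact", "semi_exact", "fuzzy"),
                          top_n = 10L, cutoff = 0, char_bigrams = FALSE) {
  .assert(all(schedule %in% c("exact", "semi_exact", "fuzzy")),
          "unknown query mode in schedule")
  .assert(length(schedule) >= 1, "schedule must name at least one mode")
  index <- if (inherits(right, "inverted_index")) right else
    build_index(right, char_bigrams)
  left <- data.table::as.data.table(left)
  n <- nrow(left)
  res_list <- vector("list", n)
  for (i in seq_len(n)) {
    probe <- left[i]
    for (mode in schedule) {
      res <- query_index(index, probe, mode, top_n = top_n, cutoff = cutoff)
      if (nrow(res)) {
        res_list[[i]] <- data.table::data.table(left_id = probe$record_id,
                                                right_id = res$record_id,
                                                score = res$score,
                                                mode = mode)
        break
      }
    }
  }
  pairs <- data.table::rbindlist(res_list)
  if (!nrow(pairs)) return(
    data.table::data.table(left_id = character(0), right_id = character(0),
                           score = numeric(0), mode = character(0)))
  data.table::setorderv(pairs, c("score", "left_id", "right_id"),
                        order = c(-1L, 1L, 1L))
  lf <- factor(pairs$left_id); rf <- factor(pairs$right_id)
  li <- as.integer(lf); ri <- as.integer(rf)
  taken_l <- logical(nlevels(lf)); taken_r <- logical(nlevels(rf))
  keep <- logical(nrow(pairs))
  for (idx in seq_len(nrow(pairs))) {
    if (!taken_l[li[idx]] && !taken_r[ri[idx]]) {
      keep[idx] <- TRUE
      taken_l[li[idx]] <- TRUE
      taken_r[ri[idx]] <- TRUE
    }
  }
  pairs[keep]
}

#' Persist an inverted index as JSON lines
#'
#' One line per token: `{"token": ..., "df": ..., "postings": [[record_idx,
#' tf], ...]}`. For inspection and audit, not a performance format.
#'
#' @param index An `inverted_index`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_index_jsonl <- function(index, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (tok in index$vocab$token) {
    p <- index$postings[[tok]]
    line <- jsonlite::toJSON(list(token = tok,
                                  df = index$vocab$df[
                                    index$vocab$token == tok],
                                  postings = unname(as.matrix(p))),
                             auto_unbox = TRUE)
    writeLines(line, con)
  }
  invisible(path)
}
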