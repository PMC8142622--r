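# Privacy-preserving probabilistic linkage: predicate blocking,
# bigram -> Bloom-filter field encoding, Dice similarity on the bit
# vectors, weighted composite scores, threshold classification with
# greedy one-to-one resolution.

#' Bloom-filter encoding parameters
#'
#' Parameters for the per-field bigram Bloom encodings and the composite
#' score. Each scored field gets its own `m`-bit filter; every bigram sets
#' `k` bits chosen by double hashing (two independent polynomial base
#' hashes `h1`, `h2`; bit `i` is `(h1 + i * h2) mod m`), salted per field so
#' the same bigram sets different bits in different fields. Defaults
#' (`m = 128`, `k = 3`) follow standard privacy-preserving record-linkage
#' practice. Non-name attributes (birth date, sex, municipality code) are
#' scored by exact agreement in `{0, 1}` rather than by bigram similarity.
#'
#' @param m Filter length in bits (`>= 8`).
#' @param k Number of hash functions (`>= 1`).
#' @param padding If `TRUE`, tokens are wrapped in the boundary symbol `_`
#'   before bigram extraction.
#' @param weights Non-negative per-field weights for the composite score;
#'   normalized to sum to 1. For a pair, weights are renormalized over the
#'   fields present in both records.
#' @return An object of class `bloom_params`.
#' @export
#' @examples
#' bloom_params(m = 64, k = 2)
bloom_params <- function(m = 128L, k = 3L, padding = TRUE,
                         weights = c(full_name = 0.3, mother_name = 0.2,
                                     birth_date = 0.2, sex = 0.1,
                                     municipality_code = 0.2)) {
  .assert(m >= 8, "`m` must be >= 8")
  .assert(k >= 1, "`k` must be >= 1")
  .assert(all(weights >= 0) && sum(weights) > 0,
          "weights must be non-negative and not all zero")
  .assert(all(c("full_name", "mother_name", "birth_date", "sex",
                "municipality_code") %in% names(weights)),
          "weights must name all five scored fields")
  structure(list(m = as.integer(m), k = as.integer(k),
                 padding = isTRUE(padding),
                 weights = weights / sum(weights)),
            class = "bloom_params")
}

#' @export
print.bloom_params <- function(x, ...) {
  cat("<bloom_params> m =", x$m, " k =", x$k,
      " padding =", x$padding, "\n  weights:",
      paste(names(x$weights), round(x$weights, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Character bigrams of a token
#'
#' @param token A normalized string.
#' @param padding If `TRUE`, the token is wrapped with the boundary symbol
#'   `_` on both sides, so `"ANA"` yields `"_A" "AN" "NA" "A_"`.
#' @return Character vector of consecutive 2-character substrings (a
#'   multiset: repeats retained); empty input gives an empty vector.
#' @export
#' @examples
#' bigrams("ANA")
#' bigrams("ANA", padding = FALSE)
bigrams <- function(token, padding = TRUE) {
  if (is.na(token) || nchar(token) == 0) return(character(0))
  if (padding) token <- paste0("_", token, "_")
  n <- nchar(token)
  if (n < 2) return(character(0))
  substring(token, 1:(n - 1), 2:n)
}

# Precompute the k bit indices of every bigram over the normalized
# alphabet (A-Z, space, boundary "_") for one (params, salt). 784 bigrams
# x k indices; encoding a field is then a table lookup.
.bloom_bit_table <- function(params, salt) {
  chars <- c(LETTERS, " ", "_")
  grams <- as.vector(outer(chars, chars, paste0))
  salted <- paste0(salt, "\r", grams)
  h1 <- .hash_strings(salted, mult = 33, init = 5381)
  h2 <- .hash_strings(salted, mult = 53, init = 77)
  h2 <- bitwOr(as.integer(h2 %% params$m), 1L)  # odd => full cycle for 2^j m
  idx <- lapply(seq_along(grams), function(g) {
    as.integer((h1[g] + (0:(params$k - 1)) * h2[g]) %% params$m)
  })
  names(idx) <- grams
  idx
}

.POP8 <- vapply(0:255, function(b) sum(bitwAnd(b, 2^(0:7)) > 0), integer(1))

# Encode a character vector of normalized field values into byte-packed
# Bloom filters: an n x ceiling(m/8) integer matrix plus per-row popcounts.
.encode_field_matrix <- function(values, params, salt) {
  tab <- .bloom_bit_table(params, salt)
  nb <- ceiling(params$m / 8)
  n <- length(values)
  bytes <- matrix(0L, nrow = n, ncol = nb)
  pop <- integer(n)
  for (i in seq_len(n)) {
    v <- values[i]
    if (is.na(v) || nchar(v) == 0) next
    bg <- bigrams(v, params$padding)
    bits <- unique(unlist(tab[unique(bg)], use.names = FALSE))
    if (is.null(bits)) next
    pop[i] <- length(bits)
    byte <- bits %/% 8L + 1L
    val <- bitwShiftL(1L, bits %% 8L)
    acc <- rowsum(val, byte)
    bytes[i, as.integer(rownames(acc))] <- as.integer(acc[, 1])
  }
  list(bytes = bytes, pop = pop)
}

#' Encode a field value as a Bloom filter
#'
#' @param value Normalized field value (one string).
#' @param params A [bloom_params()].
#' @param salt Per-field salt string; the same value encodes differently
#'   under different salts.
#' @return An object of class `bloom_vector` with elements `bits` (logical
#'   vector of length `m`) and `set_count`. Empty or `NA` input encodes to
#'   the all-zero vector.
#' @export
#' @examples
#' v <- encode_bloom("ANA", bloom_params(m = 64, k = 2), "full_name")
#' v$set_count
encode_bloom <- function(value, params = bloom_params(), salt = "") {
  .assert(length(value) == 1, "`value` must be a single string")
  enc <- .encode_field_matrix(value, params, salt)
  bits <- logical(params$m)
  if (enc$pop[1] > 0) {
    idx <- unlist(lapply(seq_len(ncol(enc$bytes)), function(j) {
      b <- enc$bytes[1, j]
      which(bitwAnd(b, 2L^(0:7)) > 0) - 1L + (j - 1L) * 8L
    }))
    bits[idx + 1L] <- TRUE
  }
  structure(list(bits = bits, m = params$m, set_count = sum(bits)),
            class = "bloom_vector")
}

#' @export
print.bloom_vector <- function(x, ...) {
  cat("<bloom_vector> m =", x$m, " set bits =", x$set_count, "\n")
  invisible(x)
}

#' Dice similarity of two Bloom vectors
#'
#' `2 |a AND b| / (|a| + |b|)` over set bits. Two all-zero vectors carry no
#' information: the result is 0 with attribute `uninformative = TRUE`.
#'
#' @param a,b `bloom_vector` objects of equal length.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' p <- bloom_params(m = 64, k = 2)
#' dice(encode_bloom("ANA", p, "s"), encode_bloom("ANA", p, "s"))  # 1
dice <- function(a, b) {
  .assert(inherits(a, "bloom_vector") && inherits(b, "bloom_vector"),
          "`a` and `b` must be bloom_vector objects")
  .assert(a$m == b$m, "Bloom vectors must have equal length")
  denom <- a$set_count + b$set_count
  if (denom == 0) return(structure(0, uninformative = TRUE))
  2 * sum(a$bits & b$bits) / denom
}

# Vectorized Dice over byte-packed encodings for row index pairs (i, j).
.dice_pairs <- function(encL, encR, i, j) {
  A <- encL$bytes[i, , drop = FALSE]
  B <- encR$bytes[j, , drop = FALSE]
  inter <- rowSums(matrix(.POP8[bitwAnd(A, B) + 1L], nrow = nrow(A)))
  denom <- encL$pop[i] + encR$pop[j]
  out <- ifelse(denom > 0, 2 * inter / denom, NA_real_)
  # a pair where either side is empty carries no name signal
  out[encL$pop[i] == 0 | encR$pop[j] == 0] <- NA_real_
  out
}

#' Blocking predicates
#'
#' A blocking predicate maps a cleaned record to a block label; candidate
#' pairs are formed within blocks. Records whose predicate inputs are
#' missing receive no label from that predicate (they are never globbed
#' into one giant block). The default set is: municipality code; birth
#' year; first two letters of the first name plus sex.
#'
#' @param name Predicate name.
#' @param fn Function from a cleaned registry to a character vector of
#'   labels (`NA` = no label).
#' @return A `blocking_predicate`; `default_predicates()` returns the
#'   default list of three.
#' @export
blocking_predicate <- function(name, fn) {
  .assert(is.character(name) && is.function(fn),
          "need a name and a label function")
  structure(list(name = name, fn = fn), class = "blocking_predicate")
}

#' @rdname blocking_predicate
#' @export
default_predicates <- function() {
  list(
    blocking_predicate("municipality", function(reg) reg$municipality_code),
    blocking_predicate("birth_year", function(reg) {
      ifelse(is.na(reg$birth_date), NA_character_,
             substr(reg$birth_date, 1, 4))
    }),
    blocking_predicate("name_initials_sex", function(reg) {
      ok <- !is.na(reg$full_name) & nchar(reg$full_name) >= 2 &
        reg$sex %in% c("M", "F")
      ifelse(ok, paste0(substr(reg$full_name, 1, 2), ":", reg$sex),
             NA_character_)
    })
  )
}

#' Build the candidate pair set by predicate blocking
#'
#' The candidate set is the union over predicates of all within-block
#' cross pairs between the two registries; each pair appears once.
#'
#' @param left,right Cleaned registries.
#' @param predicates Non-empty list of [blocking_predicate()]s. An empty
#'   list is rejected: it would silently force an all-pairs comparison.
#' @return A `data.table` with columns `left_id`, `right_id` (and row
#'   indices `left_idx`, `right_idx` into the input registries).
#' @export
build_blocks <- function(left, right, predicates = default_predicates()) {
  .assert(length(predicates) > 0,
          "empty predicate list: blocking must be explicit")
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  pieces <- lapply(predicates, function(p) {
    ll <- p$fn(left)
    rl <- p$fn(right)
    L <- data.table::data.table(left_idx = seq_len(nrow(left)), label = ll)
    R <- data.table::data.table(right_idx = seq_len(nrow(right)), label = rl)
    L <- L[!is.na(label)]
    R <- R[!is.na(label)]
    merge(L, R, by = "label", allow.cartesian = TRUE)[, .(left_idx, right_idx)]
  })
  cand <- unique(data.table::rbindlist(pieces))
  cand[, left_id := left$record_id[left_idx]]
  cand[, right_id := right$record_id[right_idx]]
  cand[]
}

#' Score candidate pairs
#'
#' Computes per-field similarities -- bigram Bloom Dice for `full_name` and
#' `mother_name`, exact agreement in `{0, 1}` for `birth_date`, `sex` and
#' `municipality_code` -- and the composite score: the weighted mean over
#' fields present in both records, with weights renormalized over the
#' present fields. Output is sorted by composite score descending, ties
#' broken by `(left_id, right_id)`.
#'
#' @param left,right Cleaned registries.
#' @param candidates Candidate pairs from [build_blocks()].
#' @param params A [bloom_params()].
#' @return A `scored_pairs` `data.table` with per-field score columns,
#'   `score` (composite) and `classification` (`"unclassified"`).
#' @export
score_candidates <- function(left, right, candidates,
                             params = bloom_params()) {
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  cand <- data.table::as.data.table(candidates)
  if (!"left_idx" %in% names(cand)) {
    cand[, left_idx := match(left_id, left$record_id)]
    cand[, right_idx := match(right_id, right$record_id)]
  }
  encL_name <- .encode_field_matrix(left$full_name, params, "full_name")
  encR_name <- .encode_field_matrix(right$full_name, params, "full_name")
  encL_mot <- .encode_field_matrix(left$mother_name, params, "mother_name")
  encR_mot <- .encode_field_matrix(right$mother_name, params, "mother_name")
  i <- cand$left_idx; j <- cand$right_idx
  agree <- function(a, b) {
    out <- as.numeric(a == b)
    out[is.na(a) | is.na(b)] <- NA_real_
    out
  }
  sexL <- ifelse(left$sex %in% c("M", "F"), left$sex, NA_character_)
  sexR <- ifelse(right$sex %in% c("M", "F"), right$sex, NA_character_)
  sc <- data.table::data.table(
    left_id = cand$left_id, right_id = cand$right_id,
    score_full_name = .dice_pairs(encL_name, encR_name, i, j),
    score_mother_name = .dice_pairs(encL_mot, encR_mot, i, j),
    score_birth_date = agree(left$birth_date[i], right$birth_date[j]),
    score_sex = agree(sexL[i], sexR[j]),
    score_municipality_code = agree(left$municipality_code[i],
                                    right$municipality_code[j])
  )
  w <- params$weights
  fields <- c("full_name", "mother_name", "birth_date", "sex",
              "municipality_code")
  S <- as.matrix(sc[, paste0("score_", fields), with = FALSE])
  W <- matrix(w[fields], nrow = nrow(S), ncol = length(fields), byrow = TRUE)
  W[is.na(S)] <- 0
  num <- rowSums(S * W, na.rm = TRUE)
  den <- rowSums(W)
  sc[, score := ifelse(den > 0, num / den, 0)]
  sc[, classification := "unclassified"]
  data.table::setorderv(sc, c("score", "left_id", "right_id"),
                        order = c(-1L, 1L, 1L))
  data.table::setattr(sc, "class",
                      c("scored_pairs", class(sc)))
  sc[]
}

#' Classify scored pairs at a cut-off with one-to-one resolution
#'
#' Pairs with composite score at or above `cutoff` are provisionally
#' linked; the provisional links are then resolved one-to-one greedily in
#' descending score order (ties by `(left_id, right_id)`): a pair is
#' accepted unless its left or right record is already taken. Accepted
#' pairs are classified `linked`, everything else `not_linked`.
#'
#' @param scored Output of [score_candidates()].
#' @param cutoff Threshold in `[0, 1]`.
#' @return The scored table with `classification` filled in. The accepted
#'   links are `links(x)`.
#' @export
classify <- function(scored, cutoff) {
  .assert(is.numeric(cutoff) && cutoff >= 0 && cutoff <= 1,
          "`cutoff` must be in [0,1]")
  sc <- data.table::copy(data.table::as.data.table(scored))
  data.table::setorderv(sc, c("score", "left_id", "right_id"),
                        order = c(-1L, 1L, 1L))
  sc[, classification := "not_linked"]
  cand <- which(sc$score >= cutoff)
  if (length(cand)) {
    lf <- factor(sc$left_id[cand])
    rf <- factor(sc$right_id[cand])
    li <- as.integer(lf); ri <- as.integer(rf)
    taken_l <- logical(nlevels(lf)); taken_r <- logical(nlevels(rf))
    keep <- logical(length(cand))
    for (idx in seq_along(cand)) {
      a <- li[idx]; b <- ri[idx]
      if (!taken_l[a] && !taken_r[b]) {
        keep[idx] <- TRUE
        taken_l[a] <- TRUE
        taken_r[b] <- TRUE
      }
    }
    sc[cand[keep], classification := "linked"]
  }
  data.table::setattr(sc, "class", c("scored_pairs", "data.table",
                                     "data.frame"))
  sc[]
}

#' @rdname classify
#' @param x A classified `scored_pairs` table.
#' @export
links <- function(x) {
  data.table::as.data.table(x)[classification == "linked"]
}

#' Bloom-filter linkage, end to end
#'
#' Blocks, scores and classifies in one call.
#'
#' @inheritParams score_candidates
#' @inheritParams classify
#' @param predicates Blocking predicates.
#' @return A classified `scored_pairs` table (see [classify()]).
#' @export
link_bloom <- function(left, right, cutoff, params = bloom_params(),
                       predicates = default_predicates()) {
  cand <- build_blocks(left, right, predicates)
  scored <- score_candidates(left, right, cand, params)
  classify(scored, cutoff)
}
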