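test_that("bigram extraction follows the padding definition", {
  expect_setequal(bigrams("ANA"), c("_A", "AN", "NA", "A_"))
  expect_identical(bigrams("ANA", padding = FALSE), c("AN", "NA"))
  expect_identical(bigrams("", padding = TRUE), character(0))
  expect_identical(bigrams(NA_character_), character(0))
  # multiset semantics: repeated bigrams are retained
  expect_identical(bigrams("AAA", padding = FALSE), c("AA", "AA"))
})

test_that("Bloom encoding matches an independent double-hashing oracle", {
  params <- bloom_params(m = 64, k = 2)
  v <- encode_bloom("ANA", params, "full_name")
  expect_lte(v$set_count, 8)  # 4 padded bigrams x 2 hashes, minus collisions
  expect_gte(v$set_count, 1)
  expect_identical(v$bits, encode_bloom("ANA", params, "full_name")$bits)
  # different salt, different bits
  expect_false(identical(v$bits, encode_bloom("ANA", params, "mother")$bits))

  zero <- encode_bloom("", params, "full_name")
  expect_equal(zero$set_count, 0)
  expect_true(all(!zero$bits))

  # oracle: recompute the bit set from scratch for several tokens
  for (token in c("ANA", "JOSE", "MARIA DA SILVA")) {
    bits <- logical(params$m)
    for (bg in unique(bigrams(token, padding = TRUE))) {
      h1 <- oracle_hash(paste0("full_name", "\r", bg), 33, 5381)
      h2 <- bitwOr(as.integer(oracle_hash(paste0("full_name", "\r", bg),
                                          53, 77) %% params$m), 1L)
      for (i in 0:(params$k - 1)) bits[(h1 + i * h2) %% params$m + 1] <- TRUE
    }
    enc <- encode_bloom(token, params, "full_name")
    expect_identical(enc$bits, bits)
    expect_equal(enc$set_count, sum(bits))
  }
})

test_that("Dice similarity is exact on all 4-bit vector pairs", {
  mk <- function(code) {
    bits <- as.logical(bitwAnd(code, 2^(0:3)))
    structure(list(bits = bits, m = 4L, set_count = sum(bits)),
              class = "bloom_vector")
  }
  for (a in 0:15) for (b in 0:15) {
    pa <- sum(as.logical(bitwAnd(a, 2^(0:3))))
    pb <- sum(as.logical(bitwAnd(b, 2^(0:3))))
    inter <- sum(as.logical(bitwAnd(bitwAnd(a, b), 2^(0:3))))
    expected <- if (pa + pb == 0) 0 else 2 * inter / (pa + pb)
    expect_equal(as.numeric(dice(mk(a), mk(b))), expected)
  }
  # hand example: 1110 vs 0110 -> 2*2 / (3+2) = 0.8
  v1 <- structure(list(bits = c(TRUE, TRUE, TRUE, FALSE), m = 4L,
                       set_count = 3L), class = "bloom_vector")
  v2 <- structure(list(bits = c(FALSE, TRUE, TRUE, FALSE), m = 4L,
                       set_count = 2L), class = "bloom_vector")
  expect_equal(dice(v1, v2), 0.8)
  expect_equal(dice(v2, v1), 0.8)
  # both empty: 0 with the uninformative marker
  z <- structure(list(bits = rep(FALSE, 4), m = 4L, set_count = 0L),
                 class = "bloom_vector")
  dz <- dice(z, z)
  expect_equal(as.numeric(dz), 0)
  expect_true(attr(dz, "uninformative"))
  # unequal lengths rejected
  v8 <- encode_bloom("ANA", bloom_params(m = 8, k = 1), "s")
  expect_error(dice(v1, v8), "equal length")
})

test_that("blocking builds the union of within-block cross pairs", {
  left <- make_clean_records(c("Ana A", "Bia B"),
                             municipality_code = c("1111111", "2222222"),
                             id_prefix = "L")
  right <- make_clean_records("Caio C", municipality_code = "1111111",
                              id_prefix = "R")
  mun_only <- list(blocking_predicate("mun", function(r) r$municipality_code))
  cand <- build_blocks(left, right, mun_only)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$left_id, "L001")
  expect_identical(cand$right_id, "R001")

  # two predicates both containing the pair: it appears once
  two <- c(mun_only,
           list(blocking_predicate("const", function(r)
             rep("all", nrow(r)))))
  cand2 <- build_blocks(left, right, two)
  expect_equal(nrow(cand2), 2)  # (L1,R1) once, (L2,R1) via const only
  expect_equal(anyDuplicated(cand2[, .(left_id, right_id)]), 0)

  # 10x10 in one block -> 100 candidates
  l10 <- make_clean_records(sprintf("P %02d", 1:10),
                            municipality_code = "1111111", id_prefix = "L")
  r10 <- make_clean_records(sprintf("Q %02d", 1:10),
                            municipality_code = "1111111", id_prefix = "R")
  expect_equal(nrow(build_blocks(l10, r10, mun_only)), 100)

  # missing predicate input yields no label, not a shared block
  lmiss <- make_clean_records(c("Ana A", "Bia B"),
                              municipality_code = c(NA, "3333333"),
                              id_prefix = "L")
  rmiss <- make_clean_records("Caio C", municipality_code = NA,
                              id_prefix = "R")
  expect_equal(nrow(build_blocks(lmiss, rmiss, mun_only)), 0)

  expect_error(build_blocks(left, right, list()), "explicit")
})

test_that("composite scores renormalize weights over present fields", {
  params <- bloom_params()
  # identical on all fields -> composite 1, each field 1
  l <- clean_registry(generate_population(5, seed = 81))
  cand <- data.table::data.table(left_id = l$record_id,
                                 right_id = l$record_id)
  sc <- score_candidates(l, l, cand, params)
  expect_true(all(abs(sc$score - 1) < 1e-12))
  expect_true(all(sc$score_full_name == 1))

  # all scored fields disagreeing maximally -> composite 0
  a <- make_clean_records("AAAA BBBB", sex = "F", mother_name = "CCCC",
                          birth_date = "1990-01-01",
                          municipality_code = "1111111", id_prefix = "L")
  b <- make_clean_records("XXXX YYYY", sex = "M", mother_name = "ZZZZ",
                          birth_date = "1991-02-02",
                          municipality_code = "2222222", id_prefix = "R")
  # wide filters so hash collisions cannot blur the disagreement
  sc0 <- score_candidates(a, b, data.table::data.table(left_id = "L001",
                                                       right_id = "R001"),
                          bloom_params(m = 1024, k = 2))
  expect_lt(sc0$score, 0.05)

  # missing fields drop out and weights renormalize
  b2 <- data.table::copy(a)
  b2$record_id <- "R001"
  b2$birth_date <- NA_character_
  sc1 <- score_candidates(a, b2,
                          data.table::data.table(left_id = "L001",
                                                 right_id = "R001"), params)
  expect_true(is.na(sc1$score_birth_date))
  expect_equal(sc1$score, 1)  # all present fields agree perfectly
})

test_that("composite equals a brute-force recomputation on random pairs", {
  params <- bloom_params(m = 64, k = 2)
  fx <- small_linked_fixture(n = 120, seed = 91,
                             config = corruption_config(seed = 92))
  cand <- build_blocks(fx$left, fx$right)
  set.seed(93)
  cand <- cand[sample(.N, min(1000, .N))]
  sc <- score_candidates(fx$left, fx$right, cand, params)

  # independent oracle: per-field bigram sets hashed from scratch,
  # Dice on the sets, weighted mean over present fields
  field_bits <- function(value, salt, m, k) {
    bits <- integer(0)
    if (is.na(value) || !nzchar(value)) return(bits)
    for (bg in unique(bigrams(value, padding = TRUE))) {
      h1 <- oracle_hash(paste0(salt, "\r", bg), 33, 5381)
      h2 <- bitwOr(as.integer(oracle_hash(paste0(salt, "\r", bg),
                                          53, 77) %% m), 1L)
      bits <- c(bits, (h1 + (0:(k - 1)) * h2) %% m)
    }
    unique(bits)
  }
  w <- params$weights
  for (i in seq_len(nrow(sc))) {
    lrec <- fx$left[record_id == sc$left_id[i]]
    rrec <- fx$right[record_id == sc$right_id[i]]
    s <- c(full_name = NA_real_, mother_name = NA_real_,
           birth_date = NA_real_, sex = NA_real_,
           municipality_code = NA_real_)
    for (f in c("full_name", "mother_name")) {
      ba <- field_bits(lrec[[f]], f, params$m, params$k)
      bb <- field_bits(rrec[[f]], f, params$m, params$k)
      if (length(ba) && length(bb))
        s[f] <- 2 * length(intersect(ba, bb)) / (length(ba) + length(bb))
    }
    for (f in c("birth_date", "municipality_code")) {
      if (!is.na(lrec[[f]]) && !is.na(rrec[[f]]))
        s[f] <- as.numeric(lrec[[f]] == rrec[[f]])
    }
    if (lrec$sex %in% c("M", "F") && rrec$sex %in% c("M", "F"))
      s["sex"] <- as.numeric(lrec$sex == rrec$sex)
    present <- !is.na(s)
    expected <- if (any(present))
      sum(w[present] * s[present]) / sum(w[present]) else 0
    expect_equal(sc$score[i], expected, tolerance = 1e-12)
  }
})

test_that("classification thresholds then resolves one-to-one greedily", {
  sc <- data.table::data.table(
    left_id = c("L1", "L1", "L2"),
    right_id = c("R1", "R2", "R3"),
    score = c(0.95, 0.90, 0.40)
  )
  out <- classify(sc, 0.8)
  lk <- links(out)
  expect_equal(nrow(lk), 1)
  expect_identical(lk$right_id, "R1")

  disjoint <- data.table::data.table(
    left_id = c("L1", "L2", "L3"), right_id = c("R1", "R2", "R3"),
    score = c(0.95, 0.85, 0.40))
  expect_equal(nrow(links(classify(disjoint, 0.8))), 2)
  expect_equal(nrow(links(classify(disjoint, 0.99))), 0)

  # contested right record: greedy trace -- (L2,R1,.95) accepted, then
  # (L1,R1) skipped (R1 taken), then (L2,R2) skipped (L2 taken)
  contest <- data.table::data.table(
    left_id = c("L1", "L2", "L2"), right_id = c("R1", "R1", "R2"),
    score = c(0.9, 0.95, 0.85))
  lk2 <- links(classify(contest, 0.5))
  expect_equal(nrow(lk2), 1)
  expect_identical(lk2$left_id, "L2")
  expect_identical(lk2$right_id, "R1")
})

test_that("lowering the cutoff never reduces the pre-resolution link count", {
  fx <- small_linked_fixture(n = 80, seed = 101,
                             config = corruption_config(seed = 102))
  sc <- score_candidates(fx$left, fx$right, build_blocks(fx$left, fx$right))
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(ct) sum(sc$score >= ct), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blocking recall is total when blocking attributes are clean", {
  cfg <- corruption_config(
    field_probs = c(full_name = 0, mother_name = 0.5),
    accent_loss_prob = 0, date_digit_swap_prob = 0,
    missing_probs = c(mother_name = 0.3), seed = 112)
  fx <- small_linked_fixture(n = 150, seed = 111, config = cfg)
  cand <- build_blocks(fx$left, fx$right)
  ckey <- paste(cand$left_id, cand$right_id)
  gkey <- paste(fx$gold$left_id, fx$gold$right_id)
  expect_true(all(gkey %in% ckey))
})

test_that("scoring is deterministic end to end", {
  fx <- small_linked_fixture(n = 60, seed = 121,
                             config = corruption_config(seed = 122))
  s1 <- score_candidates(fx$left, fx$right, build_blocks(fx$left, fx$right))
  s2 <- score_candidates(fx$left, fx$right, build_blocks(fx$left, fx$right))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
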