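toy_registry <- function(names) {
  make_clean_records(names, sex = "unknown", id_prefix = "T")
}

test_that("tokenization separates fields and keeps multiplicity", {
  r <- make_clean_records("ANA MARIA", mother_name = "RITA",
                          birth_date = "1990-01-02",
                          municipality_code = "2927408", sex = "F")
  toks <- tokenize_record(r)
  expect_setequal(toks, c("ANA", "MARIA", "M:RITA", "D:1990-01-02",
                          "Y:1990", "MD:01-02", "S:F", "C:2927408"))

  r2 <- make_clean_records(NA_character_, sex = "M",
                           birth_date = "1990-01-02")
  expect_setequal(tokenize_record(r2), c("D:1990-01-02", "Y:1990",
                                         "MD:01-02", "S:M"))

  r3 <- make_clean_records("JOSE JOSE", sex = "unknown")
  expect_equal(sum(tokenize_record(r3) == "JOSE"), 2)
})

test_that("index postings and document frequencies are consistent", {
  reg <- clean_registry(generate_population(60, seed = 131))
  idx <- build_index(reg)
  expect_equal(idx$N, 60)
  for (tok in idx$vocab$token) {
    expect_equal(idx$vocab[token == tok]$df,
                 nrow(idx$postings[[tok]]))
  }
  # a token is in the vocabulary iff some record contains it
  all_tokens <- unlist(lapply(seq_len(60), function(i)
    tokenize_record(reg[i])))
  expect_setequal(idx$vocab$token, unique(all_tokens))
  expect_error(build_index(reg[0]), "empty")
})

test_that("TF-IDF cosine matches the hand-computed toy corpus", {
  reg <- toy_registry(c("A B", "A C", "D"))
  idx <- build_index(reg)
  # weights: w(t) = (1 + ln tf) * ln(1 + N/df); N = 3, df(A) = 2,
  # df(B) = df(C) = df(D) = 1, all tf = 1
  wA <- log(1 + 3 / 2)
  wB <- log(1 + 3)
  expected <- wA^2 / (wA^2 + wB^2)  # probe {A,B} vs doc {A,C}, wC = wB
  expect_equal(tfidf_score(c("A", "B"), "T002", idx), expected,
               tolerance = 1e-12)
  expect_equal(tfidf_score(c("A", "B"), "T001", idx), 1, tolerance = 1e-12)
  expect_equal(tfidf_score(c("A", "B"), "T003", idx), 0)
  expect_error(tfidf_score("A", "nope", idx), "not in index")
})

test_that("TF-IDF scoring equals brute force and is symmetric on a corpus", {
  reg <- clean_registry(generate_population(40, seed = 141))
  idx <- build_index(reg)
  toks <- lapply(seq_len(40), function(i) tokenize_record(reg[i]))
  # independent oracle: dense tf-idf vectors and cosine, from the token
  # multisets alone
  vocab <- sort(unique(unlist(toks)))
  dfv <- vapply(vocab, function(t)
    sum(vapply(toks, function(x) t %in% x, logical(1))), numeric(1))
  vec <- function(tk) {
    tf <- table(tk)
    v <- numeric(length(vocab))
    j <- match(names(tf), vocab)
    v[j] <- (1 + log(as.numeric(tf))) * log(1 + 40 / dfv[j])
    v / sqrt(sum(v^2))
  }
  V <- vapply(toks, vec, numeric(length(vocab)))
  set.seed(142)
  for (pair in replicate(60, sample(40, 2), simplify = FALSE)) {
    i <- pair[1]; j <- pair[2]
    expected <- sum(V[, i] * V[, j])
    expect_equal(tfidf_score(toks[[i]], reg$record_id[j], idx), expected,
                 tolerance = 1e-10)
    expect_equal(tfidf_score(toks[[j]], reg$record_id[i], idx), expected,
                 tolerance = 1e-10)
  }
})

test_that("every record retrieves itself at rank 1 in every mode", {
  reg <- deduplicate(clean_registry(generate_population(50, seed = 151)))$registry
  for (cb in c(FALSE, TRUE)) {
    idx <- build_index(reg, char_bigrams = cb)
    set.seed(152)
    for (i in sample(nrow(reg), 12)) {
      for (mode in c("exact", "semi_exact", "fuzzy")) {
        res <- query_index(idx, reg[i], mode, top_n = 3)
        if (mode == "semi_exact" &&
            (is.na(reg$birth_date[i]) || is.na(reg$municipality_code[i])))
          next  # mode inapplicable without its exact-agreement fields
        expect_identical(res$record_id[1], reg$record_id[i])
        expect_equal(res$score[1], 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("query modes filter as specified", {
  reg <- make_clean_records(c("ANA SILVA", "ANA SILVA"),
                            birth_date = c("1990-01-01", "1991-05-05"),
                            municipality_code = "2927408", sex = "F",
                            id_prefix = "R")
  idx <- build_index(reg)
  # fuzzy probe sharing no token -> empty
  probe0 <- make_clean_records("ZZZ QQQ", sex = "unknown")
  expect_equal(nrow(query_index(idx, probe0, "fuzzy")), 0)
  # semi-exact: a date matching no record is fatal even with equal names
  probe <- make_clean_records("ANA SILVA", birth_date = "1992-09-09",
                              municipality_code = "2927408", sex = "F")
  expect_equal(nrow(query_index(idx, probe, "semi_exact")), 0)
  expect_gt(nrow(query_index(idx, probe, "fuzzy")), 0)
  # exact honors every non-missing probe attribute
  probe2 <- make_clean_records("ANA SILVA", birth_date = "1991-05-05",
                               municipality_code = "2927408", sex = "F")
  res <- query_index(idx, probe2, "exact")
  expect_identical(res$record_id, "R002")
  expect_equal(res$score, 1)
  # unreachable cutoff -> zero results, not an error
  expect_equal(nrow(query_index(idx, probe2, "fuzzy", cutoff = 1.01)), 0)
  expect_error(query_index(idx, probe2, "nonsense"))
})

test_that("fuzzy candidate gathering equals brute-force token sharing", {
  reg <- clean_registry(generate_population(35, seed = 161))
  idx <- build_index(reg)
  toks <- lapply(seq_len(35), function(i) unique(tokenize_record(reg[i])))
  for (i in c(1, 7, 20)) {
    res <- query_index(idx, reg[i], "fuzzy", top_n = 1000L)
    brute <- reg$record_id[vapply(seq_len(35), function(j)
      length(intersect(toks[[i]], toks[[j]])) > 0, logical(1))]
    expect_setequal(res$record_id, brute)
  }
})

test_that("mode results nest: exact within semi-exact within fuzzy", {
  fx <- small_linked_fixture(n = 100, seed = 171,
                             config = corruption_config(seed = 172))
  idx <- build_index(fx$right)
  set.seed(173)
  for (i in sample(nrow(fx$left), 15)) {
    probe <- fx$left[i]
    ex <- query_index(idx, probe, "exact", top_n = 1000L)
    se <- query_index(idx, probe, "semi_exact", top_n = 1000L)
    fz <- query_index(idx, probe, "fuzzy", top_n = 1000L)
    if (!is.na(probe$birth_date) && !is.na(probe$municipality_code)) {
      expect_true(all(ex$record_id %in% se$record_id))
    }
    expect_true(all(se$record_id %in% fz$record_id))
  }
})

test_that("index linkage is perfect on identical registries", {
  reg <- deduplicate(clean_registry(generate_population(80, seed = 181)))$registry
  lk <- link_by_index(reg, reg, schedule = "exact")
  expect_equal(nrow(lk), nrow(reg))
  expect_true(all(lk$score == 1))
  expect_identical(lk$left_id, lk$right_id)

  expect_equal(nrow(link_by_index(reg, reg, cutoff = 1.01)), 0)
})

test_that("corrupted records fall through the mode schedule", {
  left <- make_clean_records(
    c("ANA SILVA", "BRUNO COSTA", "CARLA DIAS", "DAVI ROCHA", "EVA LIMA"),
    sex = c("F", "M", "F", "M", "F"),
    birth_date = c("1990-01-01", "1980-02-02", "1970-03-03", "1960-04-04",
                   "1950-05-05"),
    municipality_code = "2927408", id_prefix = "L")
  right <- data.table::copy(left)
  right[, record_id := sub("^L", "R", record_id)]
  # corrupt two right-side names so exact cannot fire for them
  right$full_name[2] <- "BRUNO COSTAH"
  right$full_name[4] <- "DAVI ROCA"
  lk <- link_by_index(left, right, schedule = c("exact", "fuzzy"))
  expect_equal(nrow(lk), 5)
  m <- lk[order(left_id)]
  expect_identical(sub("^L", "R", m$left_id), m$right_id)
  expect_setequal(lk[left_id %in% c("L002", "L004")]$mode, "fuzzy")
  expect_setequal(lk[!left_id %in% c("L002", "L004")]$mode, "exact")
})
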