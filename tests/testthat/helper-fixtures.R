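# Shared fixtures: hand-built cleaned records and a memoised copy of the
# declared full-scale benchmark (generated once, reused by the acceptance
# blocks for both linkers).

make_clean_records <- function(full_name, sex = "F", mother_name = NA,
                               birth_date = NA, municipality_code = NA,
                               nis = NA, id_prefix = "X") {
  n <- length(full_name)
  data.table::data.table(
    record_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    full_name = full_name,
    sex = rep_len(sex, n),
    mother_name = rep_len(as.character(mother_name), n),
    birth_date = rep_len(as.character(birth_date), n),
    municipality_code = rep_len(as.character(municipality_code), n),
    nis = rep_len(as.character(nis), n),
    quality_flags = ""
  )
}

small_linked_fixture <- function(n = 200, overlap = 0.5, seed = 11,
                                 config = zero_corruption(seed = 12)) {
  base <- generate_population(n, seed = seed)
  d <- derive_linked_registry(base, overlap, config)
  list(left = deduplicate(clean_registry(base))$registry,
       right = deduplicate(clean_registry(d$registry))$registry,
       gold = d$gold)
}

.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.bench_cache$data)) {
    .bench_cache$data <- benchmark_registries(n = 5000L, overlap = 0.5,
                                              seed = 42L)
  }
  .bench_cache$data
}

# Independent polynomial hash, reimplemented here so Bloom-encoding tests
# do not lean on the package's own internals.
oracle_hash <- function(s, mult, init) {
  h <- init
  for (c in utf8ToInt(s)) h <- (h * mult + c) %% 2147483647
  h
}
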