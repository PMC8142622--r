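# Deterministic linkage: exact join on a unique key (NIS), and the
# two-stage strategy for birth registries -- mothers linked
# probabilistically first, children attached deterministically through
# the linked mother plus the child's own birth date (and sex), because
# newborns may not yet have a name of their own.

#' Link two registries on a unique key
#'
#' Pairs are formed only for key values that occur exactly once on both
#' sides. Missing keys never match. Keys occurring more than once on
#' either side are reported as ambiguous and produce no pairs: a "unique"
#' key that repeats is a data-quality event to surface, not to resolve
#' silently.
#'
#' @param left,right Registries (cleaned or raw; the key is compared as-is).
#' @param key_field Name of the key column (default `"nis"`).
#' @return An object of class `key_join_result`: `pairs` (`left_id`,
#'   `right_id`), `unmatched_left` (left ids without a pair), and
#'   `ambiguous` (a `data.table` of `key`, `side`, `record_id`).
#' @export
#' @examples
#' l <- data.table::data.table(record_id = c("A", "B"), nis = c("1", "2"))
#' r <- data.table::data.table(record_id = "C", nis = "1")
#' link_by_key(l, r)$pairs
link_by_key <- function(left, right, key_field = "nis") {
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  .assert(key_field %in% names(left) && key_field %in% names(right),
          paste0("unknown key field: ", key_field))
  kl <- left[[key_field]]; kr <- right[[key_field]]
  tl <- table(kl[!is.na(kl)]); tr <- table(kr[!is.na(kr)])
  amb_keys <- union(names(tl)[tl > 1], names(tr)[tr > 1])
  side_tab <- function(k, side, ids) {
    d <- data.table::data.table(k = k, side = side, record_id = ids)
    data.table::setnames(d, "k", "key")
    d[d$key %in% amb_keys]
  }
  ambiguous <- data.table::rbindlist(list(
    side_tab(kl, "left", left$record_id),
    side_tab(kr, "right", right$record_id)
  ))
  usable <- setdiff(intersect(names(tl), names(tr)), amb_keys)
  li <- match(usable, kl); ri <- match(usable, kr)
  pairs <- data.table::data.table(left_id = left$record_id[li],
                                  right_id = right$record_id[ri])
  data.table::setorder(pairs, left_id)
  structure(list(pairs = pairs,
                 unmatched_left = setdiff(left$record_id, pairs$left_id),
                 ambiguous = ambiguous[order(key, side, record_id)]),
            class = "key_join_result")
}

#' @export
print.key_join_result <- function(x, ...) {
  cat("<key_join_result>", nrow(x$pairs), "pairs,",
      length(x$unmatched_left), "unmatched left,",
      length(unique(x$ambiguous$key)), "ambiguous keys\n")
  invisible(x)
}

# Built-in stage-1 linkers for the two-stage strategy. Each returns a
# function(probes, target) -> data.table(left_id, right_id, score).
#' Stage-1 linkers for [link_births_two_stage()]
#'
#' `stage1_index()` probes a TF-IDF index of the target registry;
#' `stage1_bloom()` runs Bloom-filter linkage. Both return one-to-one
#' resolved mother links.
#'
#' @param schedule,top_n Passed to [link_by_index()].
#' @param params,predicates Passed to [link_bloom()].
#' @return A linker function `f(probes, target, cutoff)`.
#' @export
stage1_index <- function(schedule = c("exact", "semi_exact", "fuzzy"),
                         top_n = 10L) {
  function(probes, target, cutoff) {
    link_by_index(probes, target, schedule = schedule, top_n = top_n,
                  cutoff = cutoff)[, .(left_id, right_id, score)]
  }
}

#' @rdname stage1_index
#' @export
stage1_bloom <- function(params = bloom_params(),
                         predicates = default_predicates()) {
  function(probes, target, cutoff) {
    links(link_bloom(probes, target, cutoff, params,
                     predicates))[, .(left_id, right_id, score)]
  }
}

#' Two-stage linkage of a birth registry
#'
#' Stage 1 links each distinct mother appearing in the birth registry to
#' the target registry with a probabilistic linker, probing with the
#' mother's attributes (her name, birth date when carried by the births,
#' and municipality). Stage 2 then attaches each child to the linked
#' target person deterministically through the mother's identifier plus
#' the child's exact birth date (and sex, when present) -- the child's own
#' name is never used, so unnamed newborns are linkable. Children whose
#' mother fails stage 1 remain unlinked; same-date (and same-sex) children
#' of one linked mother cannot be told apart and are reported as
#' ambiguous, not linked.
#'
#' @param births Cleaned birth registry (must carry `mother_name`; the
#'   auxiliary `mother_birth_date` column is used when present).
#' @param target Cleaned target registry.
#' @param stage1 A stage-1 linker, see [stage1_index()] / [stage1_bloom()].
#' @param cutoff Stage-1 score cut-off.
#' @return An object of class `two_stage_result`: `links`
#'   (`child_id`, `target_id`, `mother_score`), `ambiguous` (child ids),
#'   `unlinked` (child ids).
#' @export
link_births_two_stage <- function(births, target, stage1 = stage1_index(),
                                  cutoff = 0.5) {
  births <- data.table::as.data.table(births)
  target <- data.table::as.data.table(target)
  .assert("mother_name" %in% names(births),
          "birth registry must carry mother_name")
  mbd <- if ("mother_birth_date" %in% names(births))
    births$mother_birth_date else rep(NA_character_, nrow(births))
  mkey <- paste(ifelse(is.na(births$mother_name), "", births$mother_name),
                ifelse(is.na(mbd), "", mbd),
                ifelse(is.na(births$municipality_code), "",
                       births$municipality_code), sep = "|")
  groups <- data.table::data.table(child_id = births$record_id, mkey = mkey)
  first <- !duplicated(mkey)
  probes <- data.table::data.table(
    record_id = paste0("MOTHER", seq_len(sum(first))),
    full_name = births$mother_name[first],
    sex = "F",
    mother_name = NA_character_,
    birth_date = mbd[first],
    municipality_code = births$municipality_code[first],
    nis = NA_character_,
    quality_flags = ""
  )
  key_of_probe <- mkey[first]
  m_links <- stage1(probes, target, cutoff)
  groups <- merge(groups,
                  data.table::data.table(mkey = key_of_probe,
                                         probe_id = probes$record_id),
                  by = "mkey", sort = FALSE)
  groups <- merge(groups,
                  m_links[, .(probe_id = left_id, target_id = right_id,
                              mother_score = score)],
                  by = "probe_id", all.x = TRUE, sort = FALSE)
  # stage 2: deterministic key (linked mother, child's birth_date, sex)
  ord <- match(groups$child_id, births$record_id)
  groups[, child_birth_date := births$birth_date[ord]]
  groups[, child_sex := births$sex[ord]]
  linked <- groups[!is.na(target_id)]
  det_key <- paste(linked$target_id,
                   ifelse(is.na(linked$child_birth_date), "",
                          linked$child_birth_date),
                   linked$child_sex, sep = "|")
  dup <- det_key %in% det_key[duplicated(det_key)]
  out_links <- linked[!dup, .(child_id, target_id, mother_score)]
  data.table::setorder(out_links, child_id)
  structure(list(links = out_links,
                 ambiguous = sort(linked$child_id[dup]),
                 unlinked = sort(groups$child_id[is.na(groups$target_id)])),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("<two_stage_result>", nrow(x$links), "children linked,",
      length(x$ambiguous), "ambiguous,", length(x$unlinked), "unlinked\n")
  invisible(x)
}
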