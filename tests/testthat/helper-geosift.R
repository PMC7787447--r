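# Shared fixtures and independent oracles for the test suite.

make_tokens <- function(surfaces, tags) {
  stopifnot(length(surfaces) == length(tags))
  tibble::tibble(
    surface = surfaces,
    normalized = normalize_text(surfaces),
    pos_tag = "X",
    ner_tag = tags
  )
}

# Small lexicon-driven tagger used across tests.
test_tagger <- function(extra = NULL) {
  lex <- tibble::tibble(
    phrase = c("Nancy", "France", "Madison", "Boston", "Seville", "Spain",
               "Massachusetts General Hospital", "University of Helsinki",
               "Smith", "Acme Inc"),
    tag = c("LOCATION", "LOCATION", "LOCATION", "LOCATION", "LOCATION",
            "LOCATION", "ORGANIZATION", "ORGANIZATION", "PERSON",
            "ORGANIZATION")
  )
  if (!is.null(extra)) lex <- dplyr::bind_rows(lex, extra)
  lexicon_tagger(lex)
}

toy_gazetteer_df <- function() {
  tibble::tibble(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7"),
    primary_name = c("San Francisco", "Springfield", "Springfield",
                     "Paris", "Paris", "New York", "Texas"),
    alternate_names = c("SF|Frisco", "", "", "", "", "NYC|Big Apple", ""),
    feature_class = c("P", "P", "P", "P", "P", "P", "A"),
    latitude = c(37.77, 39.80, 37.22, 48.85, 33.66, 40.71, 31.0),
    longitude = c(-122.42, -89.64, -93.29, 2.35, -95.56, -74.01, -100.0),
    population = c(873965, 150000, 10000, 2148000, 25000, 8336817, 29100000),
    country_code = c("US", "US", "US", "FR", "US", "US", "US"),
    admin_path = c("CA|USA", "IL|USA", "MO|USA", "Ile-de-France|France",
                   "Texas|USA", "NY|USA", "USA")
  )
}

write_toy_gazetteer <- function(path = tempfile(fileext = ".tsv"),
                                df = toy_gazetteer_df()) {
  readr::write_tsv(df, path, col_names = FALSE)
  path
}

load_toy_gazetteer <- function(df = toy_gazetteer_df()) {
  suppressMessages(load_gazetteer(write_toy_gazetteer(df = df)))
}

# ---- independent brute-force oracle for candidate assembly --------------

oracle_classes <- function(tokens, profile) {
  lower <- tolower(tokens$normalized)
  list(
    entity = tokens$ner_tag != "OTHER",
    ext = lower %in% profile$candidate_extension_lexicon,
    state = tokens$surface %in% profile$state_abbreviations,
    conn = lower %in% profile$connector_words,
    punct = tokens$surface %in% c(",", "(", ")", ".")
  )
}

oracle_valid_span <- function(tokens, cl, i, j) {
  idx <- i:j
  ents <- idx[cl$entity[idx]]
  if (length(ents) == 0) return(FALSE)
  a <- min(ents); b <- max(ents)
  pre <- if (a > i) i:(a - 1) else integer()
  if (length(pre) > 3 || !all(cl$ext[pre])) return(FALSE)
  run <- 0
  for (k in a:b) {
    if (cl$entity[k]) {
      run <- 0
    } else {
      run <- run + 1
      if (run > 3) return(FALSE)
      if (!(cl$ext[k] || cl$state[k] || cl$conn[k] || cl$punct[k])) {
        return(FALSE)
      }
    }
  }
  suf <- if (b < j) (b + 1):j else integer()
  if (length(suf) > 3) return(FALSE)
  for (k in suf) {
    if (cl$ext[k] || cl$state[k]) next
    if (tokens$surface[k] == "," && (k + 1) %in% suf && cl$state[k + 1]) next
    if (tokens$surface[k] == ")" &&
        sum(tokens$surface[i:(k - 1)] == "(") >
          sum(tokens$surface[i:(k - 1)] == ")")) next
    return(FALSE)
  }
  TRUE
}

# Greedy left-to-right selection of maximal valid spans by enumeration.
oracle_candidates <- function(tokens, profile) {
  n <- nrow(tokens)
  cl <- oracle_classes(tokens, profile)
  out <- list()
  pos <- 1
  while (pos <= n) {
    found <- NULL
    for (i in pos:n) {
      best_j <- NA
      for (j in i:n) {
        if (oracle_valid_span(tokens, cl, i, j)) best_j <- j
      }
      if (!is.na(best_j)) {
        found <- c(i, best_j)
        break
      }
    }
    if (is.null(found)) break
    out[[length(out) + 1L]] <- found
    pos <- found[2] + 1
  }
  out
}

# Random tagged sentences for property tests: a mixture of entities,
# connectors, extension words, state codes, punctuation and plain prose.
random_tagged_sentence <- function(max_len = 12) {
  pool <- list(
    list("Nancy", "LOCATION"), list("France", "LOCATION"),
    list("Boston", "LOCATION"), list("Smith", "PERSON"),
    list("Acme", "ORGANIZATION"), list("Hospital", "ORGANIZATION"),
    list("in", "OTHER"), list("of", "OTHER"), list("near", "OTHER"),
    list("the", "OTHER"), list("east", "OTHER"), list("region", "OTHER"),
    list("valley", "OTHER"), list("WI", "OTHER"), list("CA", "OTHER"),
    list(",", "OTHER"), list("(", "OTHER"), list(")", "OTHER"),
    list(".", "OTHER"), list("trees", "OTHER"), list("sampled", "OTHER"),
    list("were", "OTHER"), list("1998", "OTHER")
  )
  n <- sample(1:max_len, 1)
  picks <- sample(length(pool), n, replace = TRUE)
  make_tokens(
    vapply(pool[picks], `[[`, "", 1),
    vapply(pool[picks], `[[`, "", 2)
  )
}

random_candidate <- function() {
  words <- c("Nancy", "France", "University", "Inc", "GmbH", "Smith",
             "trees", "Berlin", "Hospital", "valley")
  tags <- c("LOCATION", "PERSON", "ORGANIZATION", "OTHER")
  n <- sample(1:5, 1)
  surfaces <- sample(words, n, replace = TRUE)
  tibble::tibble(
    start = 1L, end = as.integer(n),
    candidate_string = paste(surfaces, collapse = " "),
    surfaces = list(surfaces),
    tags = list(sample(tags, n, replace = TRUE)),
    prev_surface = NA_character_, next_surface = NA_character_
  )
}

random_string <- function() {
  chars <- c(letters, LETTERS, " ", " ", ",", ".", "(", ")",
             "é", "ü", "ã", "ß", "\t", "  ")
  paste(sample(chars, sample(1:25, 1), replace = TRUE), collapse = "")
}
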