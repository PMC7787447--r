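#' Domain profiles: all corpus-specific configuration
#'
#' A domain profile bundles every per-corpus customization the pipeline
#' accepts: the heading patterns that mark relevant sections, whether the
#' article title is mined, the lexicons used to extend location candidates
#' (cardinal directions, geographic feature types), keep/discard word lists
#' for the filtering stage, connector words bridged inside candidates, the
#' two-letter state abbreviations, and the reference-section heading
#' patterns. Everything else in the pipeline is domain-agnostic.
#'
#' @param profile_id Name of the profile.
#' @param heading_patterns Character vector of case-insensitive regular
#'   expressions matched with word boundaries against section headings and
#'   plain-text paragraph beginnings. Must be non-empty.
#' @param use_title Should the article title be mined for locations?
#' @param candidate_extension_lexicon Lower-cased words (cardinal directions,
#'   feature types) allowed to extend a candidate beyond its entity tokens.
#' @param keep_words Words whose presence always keeps a candidate
#'   (case-insensitive word match); disjoint from `discard_words`.
#' @param discard_words Words whose presence rejects a candidate
#'   (case-sensitive word match, so "AG" does not fire on prose "ag").
#' @param connector_words Lower-cased words bridged between entity tokens.
#' @param state_abbreviations Two-letter postal codes bridged next to
#'   entities.
#' @param references_patterns Whole-line, case-insensitive patterns that mark
#'   a references section.
#' @param tag_word_rules List of token (tag, word) combination rules; see
#'   [default_tag_word_rules()].
#' @param split_country_lists Split candidates that are comma-separated
#'   sequences of country names into one candidate per country (off by
#'   default: comma groups are kept whole).
#' @return A `domain_profile` object (a validated list).
#' @seealso [profile_orchards()], [profile_cancer()], [read_profile()]
#' @export
domain_profile <- function(profile_id,
                           heading_patterns,
                           use_title = FALSE,
                           candidate_extension_lexicon = character(),
                           keep_words = character(),
                           discard_words = character(),
                           connector_words = c("in", "upon", "of", "at", "near", "the"),
                           state_abbreviations = us_state_abbreviations(),
                           references_patterns = c(
                             "references", "bibliography", "literature cited"
                           ),
                           tag_word_rules = default_tag_word_rules(),
                           split_country_lists = FALSE) {
  if (length(heading_patterns) == 0) {
    abort("`heading_patterns` must be non-empty.")
  }
  if (length(references_patterns) == 0) {
    abort("`references_patterns` must be non-empty.")
  }
  candidate_extension_lexicon <- str_to_lower(candidate_extension_lexicon)
  connector_words <- str_to_lower(connector_words)
  overlap <- intersect(str_to_lower(keep_words), str_to_lower(discard_words))
  if (length(overlap) > 0) {
    abort(paste0(
      "`keep_words` and `discard_words` must be disjoint; shared: ",
      paste(overlap, collapse = ", ")
    ))
  }
  structure(
    list(
      profile_id = profile_id,
      heading_patterns = heading_patterns,
      use_title = isTRUE(use_title),
      candidate_extension_lexicon = candidate_extension_lexicon,
      keep_words = keep_words,
      discard_words = discard_words,
      connector_words = connector_words,
      state_abbreviations = state_abbreviations,
      references_patterns = references_patterns,
      tag_word_rules = tag_word_rules,
      split_country_lists = isTRUE(split_country_lists)
    ),
    class = "domain_profile"
  )
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("<domain_profile>", x$profile_id, "\n")
  cat("  heading patterns: ", length(x$heading_patterns),
      " | use_title: ", x$use_title, "\n", sep = "")
  cat("  keep words:", length(x$keep_words),
      "| discard words:", length(x$discard_words), "\n")
  invisible(x)
}

#' The 50 US postal state codes plus DC
#' @return Character vector of 51 two-letter codes.
#' @export
us_state_abbreviations <- function() {
  c(
    "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA", "HI", "ID",
    "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN", "MS",
    "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH", "OK",
    "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA", "WV",
    "WI", "WY", "DC"
  )
}

default_keep_words <- function() {
  c("University", "Institute", "Hospital", "Medical School",
    "Centre", "Center", "Clinic")
}

default_discard_words <- function() {
  c("Inc", "Ltd", "GmbH", "Corp", "Co", "LLC", "AG", "KGaA")
}

#' Built-in profile for ecology-style corpora
#'
#' Targets study-site and methods sections, mines the title, and extends
#' candidates with cardinal-direction and geographic feature-type words
#' ("Nancy (East of France)" rather than "Nancy" and "France" separately).
#' @return A [domain_profile()].
#' @export
profile_orchards <- function() {
  domain_profile(
    profile_id = "orchards",
    heading_patterns = c(
      "materials? and methods", "methods?", "study sites?", "study area",
      "site description", "sampling", "field", "region", "area", "site"
    ),
    use_title = TRUE,
    candidate_extension_lexicon = c(
      "north", "south", "east", "west",
      "northern", "southern", "eastern", "western",
      "northeastern", "northwestern", "southeastern", "southwestern",
      "central",
      "region", "county", "park", "valley", "river", "province",
      "district", "island"
    ),
    keep_words = default_keep_words(),
    discard_words = default_discard_words()
  )
}

#' Built-in profile for biomedical-style corpora
#'
#' Targets patients/samples/specimens sections; titles are not mined and the
#' candidate-extension lexicon is empty (biomedical provenance locations are
#' typically plain hospital or city names).
#' @return A [domain_profile()].
#' @export
profile_cancer <- function() {
  domain_profile(
    profile_id = "cancer",
    heading_patterns = c(
      "materials? and methods", "methods?", "patients?", "samples?",
      "specimens?", "subjects?", "tumou?r material", "cases?"
    ),
    use_title = FALSE,
    candidate_extension_lexicon = character(),
    keep_words = default_keep_words(),
    discard_words = default_discard_words()
  )
}

#' Look up a built-in profile by id
#' @param profile_id `"orchards"` or `"cancer"`, or a path to a YAML/JSON
#'   profile file.
#' @return A [domain_profile()].
#' @export
get_profile <- function(profile_id) {
  if (inherits(profile_id, "domain_profile")) return(profile_id)
  switch(profile_id,
    orchards = profile_orchards(),
    cancer = profile_cancer(),
    {
      if (file.exists(profile_id)) return(read_profile(profile_id))
      abort(paste0("Unknown profile: '", profile_id, "'"))
    }
  )
}

#' Read / write a profile as YAML
#'
#' Every list in a profile is user-overridable; profiles serialize to plain
#' YAML so corpus customization lives in config, not code. Fields missing
#' from the file fall back to [domain_profile()] defaults. Tag-word rules are
#' referenced by name (see [default_tag_word_rules()]).
#'
#' @param path File path.
#' @return `read_profile()` returns a [domain_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- default_tag_word_rules()
  if (!is.null(raw$tag_word_rules)) {
    rules <- rules[intersect(names(rules), unlist(raw$tag_word_rules))]
  }
  args <- raw[setdiff(names(raw), "tag_word_rules")]
  args$tag_word_rules <- rules
  do.call(domain_profile, args)
}

#' @rdname read_profile
#' @param profile A [domain_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "domain_profile"))
  out <- unclass(profile)
  out$tag_word_rules <- names(profile$tag_word_rules)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Default token (tag, word) combination rules
#'
#' These reject candidates whose tag/word patterns mark them as citations or
#' company parentheticals rather than content locations. Each rule is a
#' function of a candidate row (fields `tags`, `surfaces`, `next_surface`,
#' `prev_surface`) returning `TRUE` to reject. The rule table is profile
#' configuration and user-extensible.
#'
#' * `person_year`: a PERSON-tagged token at the end of the span followed by
#'   a four-digit year is an author citation ("Smith 1998").
#' * `org_parenthetical`: an all-ORGANIZATION span enclosed in parentheses is
#'   a company or product attribution.
#' @return Named list of rule functions.
#' @export
default_tag_word_rules <- function() {
  list(
    person_year = function(cand) {
      tags <- cand$tags
      if (length(tags) == 0 || tags[length(tags)] != "PERSON") return(FALSE)
      !is.na(cand$next_surface) &&
        stringr::str_detect(cand$next_surface, "^(1[5-9][0-9]{2}|20[0-9]{2})$")
    },
    org_parenthetical = function(cand) {
      all(cand$tags == "ORGANIZATION") &&
        identical(cand$prev_surface, "(") &&
        identical(cand$next_surface, ")")
    }
  )
}
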