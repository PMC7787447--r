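#' Harmonic-mean F1
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @return `2pr/(p+r)`, and 0 when both are 0.
#' @examples
#' harmonic_f1(0.628, 1)  # 0.771...
#' @export
harmonic_f1 <- function(p, r) {
  if (any(is.na(c(p, r))) || any(c(p, r) < 0) || any(c(p, r) > 1)) {
    abort("`p` and `r` must lie in [0, 1].")
  }
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

# Does an extracted string represent a truth string? Case-insensitive
# normalized equality or whole-string containment (with word boundaries)
# in either direction, the reproducible surrogate for a human judgment of
# "this ground-truth location is represented".
strings_match <- function(truth_string, extracted_string) {
  a <- str_to_lower(normalize_text(truth_string))
  b <- str_to_lower(normalize_text(extracted_string))
  if (identical(a, b)) return(TRUE)
  pat_a <- regex(paste0("\\b", stringr::str_escape(a), "\\b"))
  pat_b <- regex(paste0("\\b", stringr::str_escape(b), "\\b"))
  isTRUE(str_detect(b, pat_a)) || isTRUE(str_detect(a, pat_b))
}

truth_represented <- function(truth_string, extracted_strings) {
  any(map_lgl(extracted_strings, ~ strings_match(truth_string, .x)))
}

extracted_correct <- function(extracted_string, truth_strings) {
  any(map_lgl(truth_strings, ~ strings_match(.x, extracted_string)))
}

#' Location-unit extraction precision
#'
#' TP / (TP + FP) over individual extracted location strings, judged
#' correct or incorrect. With nothing extracted the metric is undefined
#' and reported as `NA` rather than 0.
#'
#' @param extracted Tibble with columns `article_id`, `location_string`.
#' @param judgments Tibble with columns `article_id`, `extracted_string`,
#'   `correct` (logical, or the strings "correct"/"incorrect"). Every
#'   extracted string must be judged.
#' @return Extraction precision in `[0, 1]`, or `NA` when nothing was
#'   extracted.
#' @export
extraction_precision <- function(extracted, judgments) {
  extracted <- as_tibble(extracted)
  if (nrow(extracted) == 0) return(NA_real_)
  correct <- join_judgments(extracted, judgments)
  mean(correct)
}

join_judgments <- function(extracted, judgments) {
  judgments <- normalize_judgments(judgments)
  keyed <- judgments |>
    mutate(.key = paste0(.data$article_id, "\r",
                         str_to_lower(normalize_text(.data$extracted_string))))
  keys <- paste0(extracted$article_id, "\r",
                 str_to_lower(normalize_text(extracted$location_string)))
  pos <- match(keys, keyed$.key)
  if (anyNA(pos)) {
    missing <- extracted$location_string[is.na(pos)][1]
    abort(paste0("No judgment for extracted string '", missing, "'."))
  }
  keyed$correct[pos]
}

normalize_judgments <- function(judgments) {
  judgments <- as_tibble(judgments)
  stopifnot(all(c("article_id", "extracted_string", "correct") %in%
                  names(judgments)))
  if (is.character(judgments$correct)) {
    judgments$correct <- judgments$correct == "correct"
  }
  judgments
}

# Is a geocode result correct for a truth location? Record-id equality when
# the truth carries an id; otherwise a great-circle distance tolerance
# scaled to the result granularity (25 km for localities and points of
# interest, 200 km for administrative areas), and name equality for
# country-level results.
geocode_correct <- function(result, truth_row,
                            tol_locality_km = 25, tol_admin_km = 200) {
  if (is.null(result) || nrow(result) == 0) return(FALSE)
  if (!is.na(truth_row$truth_record_id %||% NA) &&
      nzchar(truth_row$truth_record_id)) {
    return(identical(result$record_id, truth_row$truth_record_id))
  }
  if (result$granularity == "country") {
    return(strings_match(truth_row$truth_string, result$formatted_name))
  }
  if (is.na(truth_row$truth_lat %||% NA) || is.na(truth_row$truth_lon %||% NA)) {
    return(FALSE)
  }
  d_km <- geosphere::distHaversine(
    c(result$longitude, result$latitude),
    c(truth_row$truth_lon, truth_row$truth_lat)
  ) / 1000
  tol <- if (result$granularity == "administrative_area") tol_admin_km else tol_locality_km
  d_km <= tol
}

#' Location-unit geocoding accuracy
#'
#' Computed over the subset of extraction true positives: the share whose
#' geocode result is correct. A true positive with no geocode result counts
#' as incorrect.
#'
#' @param tp_records Tibble of true-positive extracted records
#'   (`article_id`, `location_string`) with geocode columns (`record_id`,
#'   `formatted_name`, `granularity`, `latitude`, `longitude`; NA when
#'   ungeocoded). Each record is checked against its article's matching
#'   truth locations.
#' @param truth Truth tibble (`article_id`, `truth_string`,
#'   `truth_record_id`, `truth_lat`, `truth_lon`).
#' @return Accuracy in `[0, 1]`, `NA` when there are no true positives.
#' @export
geocoding_accuracy <- function(tp_records, truth) {
  tp_records <- as_tibble(tp_records)
  if (nrow(tp_records) == 0) return(NA_real_)
  mean(geocode_correct_rows(tp_records, truth))
}

geocode_correct_rows <- function(records, truth) {
  truth <- as_tibble(truth)
  map_lgl(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    if (is.na(rec$record_id %||% NA) || !nzchar(rec$record_id %||% "")) {
      return(FALSE)  # no geocode result
    }
    trows <- truth |>
      filter(.data$article_id == rec$article_id) |>
      filter(map_lgl(.data$truth_string,
                     ~ strings_match(.x, rec$location_string)))
    if (nrow(trows) == 0) return(FALSE)
    any(map_lgl(seq_len(nrow(trows)), function(j) {
      geocode_correct(
        rec[, c("record_id", "formatted_name", "granularity",
                "latitude", "longitude")],
        trows[j, ]
      )
    }))
  })
}

#' Location-unit full-pipeline precision
#'
#' Judges the final geocoded output of every extracted string. The
#' numerator counts strings that are both correctly extracted and correctly
#' geocoded. A wrongly extracted string that returns no geocode result is a
#' true negative overall and leaves the denominator; a correctly extracted
#' string geocoded to the wrong place is a false positive overall.
#'
#' @param extracted Tibble of extracted records with geocode columns (as in
#'   [geocoding_accuracy()]).
#' @param judgments Per-string correctness judgments (see
#'   [extraction_precision()]).
#' @param truth Truth tibble.
#' @return Full-pipeline precision in `[0, 1]`, `NA` when the denominator
#'   is empty.
#' @export
full_pipeline_precision <- function(extracted, judgments, truth) {
  extracted <- as_tibble(extracted)
  if (nrow(extracted) == 0) return(NA_real_)
  correct_string <- join_judgments(extracted, judgments)
  has_geocode <- !is.na(extracted$record_id %||% rep(NA, nrow(extracted))) &
    nzchar(dplyr::coalesce(extracted$record_id, ""))
  correct_geo <- geocode_correct_rows(extracted, truth)
  true_negative <- !correct_string & !has_geocode
  denom <- sum(!true_negative)
  if (denom == 0) return(NA_real_)
  sum(correct_string & correct_geo) / denom
}

#' Article-unit precision, recall and F1
#'
#' Scores each article out of a maximum of 1 — precision 1 means every
#' extracted location string for the article is correct, recall 1 means
#' every ground-truth location is represented by at least one extracted
#' string — then averages per-article values into corpus precision and
#' recall (so multi-site articles are not over-weighted) and combines them
#' by harmonic mean into F1. Articles with nothing extracted are excluded
#' from the precision mean; articles with no truth locations are excluded
#' from the recall mean.
#'
#' @param extracted Tibble (`article_id`, `location_string`), deduplicated
#'   per article.
#' @param truth Truth tibble (`article_id`, `truth_string`; articles with
#'   no locations may appear with zero rows or NA strings).
#' @param judgments Optional per-string judgments; when absent, an
#'   extracted string is judged correct when it matches any of its
#'   article's truth strings.
#' @return List: `precision`, `recall`, `f1`, and `per_article` (tibble
#'   `article_id`, `n_extracted`, `n_truth`, `precision`, `recall`).
#' @export
article_unit_scores <- function(extracted, truth, judgments = NULL) {
  extracted <- as_tibble(extracted)
  truth_all <- as_tibble(truth)
  truth_ids <- unique(truth_all$article_id)
  # articles with no locations still appear in the truth file (with an
  # empty truth string); an article entirely absent from it indicates
  # mismatched inputs
  extra <- setdiff(unique(extracted$article_id), truth_ids)
  if (length(extra) > 0) {
    abort(paste0("Article(s) in extraction but not in truth: ",
                 paste(extra, collapse = ", ")))
  }
  truth <- truth_all |>
    filter(!is.na(.data$truth_string) & nzchar(.data$truth_string))

  if (!is.null(judgments)) {
    correct <- join_judgments(extracted, judgments)
  } else {
    correct <- map_lgl(seq_len(nrow(extracted)), function(i) {
      ts <- truth$truth_string[truth$article_id == extracted$article_id[i]]
      length(ts) > 0 && extracted_correct(extracted$location_string[i], ts)
    })
  }
  extracted$correct <- correct

  ids <- truth_ids
  per_article <- map(ids, function(id) {
    ex <- extracted[extracted$article_id == id, ]
    ts <- truth$truth_string[truth$article_id == id]
    p <- if (nrow(ex) == 0) NA_real_ else mean(ex$correct)
    r <- if (length(ts) == 0) NA_real_ else {
      mean(map_lgl(ts, ~ truth_represented(.x, ex$location_string)))
    }
    tibble(
      article_id = id, n_extracted = nrow(ex), n_truth = length(ts),
      precision = p, recall = r
    )
  }) |> list_rbind()

  p <- mean(per_article$precision, na.rm = TRUE)
  r <- mean(per_article$recall, na.rm = TRUE)
  if (is.nan(p)) p <- NA_real_
  if (is.nan(r)) r <- NA_real_
  f1 <- if (is.na(p) || is.na(r)) NA_real_ else harmonic_f1(p, r)
  list(precision = p, recall = r, f1 = f1, per_article = per_article)
}

#' Error-category names of the failure taxonomy
#' @return Character vector of the seven categories.
#' @export
error_categories <- function() {
  c("ner_error", "text_portion_not_extracted", "wrong_no_geocode",
    "comma_group", "candidate_filtering_error", "non_standard_headings",
    "other")
}

#' Tally labelled pipeline failures into the error taxonomy
#'
#' Each failure carries exactly one category (only the main source of error
#' per location unit is recorded). Percentages are of the total failure
#' count, rounded to one decimal.
#'
#' @param failures Tibble with columns `article_id`, `category`, or a
#'   character vector of categories.
#' @return Tibble `category`, `count`, `percent` covering all categories
#'   (zero rows included), in taxonomy order.
#' @export
tally_errors <- function(failures) {
  cats <- if (is.character(failures)) failures else {
    as_tibble(failures)$category
  }
  unknown <- setdiff(unique(cats), error_categories())
  if (length(unknown) > 0) {
    abort(paste0("Unknown error categor(ies): ",
                 paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(cats, levels = error_categories()))
  total <- sum(counts)
  tibble(
    category = error_categories(),
    count = as.integer(counts),
    percent = if (total == 0) rep(0, length(counts)) else {
      round(100 * as.integer(counts) / total, 1)
    }
  )
}
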