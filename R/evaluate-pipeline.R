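#' Evaluate pipeline output against ground-truth annotations
#'
#' Computes the full two-unit evaluation in one call: the 3-stage
#' location-unit metrics (extraction precision over extracted strings,
#' geocoding accuracy over extraction true positives, full-pipeline
#' precision over final geocoded output), the article-unit
#' precision/recall/F1 averages, and per-location correctness labels for
#' mapping. When no per-string judgments file is supplied, an extracted
#' string is judged correct when it matches one of its article's truth
#' strings (case-insensitive normalized equality or containment).
#'
#' @param records Extraction-record tibble from [run_corpus()] /
#'   [run_article()] (columns `article_id`, `location_string`, geocode
#'   fields).
#' @param truth Ground-truth tibble: `article_id`, `truth_string`, optional
#'   `truth_record_id`, `truth_lat`, `truth_lon`, `location_quality`.
#'   Articles with `location_quality = "none"` may have empty/NA truth
#'   strings. See [read_truth()].
#' @param judgments Optional manual judgments tibble (`article_id`,
#'   `extracted_string`, `correct`).
#' @return A `geosift_eval` object; see [tidy.geosift_eval()] and
#'   [glance.geosift_eval()].
#' @export
evaluate_pipeline <- function(records, truth, judgments = NULL) {
  records <- as_tibble(records)
  truth <- as_tibble(truth)
  for (col in c("truth_record_id", "truth_lat", "truth_lon")) {
    if (!col %in% names(truth)) truth[[col]] <- NA
  }
  truth_clean <- truth |>
    filter(!is.na(.data$truth_string) & nzchar(.data$truth_string))

  if (is.null(judgments)) {
    judgments <- tibble(
      article_id = records$article_id,
      extracted_string = records$location_string,
      correct = map_lgl(seq_len(nrow(records)), function(i) {
        ts <- truth_clean$truth_string[
          truth_clean$article_id == records$article_id[i]
        ]
        length(ts) > 0 &&
          extracted_correct(records$location_string[i], ts)
      })
    ) |> distinct(.data$article_id, .data$extracted_string, .keep_all = TRUE)
  }

  correct_string <- if (nrow(records) > 0) {
    join_judgments(records, judgments)
  } else logical()
  has_geocode <- if (nrow(records) > 0) {
    !is.na(records$record_id) & nzchar(dplyr::coalesce(records$record_id, ""))
  } else logical()
  correct_geo <- if (nrow(records) > 0) {
    geocode_correct_rows(records, truth_clean)
  } else logical()

  per_location <- records |>
    mutate(
      extraction_correct = correct_string,
      has_geocode = has_geocode,
      geocode_correct = correct_geo,
      label = dplyr::case_when(
        !has_geocode & !correct_string ~ "TN",
        correct_string & correct_geo ~ "TP",
        TRUE ~ "FP"
      )
    )

  art <- article_unit_scores(
    select(records, "article_id", "location_string"),
    truth, judgments = judgments
  )

  structure(
    list(
      extraction_precision = extraction_precision(records, judgments),
      geocoding_accuracy = geocoding_accuracy(
        per_location[per_location$extraction_correct, ], truth_clean
      ),
      full_pipeline_precision = full_pipeline_precision(
        records, judgments, truth_clean
      ),
      article_unit_precision = art$precision,
      article_unit_recall = art$recall,
      article_unit_f1 = art$f1,
      per_article = art$per_article,
      per_location = per_location,
      n_articles = length(unique(truth$article_id)),
      n_extracted = nrow(records)
    ),
    class = "geosift_eval"
  )
}

#' @export
print.geosift_eval <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "n/a", sprintf("%.3f", v))
  cat("<geosift_eval> ", x$n_articles, " article(s), ",
      x$n_extracted, " extracted location(s)\n", sep = "")
  cat("  location unit:  extraction precision ", f(x$extraction_precision),
      " | geocoding accuracy ", f(x$geocoding_accuracy),
      " | full pipeline precision ", f(x$full_pipeline_precision), "\n",
      sep = "")
  cat("  article unit:   P ", f(x$article_unit_precision),
      " | R ", f(x$article_unit_recall),
      " | F1 ", f(x$article_unit_f1), "\n", sep = "")
  invisible(x)
}

#' Tidy per-article evaluation results
#'
#' @param x A `geosift_eval` object.
#' @param ... Unused.
#' @return A tibble with one row per article: `article_id`, `n_extracted`,
#'   `n_truth`, `precision`, `recall`.
#' @exportS3Method generics::tidy
tidy.geosift_eval <- function(x, ...) {
  x$per_article
}

#' One-row summary of an evaluation
#'
#' @param x A `geosift_eval` object.
#' @param ... Unused.
#' @return One-row tibble with the corpus-level metrics, rounded to 3
#'   decimals for reporting.
#' @exportS3Method generics::glance
glance.geosift_eval <- function(x, ...) {
  tibble(
    n_articles = x$n_articles,
    n_extracted = x$n_extracted,
    extraction_precision = round(x$extraction_precision, 3),
    geocoding_accuracy = round(x$geocoding_accuracy, 3),
    full_pipeline_precision = round(x$full_pipeline_precision, 3),
    article_unit_precision = round(x$article_unit_precision, 3),
    article_unit_recall = round(x$article_unit_recall, 3),
    article_unit_f1 = round(x$article_unit_f1, 3)
  )
}

#' Plot per-article precision and recall
#'
#' @param object A `geosift_eval` object.
#' @param ... Unused.
#' @return A ggplot: articles on the x axis, per-article precision and
#'   recall as points.
#' @exportS3Method ggplot2::autoplot
autoplot.geosift_eval <- function(object, ...) {
  df <- object$per_article |>
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$article_id, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "article", y = "score", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Read a ground-truth annotation file
#'
#' One row per truth location. Tab-separated with header:
#' `article_id`, `truth_string`, `truth_record_id`, `truth_lat`,
#' `truth_lon`, `location_quality` (one of none/bad/medium/good). Articles
#' without locations appear with an empty `truth_string`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_truth <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      article_id = readr::col_character(),
      truth_string = readr::col_character(),
      truth_record_id = readr::col_character(),
      truth_lat = readr::col_double(),
      truth_lon = readr::col_double(),
      location_quality = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Read a per-string judgments file
#'
#' Tab-separated with header: `article_id`, `extracted_string`, `correct`
#' (`correct`/`incorrect`).
#'
#' @param path TSV file path.
#' @return A tibble with a logical `correct` column.
#' @export
read_judgments <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ) |>
    normalize_judgments()
}
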