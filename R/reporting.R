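#' Write extraction records as a GeoJSON FeatureCollection
#'
#' One point feature per geocoded record (GeoJSON coordinate order:
#' longitude, then latitude). Records without a geocode result are skipped
#' and counted. When an evaluation is supplied, each feature carries a
#' `label` property (`"TP"` / `"FP"`) reflecting full-pipeline
#' correctness, which is what a corpus map colour-codes.
#'
#' @param records Extraction-record tibble from [run_corpus()].
#' @param path Output file path, or `NULL` to return the GeoJSON list
#'   only.
#' @param evaluation Optional [evaluate_pipeline()] result.
#' @return Invisibly, a list: `geojson` (the FeatureCollection as an R
#'   list), `n_features`, `n_skipped`.
#' @export
write_geojson <- function(records, path = NULL, evaluation = NULL) {
  records <- as_tibble(records)
  geocoded <- records |>
    filter(!is.na(.data$latitude) & !is.na(.data$longitude) &
             !is.na(.data$record_id))
  n_skipped <- nrow(records) - nrow(geocoded)

  labels <- NULL
  if (!is.null(evaluation)) {
    stopifnot(inherits(evaluation, "geosift_eval"))
    pl <- evaluation$per_location
    key <- paste0(pl$article_id, "\r", pl$location_string)
    labels <- stats::setNames(pl$label, key)
  }

  features <- map(seq_len(nrow(geocoded)), function(i) {
    row <- geocoded[i, ]
    props <- list(
      article_id = row$article_id,
      location_string = row$location_string,
      formatted_name = row$formatted_name,
      granularity = row$granularity
    )
    if (!is.null(labels)) {
      props$label <- unname(labels[paste0(row$article_id, "\r",
                                          row$location_string)])
    }
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(row$longitude, row$latitude)
      ),
      properties = props
    )
  })
  geojson <- list(type = "FeatureCollection", features = features)

  if (!is.null(path)) {
    jsonlite::write_json(geojson, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
  }
  invisible(list(
    geojson = geojson, n_features = length(features), n_skipped = n_skipped
  ))
}

#' Write extraction records as a delimited table
#'
#' Fixed, documented column order; sentence text is CSV-quoted so that
#' commas and quotes round-trip exactly.
#'
#' @param records Extraction-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_table <- function(records, path) {
  cols <- c(
    "article_id", "location_string", "sentence_text", "heading",
    "para_idx", "sentence_idx", "n_duplicates", "formatted_name",
    "granularity", "latitude", "longitude", "record_id", "backend_id",
    "variant"
  )
  records <- as_tibble(records)[, cols]
  readr::write_csv(records, path, na = "")
  invisible(path)
}

# JSON-lines serialization of the records (one JSON object per line).
write_records_jsonl <- function(records, path) {
  records <- as_tibble(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    line <- jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                             digits = NA, na = "null")
    writeLines(line, con, sep = "\n")
  }
  invisible(path)
}

#' Map geocoded extraction records
#'
#' A simple global scatter of geocoded locations in longitude/latitude,
#' colour-coded by full-pipeline correctness when an evaluation is
#' supplied (true positives vs false positives). For publication maps,
#' export with [write_geojson()] and render with dedicated GIS tooling.
#'
#' @param records Extraction-record tibble.
#' @param evaluation Optional [evaluate_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_locations <- function(records, evaluation = NULL) {
  geocoded <- as_tibble(records) |>
    filter(!is.na(.data$latitude) & !is.na(.data$longitude))
  if (!is.null(evaluation)) {
    pl <- evaluation$per_location |>
      select("article_id", "location_string", "label") |>
      distinct()
    geocoded <- left_join(geocoded, pl,
                          by = c("article_id", "location_string"))
    p <- ggplot2::ggplot(geocoded, ggplot2::aes(
      x = .data$longitude, y = .data$latitude, colour = .data$label
    )) +
      ggplot2::scale_colour_manual(
        values = c(TP = "#2166ac", FP = "#b2182b", TN = "grey60"),
        na.value = "grey40"
      )
  } else {
    p <- ggplot2::ggplot(geocoded, ggplot2::aes(
      x = .data$longitude, y = .data$latitude
    ))
  }
  p +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_quickmap(xlim = c(-180, 180), ylim = c(-90, 90)) +
    ggplot2::labs(x = "longitude", y = "latitude", colour = NULL) +
    ggplot2::theme_minimal()
}
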