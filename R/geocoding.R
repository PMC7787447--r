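#' Load a gazetteer from a GeoNames-dump-style TSV file
#'
#' Columns (tab-separated, no header): record id, primary name, alternate
#' names (pipe-separated), feature class (`P` populated place, `A`
#' administrative area / country, `S` spot or point of interest), latitude,
#' longitude, population, ISO country code, admin containment path
#' (pipe-separated, most specific first, e.g. `CA|USA`). Malformed rows
#' (unparseable numbers, out-of-range coordinates, negative population) are
#' skipped with a warning naming the line number; a file with zero valid
#' rows is an error.
#'
#' @param path TSV file path, or a data frame with the same columns
#'   (`record_id`, `primary_name`, `alternate_names`, `feature_class`,
#'   `latitude`, `longitude`, `population`, `country_code`, `admin_path`;
#'   the two multi-valued columns pipe-separated strings or list-columns).
#' @return A `gazetteer` object: `$records` (tibble, list-columns
#'   `alternate_names` and `admin_path`) and `$index` (long tibble of
#'   normalized names for lookup).
#' @export
load_gazetteer <- function(path) {
  cols <- c("record_id", "primary_name", "alternate_names", "feature_class",
            "latitude", "longitude", "population", "country_code",
            "admin_path")
  if (is.character(path) && length(path) == 1) {
    raw <- readr::read_tsv(
      path, col_names = cols,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, na = character()
    )
  } else {
    raw <- as_tibble(path)
    stopifnot(all(cols %in% names(raw)))
    raw <- raw[cols]
  }

  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  pop <- suppressWarnings(as.numeric(raw$population))
  ok <- !is.na(lat) & !is.na(lon) & !is.na(pop) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180 & pop >= 0 &
    nzchar(raw$primary_name)
  if (any(!ok)) {
    warn(paste0(
      "Skipping ", sum(!ok), " malformed gazetteer row(s) at line(s): ",
      paste(which(!ok), collapse = ", ")
    ))
  }
  if (!any(ok)) abort("Gazetteer contains no valid rows.")

  split_pipe <- function(x) {
    map(x, function(v) {
      if (is.character(v) && length(v) == 1) {
        out <- str_split(v, fixed("|"))[[1]]
        out[nzchar(out)]
      } else {
        v <- as.character(v)
        v[nzchar(v)]
      }
    })
  }
  records <- tibble(
    record_id = raw$record_id[ok],
    primary_name = raw$primary_name[ok],
    alternate_names = split_pipe(raw$alternate_names[ok]),
    feature_class = raw$feature_class[ok],
    latitude = lat[ok],
    longitude = lon[ok],
    population = pop[ok],
    country_code = raw$country_code[ok],
    admin_path = split_pipe(raw$admin_path[ok])
  )
  index <- bind_rows(
    tibble(
      norm_name = str_to_lower(normalize_text(records$primary_name)),
      record_id = records$record_id,
      match_type = "primary"
    ),
    records |>
      select("record_id", "alternate_names") |>
      tidyr::unnest_longer("alternate_names", values_to = "name") |>
      mutate(
        norm_name = str_to_lower(normalize_text(.data$name)),
        match_type = "alternate"
      ) |>
      select("norm_name", "record_id", "match_type")
  )
  inform(paste0("Loaded gazetteer: ", nrow(records), " record(s)."))
  structure(list(records = records, index = index), class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer>", nrow(x$records), "records\n")
  invisible(x)
}

#' Rank gazetteer records for a query
#'
#' Resolution of an ambiguous place name follows a fixed, deterministic
#' ranking: exact primary-name match beats exact alternate-name match beats
#' a match where all query tokens are contained in the primary name; ties
#' break by descending population (the classical population heuristic for
#' toponym disambiguation), then ascending record id. Qualified queries
#' ("Paris, Texas") are resolved by matching the head part and requiring
#' each remaining comma-separated part to appear in the record's admin
#' containment path, country code, or country name.
#'
#' @param query Location string (normalized internally).
#' @param gazetteer A [load_gazetteer()] object.
#' @return Tibble of matching records, best first (possibly zero rows).
#' @export
gazetteer_lookup <- function(query, gazetteer) {
  stopifnot(inherits(gazetteer, "gazetteer"))
  q <- str_to_lower(normalize_text(query))
  if (!nzchar(q)) return(gazetteer$records[0, ])
  parts <- str_trim(str_split(q, fixed(","))[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return(gazetteer$records[0, ])
  head_part <- parts[1]
  qualifiers <- parts[-1]

  idx <- gazetteer$index
  exact <- idx |>
    filter(.data$norm_name == head_part) |>
    mutate(match_class = ifelse(.data$match_type == "primary", 1L, 2L))
  # containment: every token of the head part appears in the primary name
  q_tokens <- tokenize(head_part)
  contained <- gazetteer$records |>
    filter(map_lgl(
      str_to_lower(normalize_text(.data$primary_name)),
      function(nm) length(q_tokens) > 0 && all(q_tokens %in% tokenize(nm))
    )) |>
    transmute_ids(match_class = 3L)
  all_hits <- bind_rows(
    select(exact, "record_id", "match_class"),
    contained
  )
  if (nrow(all_hits) == 0) return(gazetteer$records[0, ])
  hits <- all_hits |>
    group_by(.data$record_id) |>
    summarise(match_class = min(.data$match_class), .groups = "drop")
  res <- gazetteer$records |>
    dplyr::inner_join(hits, by = "record_id")

  if (length(qualifiers) > 0) {
    keep <- map_lgl(seq_len(nrow(res)), function(i) {
      path <- str_to_lower(normalize_text(res$admin_path[[i]]))
      cc <- str_to_lower(res$country_code[i])
      all(qualifiers %in% c(path, cc))
    })
    res <- res[keep, , drop = FALSE]
  }
  res |>
    arrange(.data$match_class, dplyr::desc(.data$population), .data$record_id) |>
    select(-"match_class")
}

transmute_ids <- function(df, match_class) {
  tibble(record_id = df$record_id, match_class = match_class)
}

granularity_of <- function(feature_class, admin_path) {
  dplyr::case_when(
    feature_class == "P" ~ "locality",
    feature_class == "S" ~ "point_of_interest",
    feature_class == "A" & lengths(admin_path) == 0 ~ "country",
    feature_class == "A" ~ "administrative_area",
    TRUE ~ "locality"
  )
}

#' Offline gazetteer geocoding backend
#'
#' Wraps a loaded gazetteer in the geocoding-backend contract: a backend is
#' a list with an `id` and a `lookup(query)` function returning ranked
#' results as a tibble (`formatted_name`, `granularity`, `latitude`,
#' `longitude`, `record_id`). The offline backend is fully deterministic —
#' identical (gazetteer, query) pairs give identical results on every run
#' and platform — which is what makes pipeline outputs reproducible without
#' network access. Adapters wrapping remote HTTP geocoding services
#' implement the same contract.
#'
#' @param gazetteer A [load_gazetteer()] object.
#' @param id Backend name recorded in results.
#' @return A `geocoder_backend`.
#' @export
gazetteer_backend <- function(gazetteer, id = "gazetteer") {
  stopifnot(inherits(gazetteer, "gazetteer"))
  lookup <- function(query) {
    res <- gazetteer_lookup(query, gazetteer)
    if (nrow(res) == 0) {
      return(tibble(
        formatted_name = character(), granularity = character(),
        latitude = numeric(), longitude = numeric(), record_id = character()
      ))
    }
    tibble(
      formatted_name = map_chr(seq_len(nrow(res)), function(i) {
        paste(c(res$primary_name[i], res$admin_path[[i]]), collapse = ", ")
      }),
      granularity = granularity_of(res$feature_class, res$admin_path),
      latitude = res$latitude,
      longitude = res$longitude,
      record_id = res$record_id
    )
  }
  structure(
    list(id = id, lookup = lookup, cache = new.env(parent = emptyenv())),
    class = "geocoder_backend"
  )
}

#' Geocode a cleaned location string
#'
#' Queries the backend once and retains the top-ranked result, or returns a
#' zero-row tibble when the backend has no result. Results are cached per
#' (backend, query) within a run, so repeated strings cost one lookup.
#'
#' @param query Cleaned, non-empty location string.
#' @param backend A geocoding backend (e.g. [gazetteer_backend()]).
#' @return A one-row tibble (`query`, `formatted_name`, `granularity`,
#'   `latitude`, `longitude`, `record_id`, `backend_id`) or a zero-row
#'   tibble when nothing matched.
#' @export
geocode <- function(query, backend) {
  stopifnot(inherits(backend, "geocoder_backend"))
  stopifnot(is.character(query), length(query) == 1, nzchar(query))
  key <- paste0(backend$id, "\r", str_to_lower(normalize_text(query)))
  if (!is.null(backend$cache) && exists(key, envir = backend$cache)) {
    res <- get(key, envir = backend$cache)
  } else {
    res <- backend$lookup(query)
    if (!is.null(backend$cache)) assign(key, res, envir = backend$cache)
  }
  if (nrow(res) == 0) {
    return(tibble(
      query = character(), formatted_name = character(),
      granularity = character(), latitude = numeric(), longitude = numeric(),
      record_id = character(), backend_id = character()
    ))
  }
  top <- res[1, ]
  stopifnot(
    top$latitude >= -90, top$latitude <= 90,
    top$longitude >= -180, top$longitude <= 180,
    nzchar(top$formatted_name)
  )
  tibble(
    query = query,
    formatted_name = top$formatted_name,
    granularity = top$granularity,
    latitude = top$latitude,
    longitude = top$longitude,
    record_id = top$record_id,
    backend_id = backend$id
  )
}
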