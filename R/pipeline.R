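#' Pipeline configuration
#'
#' Bundles a domain profile, the stage switches, and the geocoding backend.
#' The four named ablation variants are expressible through the three
#' switches:
#'
#' | variant          | `extract_enabled` | `identification_mode` | `filter_enabled` |
#' |------------------|-------------------|-----------------------|------------------|
#' | `full`           | TRUE              | `"full"`              | TRUE             |
#' | `no_extract`     | FALSE             | `"full"`              | TRUE             |
#' | `locations_only` | TRUE              | `"locations_only"`    | TRUE             |
#' | `no_filter`      | TRUE              | `"full"`              | FALSE            |
#'
#' @param profile A [domain_profile()] or built-in profile id.
#' @param backend A geocoding backend ([gazetteer_backend()]), or `NULL` to
#'   skip geocoding.
#' @param extract_enabled Target relevant sections (`TRUE`) or process the
#'   whole article excluding references (`FALSE`).
#' @param identification_mode `"full"` (keep any entity-bearing span) or
#'   `"locations_only"` (only LOCATION-tagged tokens).
#' @param filter_enabled Apply the candidate filtering rules?
#' @param variant Shorthand: one of `"full"`, `"no_extract"`,
#'   `"locations_only"`, `"no_filter"`; overrides the three switches.
#' @param output_dir Where [run_corpus()] writes outputs (`NULL`: return
#'   only).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(profile, backend = NULL,
                            extract_enabled = TRUE,
                            identification_mode = c("full", "locations_only"),
                            filter_enabled = TRUE,
                            variant = NULL,
                            output_dir = NULL) {
  identification_mode <- match.arg(identification_mode)
  if (!is.null(variant)) {
    variant <- match.arg(variant,
                         c("full", "no_extract", "locations_only", "no_filter"))
    extract_enabled <- variant != "no_extract"
    identification_mode <- if (variant == "locations_only") "locations_only" else "full"
    filter_enabled <- variant != "no_filter"
  }
  profile <- get_profile(profile)
  structure(
    list(
      profile = profile,
      backend = backend,
      extract_enabled = isTRUE(extract_enabled),
      identification_mode = identification_mode,
      filter_enabled = isTRUE(filter_enabled),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

config_variant <- function(config) {
  if (!config$extract_enabled) return("no_extract")
  if (config$identification_mode == "locations_only") return("locations_only")
  if (!config$filter_enabled) return("no_filter")
  "full"
}

empty_records <- function() {
  tibble(
    article_id = character(), location_string = character(),
    sentence_text = character(), heading = character(),
    para_idx = integer(), sentence_idx = integer(),
    n_duplicates = integer(),
    formatted_name = character(), granularity = character(),
    latitude = numeric(), longitude = numeric(), record_id = character(),
    backend_id = character(), variant = character()
  )
}

empty_rejects <- function() {
  tibble(
    article_id = character(), candidate_string = character(),
    rejection_reason = character(), heading = character(),
    para_idx = integer(), sentence_idx = integer()
  )
}

#' Run the pipeline on one article
#'
#' Executes the configured stages — section targeting (or whole-article
#' processing excluding references), normalization and sentence
#' segmentation, entity tagging, candidate assembly, filtering, cleaning,
#' deduplication, geocoding — and returns one extraction record per kept
#' location, with the sentence it was found in and full provenance. When
#' the profile mines titles, the title is processed as a one-sentence
#' section with heading `"TITLE"` and passes through the same filter rules
#' as body text.
#'
#' @param xml_doc,text_doc [article_document()]s (either may be `NULL`).
#' @param config A [pipeline_config()].
#' @param tagger An [entity_tagger()].
#' @return List with `records` (extraction-record tibble) and `rejects`
#'   (rejected-candidate tibble with reasons).
#' @export
run_article <- function(xml_doc = NULL, text_doc = NULL, config, tagger) {
  stopifnot(inherits(config, "pipeline_config"))
  profile <- config$profile
  article_id <- (xml_doc %||% text_doc)$article_id

  if (config$extract_enabled) {
    targeted <- extract_target_text(xml_doc, text_doc, profile)
    targets <- targeted$targets
    title <- targeted$title
  } else {
    doc <- xml_doc %||% text_doc
    targets <- whole_article_text(doc)
    title <- if (profile$use_title) doc$title else NULL
  }
  if (!is.null(title) && nzchar(title)) {
    targets <- bind_rows(
      tibble(heading = "TITLE", pattern_id = NA_integer_,
             para_idx = 0L, text = title),
      targets
    )
  }
  if (nrow(targets) == 0) {
    warn(paste0("Article '", article_id, "': no text targeted."))
    return(list(records = empty_records(), rejects = empty_rejects()))
  }

  candidates <- map(seq_len(nrow(targets)), function(i) {
    sentences <- tryCatch(
      segment_and_tag(targets$text[i], tagger),
      error = function(e) {
        warn(paste0("Article '", article_id, "' paragraph ",
                    targets$para_idx[i], " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(sentences) || nrow(sentences) == 0) return(NULL)
    map(seq_len(nrow(sentences)), function(s) {
      cand <- assemble_candidates(sentences$tokens[[s]], profile)
      if (nrow(cand) == 0) return(NULL)
      mutate(cand,
        article_id = article_id,
        heading = targets$heading[i] %||% NA_character_,
        para_idx = targets$para_idx[i],
        sentence_idx = sentences$sentence_idx[s],
        sentence_text = sentences$raw_text[s]
      )
    }) |> compact() |> list_rbind()
  }) |> compact() |> list_rbind()

  if (is.null(candidates) || nrow(candidates) == 0) {
    return(list(records = empty_records(), rejects = empty_rejects()))
  }

  mode <- if (!config$filter_enabled) "no_filter" else config$identification_mode
  filtered <- filter_candidates(candidates, profile, mode = mode)

  rejects <- filtered |>
    filter(.data$rejected) |>
    select("article_id", "candidate_string", "rejection_reason",
           "heading", "para_idx", "sentence_idx")

  kept <- filtered |>
    filter(!.data$rejected) |>
    deduplicate_locations()

  geo <- if (!is.null(config$backend) && nrow(kept) > 0) {
    map(kept$location_string, function(q) {
      res <- geocode(q, config$backend)
      if (nrow(res) == 0) {
        tibble(
          formatted_name = NA_character_, granularity = NA_character_,
          latitude = NA_real_, longitude = NA_real_,
          record_id = NA_character_, backend_id = config$backend$id
        )
      } else {
        select(res, -"query")
      }
    }) |> list_rbind()
  } else {
    tibble(
      formatted_name = rep(NA_character_, nrow(kept)),
      granularity = NA_character_, latitude = NA_real_, longitude = NA_real_,
      record_id = NA_character_, backend_id = NA_character_
    )
  }

  records <- bind_rows(
    empty_records(),
    dplyr::bind_cols(
      select(kept, "article_id", "location_string", "sentence_text",
             "heading", "para_idx", "sentence_idx", "n_duplicates"),
      geo
    ) |> mutate(variant = config_variant(config))
  ) |> arrange(.data$para_idx, .data$sentence_idx)

  list(records = records, rejects = rejects)
}

#' Run the pipeline over a corpus of articles
#'
#' Processes every article, isolating per-article failures (a malformed
#' article is counted as failed and the run continues), and returns —
#' and optionally writes — the extraction records, the rejected-candidate
#' log, and a run summary. Output ordering is deterministic: articles by
#' id, records by document position; two runs over identical inputs with
#' the offline backend produce byte-identical files.
#'
#' @param articles A tibble with column `article_id` and any of `xml_path`,
#'   `text_path` (see [read_corpus_dir()]), or a named list of lists with
#'   elements `xml_doc` / `text_doc`.
#' @param config A [pipeline_config()]; when `config$output_dir` is set,
#'   `records.csv`, `records.jsonl`, `rejects.csv` and `summary.csv` are
#'   written there.
#' @param tagger An [entity_tagger()].
#' @return List: `records`, `rejects`, `summary` (tibbles).
#' @export
run_corpus <- function(articles, config, tagger) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.data.frame(articles)) {
    articles <- as_tibble(articles)
    entries <- map(seq_len(nrow(articles)), function(i) {
      list(
        article_id = articles$article_id[i],
        xml_path = if ("xml_path" %in% names(articles)) articles$xml_path[i] else NA,
        text_path = if ("text_path" %in% names(articles)) articles$text_path[i] else NA
      )
    })
  } else {
    entries <- articles
  }
  ord <- order(map_chr(entries, ~ as.character(.x$article_id)))
  entries <- entries[ord]

  all_records <- list()
  all_rejects <- list()
  failed <- character()
  for (entry in entries) {
    res <- tryCatch({
      xml_doc <- entry$xml_doc
      text_doc <- entry$text_doc
      if (is.null(xml_doc) && !is.null(entry$xml_path) &&
          !is.na(entry$xml_path)) {
        xml_doc <- parse_structured_article(
          entry$xml_path, article_id = entry$article_id,
          references_patterns = config$profile$references_patterns
        )
      }
      if (is.null(text_doc) && !is.null(entry$text_path) &&
          !is.na(entry$text_path)) {
        text_doc <- parse_plain_text(
          entry$text_path, article_id = entry$article_id,
          references_patterns = config$profile$references_patterns
        )
      }
      suppressMessages(
        run_article(xml_doc, text_doc, config = config, tagger = tagger)
      )
    }, error = function(e) {
      warn(paste0("Article '", entry$article_id, "' failed: ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, entry$article_id)
    } else {
      all_records[[length(all_records) + 1L]] <- res$records
      all_rejects[[length(all_rejects) + 1L]] <- res$rejects
    }
  }

  records <- bind_rows(empty_records(), list_rbind(all_records))
  rejects <- bind_rows(empty_rejects(), list_rbind(all_rejects))

  reject_counts <- rejects |>
    group_by(.data$rejection_reason) |>
    summarise(n = n(), .groups = "drop")
  summary <- tibble(
    metric = c(
      "articles_processed", "articles_failed", "locations_kept",
      "candidates_rejected",
      paste0("rejected_", reject_counts$rejection_reason, recycle0 = TRUE)
    ),
    value = c(
      length(entries) - length(failed), length(failed), nrow(records),
      nrow(rejects), reject_counts$n
    )
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_records_table(records,
                        file.path(config$output_dir, "records.csv"))
    write_records_jsonl(records,
                        file.path(config$output_dir, "records.jsonl"))
    readr::write_csv(rejects, file.path(config$output_dir, "rejects.csv"))
    readr::write_csv(summary, file.path(config$output_dir, "summary.csv"))
  }

  list(records = records, rejects = rejects, summary = summary)
}

#' Enumerate a corpus directory pair
#'
#' @param xml_dir,text_dir Directories of per-article `.xml` / `.txt`
#'   files; file stems are article ids. Either may be `NULL`.
#' @return A tibble with columns `article_id`, `xml_path`, `text_path`.
#' @export
read_corpus_dir <- function(xml_dir = NULL, text_dir = NULL) {
  xml_files <- if (!is.null(xml_dir)) {
    list.files(xml_dir, pattern = "\\.xml$", full.names = TRUE)
  } else character()
  text_files <- if (!is.null(text_dir)) {
    list.files(text_dir, pattern = "\\.txt$", full.names = TRUE)
  } else character()
  ids <- sort(unique(c(
    tools::file_path_sans_ext(basename(xml_files)),
    tools::file_path_sans_ext(basename(text_files))
  )))
  if (length(ids) == 0) abort("No articles found.")
  xml_map <- stats::setNames(xml_files,
                             tools::file_path_sans_ext(basename(xml_files)))
  text_map <- stats::setNames(text_files,
                              tools::file_path_sans_ext(basename(text_files)))
  tibble(
    article_id = ids,
    xml_path = unname(xml_map[ids]),
    text_path = unname(text_map[ids])
  )
}
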