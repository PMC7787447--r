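#' Built-in place table used by the synthetic-corpus generator
#'
#' A small table of real-world cities, countries and medical institutions
#' with approximate coordinates, used to build the toy gazetteer and mock
#' tagger lexicon that synthetic corpora draw from.
#'
#' @return Tibble with gazetteer-style columns (`record_id`,
#'   `primary_name`, `alternate_names`, `feature_class`, `latitude`,
#'   `longitude`, `population`, `country_code`, `admin_path`).
#' @export
builtin_places <- function() {
  city <- function(id, name, admin1, country, cc, lat, lon, pop) {
    tibble(
      record_id = id, primary_name = name, alternate_names = "",
      feature_class = "P", latitude = lat, longitude = lon,
      population = pop, country_code = cc,
      admin_path = paste(admin1, country, sep = "|")
    )
  }
  country <- function(id, name, cc, lat, lon, pop, alts = "") {
    tibble(
      record_id = id, primary_name = name, alternate_names = alts,
      feature_class = "A", latitude = lat, longitude = lon,
      population = pop, country_code = cc, admin_path = ""
    )
  }
  poi <- function(id, name, city, country, cc, lat, lon) {
    tibble(
      record_id = id, primary_name = name, alternate_names = "",
      feature_class = "S", latitude = lat, longitude = lon,
      population = 0, country_code = cc,
      admin_path = paste(city, country, sep = "|")
    )
  }
  bind_rows(
    city("c001", "Seville", "Andalusia", "Spain", "ES", 37.39, -5.98, 688000),
    city("c002", "Valencia", "Valencia", "Spain", "ES", 39.47, -0.38, 791000),
    city("c003", "Florence", "Tuscany", "Italy", "IT", 43.77, 11.26, 382000),
    city("c004", "Bologna", "Emilia-Romagna", "Italy", "IT", 44.49, 11.34, 388000),
    city("c005", "Nancy", "Grand Est", "France", "FR", 48.69, 6.18, 104000),
    city("c006", "Avignon", "Provence", "France", "FR", 43.95, 4.81, 92000),
    city("c007", "Zurich", "Zurich", "Switzerland", "CH", 47.37, 8.54, 402000),
    city("c008", "Bern", "Bern", "Switzerland", "CH", 46.95, 7.45, 133000),
    city("c009", "Freiburg", "Baden-Wurttemberg", "Germany", "DE", 47.99, 7.85, 230000),
    city("c010", "Jena", "Thuringia", "Germany", "DE", 50.93, 11.59, 111000),
    city("c011", "Uppsala", "Uppsala County", "Sweden", "SE", 59.86, 17.64, 166000),
    city("c012", "Wageningen", "Gelderland", "Netherlands", "NL", 51.97, 5.67, 39000),
    city("c013", "Thessaloniki", "Macedonia", "Greece", "GR", 40.64, 22.94, 325000),
    city("c014", "Porto", "Norte", "Portugal", "PT", 41.15, -8.61, 237000),
    city("c015", "Izmir", "Aegean", "Turkey", "TR", 38.42, 27.13, 2937000),
    city("c016", "Boston", "MA", "USA", "US", 42.36, -71.06, 692000),
    city("c017", "Madison", "WI", "USA", "US", 43.07, -89.40, 269000),
    city("c018", "Davis", "CA", "USA", "US", 38.55, -121.74, 68000),
    city("c019", "Ithaca", "NY", "USA", "US", 42.44, -76.50, 31000),
    city("c020", "Guelph", "Ontario", "Canada", "CA", 43.55, -80.25, 132000),
    city("c021", "Adelaide", "South Australia", "Australia", "AU", -34.93, 138.60, 1345000),
    city("c022", "Stellenbosch", "Western Cape", "South Africa", "ZA", -33.93, 18.86, 156000),
    city("c023", "Mendoza", "Mendoza Province", "Argentina", "AR", -32.89, -68.83, 115000),
    city("c024", "Nagano", "Nagano Prefecture", "Japan", "JP", 36.65, 138.18, 377000),
    city("c025", "London", "England", "United Kingdom", "GB", 51.51, -0.13, 8982000),
    city("c026", "Stockholm", "Stockholm County", "Sweden", "SE", 59.33, 18.07, 975000),
    city("c027", "Helsinki", "Uusimaa", "Finland", "FI", 60.17, 24.94, 656000),
    city("c028", "Toronto", "Ontario", "Canada", "CA", 43.65, -79.38, 2930000),
    city("c029", "Heidelberg", "Baden-Wurttemberg", "Germany", "DE", 49.40, 8.67, 160000),
    country("n001", "Spain", "ES", 40.2, -3.5, 47400000),
    country("n002", "Italy", "IT", 42.5, 12.5, 58900000),
    country("n003", "France", "FR", 46.6, 2.2, 68000000),
    country("n004", "Switzerland", "CH", 46.8, 8.2, 8700000),
    country("n005", "Germany", "DE", 51.1, 10.4, 83200000),
    country("n006", "Sweden", "SE", 62.0, 15.0, 10500000),
    country("n007", "Netherlands", "NL", 52.2, 5.3, 17700000),
    country("n008", "Greece", "GR", 39.0, 22.0, 10400000),
    country("n009", "Portugal", "PT", 39.6, -8.0, 10300000),
    country("n010", "Turkey", "TR", 39.0, 35.0, 85000000),
    country("n011", "USA", "US", 39.8, -98.6, 331900000,
            alts = "United States|United States of America|US"),
    country("n012", "Canada", "CA", 56.1, -106.3, 38200000),
    country("n013", "Australia", "AU", -25.3, 133.8, 25700000),
    country("n014", "South Africa", "ZA", -28.5, 24.7, 59400000),
    country("n015", "Argentina", "AR", -34.0, -64.0, 45800000),
    country("n016", "Japan", "JP", 36.2, 138.3, 125700000),
    country("n017", "United Kingdom", "GB", 54.0, -2.0, 67300000,
            alts = "UK|Great Britain"),
    country("n018", "Finland", "FI", 64.0, 26.0, 5500000),
    poi("h001", "Massachusetts General Hospital", "Boston", "USA", "US",
        42.363, -71.069),
    poi("h002", "Royal Free Hospital", "London", "United Kingdom", "GB",
        51.553, -0.165),
    poi("h003", "Karolinska University Hospital", "Stockholm", "Sweden", "SE",
        59.352, 18.027),
    poi("h004", "University Hospital Zurich", "Zurich", "Switzerland", "CH",
        47.376, 8.551),
    poi("h005", "Helsinki University Hospital", "Helsinki", "Finland", "FI",
        60.168, 24.959),
    poi("h006", "Toronto General Hospital", "Toronto", "Canada", "CA",
        43.659, -79.388),
    poi("h007", "Heidelberg University Hospital", "Heidelberg", "Germany",
        "DE", 49.417, 8.671),
    poi("h008", "Mayo Clinic", "Rochester", "USA", "US", 44.022, -92.467)
  )
}

#' Build a mock-tagger lexicon from a gazetteer
#'
#' Maps every gazetteer name (primary and alternate) to a tag: LOCATION by
#' default, ORGANIZATION for institutional names (hospitals, universities,
#' institutes, clinics), mirroring how a 3-class NER model labels such
#' entities. Extra entities (person names, company names) are appended.
#' Duplicate phrases are deduplicated with precedence LOCATION >
#' ORGANIZATION > PERSON; output order is deterministic (alphabetical by
#' phrase).
#'
#' @param gazetteer A [load_gazetteer()] object.
#' @param extra_entities Optional tibble (`phrase`, `tag`).
#' @return Tibble (`phrase`, `tag`) suitable for [lexicon_tagger()].
#' @export
build_mock_lexicon <- function(gazetteer, extra_entities = NULL) {
  stopifnot(inherits(gazetteer, "gazetteer"))
  rec <- gazetteer$records
  org_pat <- regex("hospital|university|institute|clinic|medical|centre|center",
                   ignore_case = TRUE)
  names_df <- bind_rows(
    tibble(phrase = rec$primary_name),
    tibble(phrase = unlist(rec$alternate_names))
  ) |>
    filter(nzchar(.data$phrase)) |>
    mutate(tag = ifelse(str_detect(.data$phrase, org_pat),
                        "ORGANIZATION", "LOCATION"))
  lex <- bind_rows(names_df, as_tibble(extra_entities))
  precedence <- c(LOCATION = 1L, ORGANIZATION = 2L, PERSON = 3L, OTHER = 4L)
  lex |>
    mutate(.prec = precedence[.data$tag]) |>
    arrange(.data$phrase, .data$.prec) |>
    distinct(.data$phrase, .keep_all = TRUE) |>
    select("phrase", "tag") |>
    arrange(.data$phrase)
}

xml_escape <- function(x) {
  x <- str_replace_all(x, fixed("&"), "&amp;")
  x <- str_replace_all(x, fixed("<"), "&lt;")
  str_replace_all(x, fixed(">"), "&gt;")
}

# Render a section list (heading, paragraphs) to the JATS-ish XML dialect
# and to the plain-text representation the pipeline consumes.
render_article_xml <- function(title, sections) {
  body <- map_chr(sections, function(sec) {
    paste0(
      "    <sec>\n      <title>", xml_escape(sec$heading), "</title>\n",
      paste0("      <p>", xml_escape(sec$paragraphs), "</p>",
             collapse = "\n"),
      "\n    </sec>"
    )
  })
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<article>\n  <front>\n    <article-meta>\n      <title-group>\n",
    "        <article-title>", xml_escape(title), "</article-title>\n",
    "      </title-group>\n    </article-meta>\n  </front>\n  <body>\n",
    paste(body, collapse = "\n"),
    "\n  </body>\n</article>\n"
  )
}

render_article_text <- function(title, sections) {
  paras <- c(title, unlist(map(sections, function(sec) {
    c(sec$heading, sec$paragraphs)
  })))
  paste0(paste(paras, collapse = "\n\n"), "\n")
}

#' Generate a synthetic article corpus
#'
#' Writes a complete, self-contained test corpus: articles in both the
#' structured-XML and plain-text representations, a ground-truth annotation
#' file listing every planted relevant location, a toy gazetteer, and a
#' mock-tagger lexicon. Articles follow the shape of real full text: a
#' title (with a study location for the orchards-like template), an
#' introduction, a relevant methods/study-site (or patients/samples)
#' section holding the planted locations and any distractors, a results
#' section, and a references section. Distractor sentences are company
#' parentheticals — always containing a discard word, so the full filter
#' provably removes them — and author-year citations. All randomness flows
#' from `seed`; the same seed and settings give byte-identical files.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed governing all randomness.
#' @param n_articles Number of articles.
#' @param relevant_range Inclusive range of planted relevant locations per
#'   article (for articles with reportable locations).
#' @param distractor_range Inclusive range of distractor sentences per
#'   article.
#' @param style `"orchards"` (ecology-like: study sites, titles carry
#'   locations, uniformly good reporting quality) or `"cancer"`
#'   (biomedical-like: hospitals and cities, no title locations, a mix of
#'   none/bad/medium/good reporting quality).
#' @param heading_style Which representations to write: `"both"`, `"xml"`
#'   or `"plain"`.
#' @return Invisibly, a list: `articles` (tibble of ids and paths),
#'   `truth` (tibble), `gazetteer_path`, `lexicon_path`.
#' @export
generate_corpus <- function(out_dir, seed = 1L, n_articles = 20L,
                            relevant_range = c(1L, 3L),
                            distractor_range = c(0L, 2L),
                            style = c("orchards", "cancer"),
                            heading_style = c("both", "xml", "plain")) {
  style <- match.arg(style)
  heading_style <- match.arg(heading_style)
  if (relevant_range[1] > relevant_range[2] || relevant_range[1] < 0 ||
      distractor_range[1] > distractor_range[2] || distractor_range[1] < 0) {
    abort("Invalid `relevant_range` / `distractor_range` bounds.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  xml_dir <- file.path(out_dir, "xml")
  txt_dir <- file.path(out_dir, "txt")
  if (heading_style %in% c("both", "xml")) dir.create(xml_dir, showWarnings = FALSE)
  if (heading_style %in% c("both", "plain")) dir.create(txt_dir, showWarnings = FALSE)

  places <- builtin_places()
  gaz_path <- file.path(out_dir, "gazetteer.tsv")
  readr::write_tsv(places, gaz_path, col_names = FALSE)
  gaz <- suppressMessages(load_gazetteer(gaz_path))

  persons <- c("Smith", "Johnson", "Muller", "Tanaka", "Rossi", "Garcia")
  companies <- c("Acme Inc", "BioSupply Ltd", "Genomix GmbH", "AgriTech Corp")
  lexicon <- build_mock_lexicon(
    gaz,
    extra_entities = bind_rows(
      tibble(phrase = persons, tag = "PERSON"),
      tibble(phrase = companies, tag = "ORGANIZATION")
    )
  )
  lex_path <- file.path(out_dir, "lexicon.tsv")
  readr::write_tsv(lexicon, lex_path, col_names = FALSE)

  cities <- filter(places, .data$feature_class == "P")
  hospitals <- filter(places, .data$feature_class == "S")
  country_of <- function(city_row) {
    path <- str_split(city_row$admin_path, fixed("|"))[[1]]
    path[length(path)]
  }

  truth_rows <- list()
  article_rows <- list()
  sample_range <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1)

  withr::with_seed(seed, {
    for (k in seq_len(n_articles)) {
      article_id <- sprintf("%s-%03d", style, k)
      quality <- if (style == "orchards") "good" else {
        sample(c("good", "medium", "bad", "none"), 1,
               prob = c(0.6, 0.2, 0.1, 0.1))
      }
      n_rel <- if (quality %in% c("bad", "none")) 0L else if (quality == "medium") 1L else {
        sample_range(relevant_range[1], relevant_range[2])
      }
      n_dis <- sample_range(distractor_range[1], distractor_range[2])

      # draw relevant and distractor places, disjoint within the article
      city_pool <- cities[sample(nrow(cities)), ]
      hosp_pool <- hospitals[sample(nrow(hospitals)), ]
      rel <- list()
      ci <- 1; hi <- 1
      if (n_rel > 0) {
        for (j in seq_len(n_rel)) {
          use_hospital <- style == "cancer" &&
            (quality == "medium" || stats::runif(1) < 0.5) &&
            hi <= nrow(hosp_pool)
          if (use_hospital) {
            h <- hosp_pool[hi, ]; hi <- hi + 1
            rel[[j]] <- list(string = h$primary_name, rec = h)
          } else {
            cty <- city_pool[ci, ]; ci <- ci + 1
            rel[[j]] <- list(
              string = paste0(cty$primary_name, ", ", country_of(cty)),
              rec = cty
            )
          }
        }
      }

      rel_templates <- if (style == "orchards") c(
        "Field work was conducted in %s.",
        "The experimental orchard was located in %s.",
        "Sampling took place in %s over two consecutive seasons."
      ) else c(
        "Patients were recruited in %s.",
        "Tumour specimens were obtained from patients treated at %s.",
        "Samples were collected at %s."
      )
      rel_sentences <- map_chr(seq_along(rel), function(j) {
        sprintf(rel_templates[((j - 1) %% length(rel_templates)) + 1],
                rel[[j]]$string)
      })
      if (quality == "bad") {
        rel_sentences <- "Samples were obtained as described previously."
      }
      if (quality == "none") {
        rel_sentences <- "Sample provenance was not recorded for this cohort."
      }

      dis_sentences <- character()
      if (n_dis > 0) {
        for (d in seq_len(n_dis)) {
          if (d == 1) {
            comp <- sample(companies, 1)
            cty <- city_pool[ci, ]; ci <- ci + 1
            dis_sentences <- c(dis_sentences, sprintf(
              "Reagents were purchased commercially (%s., %s, %s).",
              comp, cty$primary_name, country_of(cty)
            ))
          } else {
            dis_sentences <- c(dis_sentences, sprintf(
              "All procedures followed established protocols (%s %d).",
              sample(persons, 1), sample(1990:2015, 1)
            ))
          }
        }
      }

      rel_heading <- if (style == "orchards") {
        sample(c("Study site", "Materials and methods", "Study area",
                 "2.1 Study site description"), 1)
      } else {
        sample(c("Patients and samples", "Materials and methods",
                 "Patients", "Samples and methods"), 1)
      }

      title <- if (style == "orchards" && n_rel > 0) {
        sprintf("Arthropod diversity in fruit orchards in %s",
                rel[[1]]$string)
      } else if (style == "orchards") {
        "Arthropod diversity in fruit orchards"
      } else {
        "Genomic profiling of tumour samples by comparative hybridization"
      }

      sections <- list(
        list(
          heading = "Introduction",
          paragraphs = paste(
            "Agricultural intensification has altered biodiversity over",
            "recent decades, and long-term monitoring remains scarce."
          )
        ),
        list(
          heading = rel_heading,
          paragraphs = paste(c(rel_sentences, dis_sentences), collapse = " ")
        ),
        list(
          heading = "Results",
          paragraphs = paste(
            "Species richness differed between management regimes, and",
            "abundance varied across seasons."
          )
        ),
        list(
          heading = "References",
          paragraphs = paste0(
            sample(persons, 1), " J (",
            sample(1990:2015, 1),
            ") Long-term monitoring of managed systems. Journal of Applied",
            " Studies 12:1-10."
          )
        )
      )

      xml_path <- NA_character_
      text_path <- NA_character_
      if (heading_style %in% c("both", "xml")) {
        xml_path <- file.path(xml_dir, paste0(article_id, ".xml"))
        writeLines(render_article_xml(title, sections), xml_path, sep = "")
      }
      if (heading_style %in% c("both", "plain")) {
        text_path <- file.path(txt_dir, paste0(article_id, ".txt"))
        writeLines(render_article_text(title, sections), text_path, sep = "")
      }
      article_rows[[k]] <- tibble(
        article_id = article_id, xml_path = xml_path, text_path = text_path,
        location_quality = quality
      )

      if (n_rel > 0) {
        truth_rows[[length(truth_rows) + 1L]] <- list_rbind(
          map(rel, function(r) tibble(
            article_id = article_id,
            truth_string = r$string,
            truth_record_id = r$rec$record_id,
            truth_lat = r$rec$latitude,
            truth_lon = r$rec$longitude,
            location_quality = quality
          ))
        )
      } else {
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          article_id = article_id, truth_string = NA_character_,
          truth_record_id = NA_character_, truth_lat = NA_real_,
          truth_lon = NA_real_, location_quality = quality
        )
      }
    }
  })

  truth <- list_rbind(truth_rows)
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, na = "")

  invisible(list(
    articles = list_rbind(article_rows),
    truth = truth,
    truth_path = truth_path,
    gazetteer_path = gaz_path,
    lexicon_path = lex_path,
    xml_dir = if (heading_style %in% c("both", "xml")) xml_dir else NULL,
    text_dir = if (heading_style %in% c("both", "plain")) txt_dir else NULL
  ))
}
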