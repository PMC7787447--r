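---
title: "Extracting relevant locations from scientific full text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting relevant locations from scientific full text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(geosift)
```

## The problem and the model

An article's full text mentions many places; only a few describe where the
science happened. geosift treats relevant-location extraction as a
two-sided precision/recall problem and splits it into a *high-recall*
identification stage and a *high-precision* filtering stage, with two
structural priors doing most of the work:

1. **Relevant locations concentrate in predictable sections** — methods,
   study-site, patients/samples sections, and (in some domains) the
   title. Section targeting discards the rest of the article before any
   entity tagging happens.
2. **Irrelevant locations carry recognizable lexical signatures** —
   company suffixes ("Inc", "GmbH") in reagent parentheticals,
   author-plus-year patterns in citations, spans with no location-tagged
   token. Rule-based filtering removes them after tagging.

Both priors are configuration, not code: a `domain_profile` holds the
heading patterns, lexicons and word lists, and nothing else in the
pipeline is domain-specific. The two built-ins mirror the two corpus
archetypes the approach was developed around: an ecology-style profile
(`profile_orchards()`: study-site headings, cardinal-direction and
feature-type extension words, titles mined) and a biomedical-style
profile (`profile_cancer()`: patients/samples headings, no extension
lexicon, titles not mined — biomedical titles rarely name provenance).

Entity tagging itself sits behind a deliberately small contract: a pure
function from token surfaces to per-token tags in
`{LOCATION, PERSON, ORGANIZATION, OTHER}`. Any pretrained 3-class NER
model can be adapted to it; the package ships a deterministic
lexicon-based tagger (`lexicon_tagger()`) used by the tests and synthetic
corpora, because the scientific claims under test concern the machinery
*around* the tagger, not the tagger itself.

## Candidate assembly: the bridging predicate

The chunking stage turns tagged sentences into maximal candidate spans.
The intent — keep whole descriptions like "Nancy (East of France)" or
"Madison, WI" together because qualified strings geocode better — needs a
precise predicate. geosift's is:

* a span must contain at least one entity-tagged token;
* **interior gaps** between entity tokens may hold at most 3 consecutive
  non-entity tokens, each of which is a connector word (`in`, `upon`,
  `of`, `at`, `near`, `the`), a comma/parenthesis/period, a two-letter
  state abbreviation, or an extension-lexicon word;
* **prefix** tokens before the first entity must come from the extension
  lexicon (so "in Nancy …" does not absorb the "in");
* **suffix** tokens after the last entity may be extension words, a state
  abbreviation optionally preceded by a comma ("Madison, WI"), or a `)`
  balancing a parenthesis opened inside the span.

The 3-token gap limit stops entity-dense sentences from collapsing into
one sentence-length candidate. The asymmetry between prefix (strict) and
interior (permissive) reproduces the field's intuition that connectors
*join* locations but do not *start* them. Because the greedy left-to-right
implementation of this predicate is easy to get subtly wrong, the test
suite checks it against an independent brute-force span enumeration on
1,000 seeded random sentences of up to 12 tokens.

## Filtering and cleaning

Rules apply in a fixed order: keep-word override, discard words, the
no-LOCATION-tag rule, then tag–word combination rules. Two choices were
genuinely open:

* **Keep-words beat everything.** A candidate containing "University",
  "Hospital", "Institute" etc. survives discard *and* tag rules. The
  alternative (discard wins) would drop strings like "University of
  Helsinki Inc. spin-off" — but in the target domains hospitals and
  universities are the archetypal relevant locations and company suffixes
  inside such names are vanishingly rare, so keep-wins loses less.
* **Comma groups stay whole by default.** "Burlington, Cambridge" is kept
  as one string even when the parts are separate places, because splitting
  every comma sequence would destroy the far more common "City, Country"
  qualifications. An opt-in `split_country_lists` profile flag splits
  candidates that are entirely comma-separated country names, the one case
  that is reliably separable.

Discard-word matching is case-sensitive (word-boundary), so "AG" and "Co"
never fire on lowercase prose; keep-word matching is case-insensitive.
Cleaning strips trailing connectors and punctuation and dangling
parentheses iteratively to a fixed point; it is idempotent and never
lengthens a string (both property-tested).

## Offline geocoding

The geocoding backend contract mirrors commercial geocoders (query in,
ranked structured results out) but the bundled implementation is a local
GeoNames-style gazetteer, ranked by match class (exact primary name >
exact alternate name > all-query-tokens-contained), then descending
population — the classical population heuristic for toponym
disambiguation — then ascending record id as a total tie-break. Qualified
queries ("Paris, Texas") constrain the head match by requiring remaining
comma parts to appear in the record's admin containment path or country
code. Determinism here is what makes whole-pipeline runs byte-identical
across machines; remote services plug in behind the same contract with an
on-disk cache, but nothing in the tests touches a network.

## Evaluation design

Geocode *correctness* against ground truth needs a reproducible surrogate
for what is really a human judgment. geosift uses record-id equality when
the annotation provides an id; otherwise great-circle distance with a
granularity-scaled tolerance — 25 km for localities and points of
interest, 200 km for administrative areas — and name equality for
country-level results. The tolerances reflect gazetteer centroid
variation at each scale, not pipeline accuracy targets.

Two exclusion rules keep the article-unit averages honest: articles with
nothing extracted are excluded from the precision mean (not scored 0 or
1), and articles with no ground-truth locations are excluded from the
recall mean. Scoring empty extractions as precision 1 would reward
silence; scoring them 0 would punish abstention on articles that truly
report no location.

"Represented" for recall — and string correctness when no manual
judgments file is supplied — means case-insensitive, diacritic-normalized
equality or whole-string containment with word boundaries in either
direction, so truth "Seville" is represented by extracted "Seville,
Spain" and vice versa, while "Nice" does not match inside "Venice". A
judgments file (`read_judgments()`) overrides this for human-annotated
corpora.

The full-pipeline metric deliberately allows the pipeline to beat its own
extraction precision: a wrongly extracted string that the geocoder cannot
resolve becomes a true negative and leaves the denominator.

## The synthetic-corpus generator

`generate_corpus()` is first-class, tested code, and its defaults are the
study conditions the test suite runs under: 20 articles, 1–3 planted
relevant locations per article, 0–2 distractors, both XML and plain-text
representations. Articles have a realistic skeleton — title,
introduction, a relevant section under a sampled heading (including
numbered forms like "2.1 Study site description"), results, references —
with relevant locations drawn from a built-in gazetteer of real cities,
countries and hospitals. Distractors are company parentheticals
guaranteed to carry a discard word, and author–year citations. The
cancer-style template adds hospital names (tagged ORGANIZATION, recovered
only through keep words) and a none/bad/medium/good location-reporting
quality mix. A single seed governs all randomness through a local RNG
scope; equal seeds give byte-identical file trees.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: noisy NER output (the lexicon tagger is
perfect by construction), PDF-conversion artifacts (garbled coordinates,
broken paragraph boundaries), vague regions ("eastern Spain") that
resolve poorly, locations appearing only in acknowledgements, and
non-standard headings. On real corpora those are exactly the failure
modes the error taxonomy (`tally_errors()`) is designed to count, and
perfect synthetic scores must not be read as expected field performance.

## Numerical and degenerate-input choices

* Plain-text "paragraph beginning" = first line, capped at 120
  characters; headings converted from PDF occupy one short line, and the
  cap avoids matching mid-prose words. Plain-text target spans run to the
  next heading-like paragraph (short single line without sentence-final
  punctuation, all-caps, or numbered), capped at 10 paragraphs.
* Sentence splitting protects scientific abbreviations at word
  boundaries and never breaks inside parentheticals shorter than 60
  characters (long enough for coordinates and company addresses, short
  enough not to swallow real multi-sentence asides).
* Empty extraction → precision is `NA` ("not applicable"), never 0.
  `harmonic_f1(0, 0)` is defined as 0. Out-of-range inputs error.
* Malformed gazetteer rows are skipped with line numbers; a file with no
  valid rows errors. Undecodable bytes in plain text become U+FFFD with a
  warning.
* One failing article never aborts a corpus run; failures are counted in
  the run summary.
* Reported metrics round to 3 decimals; error-taxonomy percentages to
  one decimal (their sum can drift from 100 by up to 0.35 with seven
  rounded categories).

## Problem sizes

The test and acceptance runs use 20-article synthetic corpora, 1,000
random sentences for the assembly oracle, and 200 generated cases per
property invariant — sizes at which every behaviour under test is already
fully exercised, chosen as the package's own testing design.

## Known limitations

Coordinate strings in text are not parsed (their PDF-converted forms are
unreliable; the retained sentence context keeps them accessible to human
annotators). Compositional descriptions ("30 km from Florence") are
retained only via sentence context, not interpreted. All geocodes are
point representations; bounding boxes pass through when a backend
supplies them, but no polygon geometries. There is no cross-location
disambiguation (e.g. minimizing pairwise distance among an article's
locations) — strings geocode independently. Acknowledgements sections are
not mined. Semantic sentence classification is a plausible alternative
architecture, deliberately out of scope here.
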