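#' Default diagnosis pattern set
#'
#' Regex patterns for mining self-reported diagnosis statements. Three
#' classes: `inclusion` patterns match statements of a received
#' bipolar-disorder diagnosis ("I was diagnosed with bipolar disorder");
#' `exclusion` patterns void a candidate ("not officially diagnosed",
#' "self-diagnosed", ...); `other_diagnoses` maps labels for further
#' conditions to their statement patterns, with `psychotic_disorder`
#' mandatory because a reported psychotic-disorder diagnosis removes a user
#' from the cohort (whereas a major-depressive-disorder statement does not:
#' a large share of people diagnosed with bipolar disorder first received a
#' depression diagnosis).
#'
#' The original research pipelines use on the order of 74 exclusion
#' patterns; the shipped default is a smaller, documented set built from the
#' canonical examples. Supply your own pattern file via
#' [read_patterns_yaml()] as the source of truth for real analyses.
#'
#' @return A `diagnosis_patterns` object.
#' @export
default_patterns <- function() {
  diagnosis_patterns(
    inclusion = c(
      "i\\s+(?:was|am|have\\s+been|got|'ve\\s+been|recently\\s+got)\\s+(?:officially\\s+|formally\\s+|recently\\s+|just\\s+)?diagnosed\\s+(?:with|as)\\s+(?:having\\s+)?bipolar",
      "(?:doctor|psychiatrist|psych|therapist)\\s+(?:has\\s+)?diagnosed\\s+me\\s+with\\s+bipolar",
      "my\\s+bipolar\\s+diagnosis",
      "i\\s+(?:have|received|got)\\s+a\\s+(?:bipolar|bp[12]?)\\s+(?:disorder\\s+)?diagnosis",
      "diagnosed\\s+(?:as\\s+)?bipolar(?:\\s+type)?(?:\\s+(?:1|2|i|ii|one|two))?"
    ),
    exclusion = c(
      "not\\s+officially\\s+diagnosed",
      "not\\s+formally\\s+diagnosed",
      "never\\s+(?:been\\s+)?(?:officially\\s+)?diagnosed",
      "self[\\s-]?diagnosed",
      "self[\\s-]?diagnosis",
      "un[\\s-]?diagnosed",
      "not\\s+(?:been\\s+)?diagnosed",
      "no\\s+official\\s+diagnosis",
      "without\\s+a\\s+diagnosis",
      "if\\s+i\\s+(?:was|were|got)\\s+diagnosed",
      "haven't\\s+been\\s+diagnosed",
      "waiting\\s+(?:for|on)\\s+a\\s+diagnosis"
    ),
    other_diagnoses = list(
      psychotic_disorder = c(
        "diagnosed\\s+(?:with|as)\\s+(?:having\\s+)?(?:schizophrenia|schizoaffective|schizophreniform|psychosis|a\\s+psychotic\\s+disorder)",
        "my\\s+(?:schizophrenia|schizoaffective|psychosis)\\s+diagnosis"
      ),
      major_depressive_disorder = c(
        "diagnosed\\s+(?:with|as\\s+having)\\s+(?:major\\s+)?depress(?:ion|ive\\s+disorder)",
        "my\\s+(?:major\\s+)?depression\\s+diagnosis"
      ),
      anxiety_disorder = c("diagnosed\\s+with\\s+(?:an\\s+)?(?:generalized\\s+|generalised\\s+)?anxiety\\s+disorder"),
      ptsd = c("diagnosed\\s+with\\s+(?:c-?)?ptsd"),
      ocd = c("diagnosed\\s+with\\s+ocd"),
      adhd = c("diagnosed\\s+with\\s+adh?d"),
      eating_disorder = c("diagnosed\\s+with\\s+(?:an\\s+)?(?:anorexia|bulimia|eating\\s+disorder)"),
      borderline_pd = c("diagnosed\\s+with\\s+(?:bpd|borderline)"),
      autism = c("diagnosed\\s+with\\s+(?:autism|asperger)")
    ),
    version = "peerforum-default-0.1"
  )
}

#' Construct a diagnosis pattern set
#'
#' @param inclusion Character vector of inclusion regexes (case-insensitive,
#'   Perl syntax, matched against whitespace-normalised text).
#' @param exclusion Character vector of exclusion regexes.
#' @param other_diagnoses Named list of regex vectors; must contain a
#'   `psychotic_disorder` entry.
#' @param version Free-text label.
#' @return A `diagnosis_patterns` object.
#' @export
diagnosis_patterns <- function(inclusion, exclusion, other_diagnoses,
                               version = "custom") {
  if (length(inclusion) == 0L) stop("inclusion pattern list must be non-empty")
  if (length(exclusion) == 0L) stop("exclusion pattern list must be non-empty")
  if (!"psychotic_disorder" %in% names(other_diagnoses)) {
    stop("other_diagnoses must contain a 'psychotic_disorder' entry")
  }
  if (any(vapply(other_diagnoses, length, integer(1)) == 0L)) {
    stop("other_diagnoses pattern lists must be non-empty")
  }
  structure(list(inclusion = inclusion, exclusion = exclusion,
                 other_diagnoses = other_diagnoses, version = version),
            class = "diagnosis_patterns")
}

#' Read a pattern set from YAML
#'
#' Expects keys `inclusion`, `exclusion` and `other_diagnoses` (a mapping of
#' diagnosis label to pattern list).
#'
#' @param path YAML file path.
#' @return A `diagnosis_patterns` object.
#' @export
read_patterns_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  diagnosis_patterns(
    inclusion = as.character(y$inclusion),
    exclusion = as.character(y$exclusion),
    other_diagnoses = lapply(y$other_diagnoses, as.character),
    version = basename(path)
  )
}

# collapse runs of whitespace so multi-word patterns match across line breaks
.normalise_ws <- function(text) gsub("\\s+", " ", text)

.find_class <- function(text, patterns, class, label) {
  hits <- list()
  for (pat in patterns) {
    # word-boundary anchoring; case-insensitive over normalised whitespace
    m <- gregexpr(paste0("\\b(?:", pat, ")"), text, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      hits[[length(hits) + 1L]] <- data.frame(
        class = class, label = label, start = m[k], end = m[k] + len[k] - 1L,
        match = substr(text, m[k], m[k] + len[k] - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  hits
}

#' Find diagnosis statements in a text
#'
#' Scans one text for inclusion statements, exclusion phrases and
#' other-diagnosis statements. Matching is case-insensitive over
#' whitespace-normalised text and anchored at word boundaries; exclusion
#' matches are reported independently of inclusion matches; results are in
#' left-to-right order of match start.
#'
#' @param text A single string (may be empty).
#' @param patterns A `diagnosis_patterns` object.
#' @return A tibble with columns `class` (`inclusion` / `exclusion` /
#'   `other`), `label` (`bipolar`, the exclusion class, or the diagnosis
#'   label), `start`, `end`, `match`.
#' @export
#' @examples
#' find_statements("I was diagnosed with bipolar disorder last year",
#'                 default_patterns())
find_statements <- function(text, patterns) {
  stopifnot(inherits(patterns, "diagnosis_patterns"), length(text) == 1L)
  empty <- tibble::tibble(class = character(), label = character(),
                          start = integer(), end = integer(),
                          match = character())
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- .normalise_ws(text)
  hits <- c(
    .find_class(text, patterns$inclusion, "inclusion", "bipolar"),
    .find_class(text, patterns$exclusion, "exclusion", "exclusion_phrase")
  )
  for (lab in names(patterns$other_diagnoses)) {
    hits <- c(hits, .find_class(text, patterns$other_diagnoses[[lab]], "other", lab))
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end), , drop = FALSE]
  # de-duplicate overlapping matches of the same class+label (several
  # patterns can fire on one statement)
  key <- paste(out$class, out$label, out$start)
  out <- out[!duplicated(key), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Decide cohort membership for one author
#'
#' A user is included iff at least one post carries a bipolar-diagnosis
#' inclusion statement, no post carries an exclusion phrase, and no post
#' carries a psychotic-disorder statement. Statements of other diagnoses
#' (major depressive disorder in particular) do not exclude. Exclusion is
#' user-level: any post at any time counts.
#'
#' @param texts Character vector: all post bodies of one author.
#' @param patterns A `diagnosis_patterns` object.
#' @param author Optional author name carried into the result.
#' @return A list with `author`, `status` (`included`/`excluded`), `reason`
#'   (`included`, `no_inclusion_match`, `exclusion_pattern`,
#'   `psychotic_comorbidity`) and `evidence` (tibble of matches).
#' @export
classify_user <- function(texts, patterns, author = NA_character_) {
  matches <- lapply(texts, find_statements, patterns = patterns)
  ev <- if (length(matches) > 0L) do.call(rbind, matches) else find_statements("", patterns)
  has_inclusion <- any(ev$class == "inclusion")
  has_exclusion <- any(ev$class == "exclusion")
  has_psychotic <- any(ev$class == "other" & ev$label == "psychotic_disorder")
  reason <- if (!has_inclusion) {
    "no_inclusion_match"
  } else if (has_exclusion) {
    "exclusion_pattern"
  } else if (has_psychotic) {
    "psychotic_comorbidity"
  } else {
    "included"
  }
  list(author = author,
       status = if (reason == "included") "included" else "excluded",
       reason = reason,
       evidence = tibble::as_tibble(ev))
}

#' Build the analysis cohort from a corpus
#'
#' Applies [classify_user()] to every author and returns the included author
#' set, the per-author decisions and a corpus summary.
#'
#' @param posts Post tibble (from [read_posts()] or [synth_generate()]).
#' @param patterns A `diagnosis_patterns` object, default [default_patterns()].
#' @return A list: `authors` (character vector of included authors),
#'   `decisions` (tibble author/status/reason), `summary` (list with
#'   `n_users`, `n_posts`, `n_included`, `frac_single_post`).
#' @export
build_cohort <- function(posts, patterns = default_patterns()) {
  validate_posts(posts)
  by_author <- split(posts$body, posts$author)
  decisions <- lapply(names(by_author), function(a) {
    d <- classify_user(by_author[[a]], patterns, author = a)
    data.frame(author = a, status = d$status, reason = d$reason,
               stringsAsFactors = FALSE)
  })
  decisions <- if (length(decisions) > 0L) {
    tibble::as_tibble(do.call(rbind, decisions))
  } else {
    tibble::tibble(author = character(), status = character(), reason = character())
  }
  n_posts_per_author <- vapply(by_author, length, integer(1))
  list(
    authors = decisions$author[decisions$status == "included"],
    decisions = decisions,
    summary = list(
      n_users = length(by_author),
      n_posts = nrow(posts),
      n_included = sum(decisions$status == "included"),
      frac_single_post = if (length(by_author) > 0L) mean(n_posts_per_author == 1L) else NA_real_
    )
  )
}
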