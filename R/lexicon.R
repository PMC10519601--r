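#' Tokenise text for dictionary scoring
#'
#' Word-count semantics used throughout the package: text is lower-cased and
#' split on whitespace; leading and trailing punctuation is stripped from
#' each fragment; internal apostrophes are kept (`"don't"` is one token);
#' fragments that are pure punctuation are dropped; numerals count as
#' tokens. The token count is the `wc` denominator of every category score
#' and the basis of the 25-word reliability filter.
#'
#' @param text Character vector.
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of such vectors.
#' @export
#' @examples
#' tokenize("Don't worry — I'm fine.")
tokenize <- function(text) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    frags <- strsplit(tolower(s), "\\s+")[[1]]
    toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", frags)
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Construct an affect lexicon
#'
#' A lexicon maps each of the five category labels used in this package --
#' `posemo` (positive emotion), `anxiety`, `anger`, `sadness` and `i`
#' (first-person singular pronouns) -- to a set of entries. An entry is a
#' literal lower-case word or a stem with a trailing `*` wildcard
#' (`worri*` matches `worried`, `worries`, ...).
#'
#' @param entries Named list, one character vector per category.
#' @param version Free-text version label.
#' @return An `affect_lexicon` object.
#' @export
affect_lexicon <- function(entries, version = "custom") {
  cats <- c("posemo", "anxiety", "anger", "sadness", "i")
  miss <- setdiff(cats, names(entries))
  if (length(miss) > 0L) stop("lexicon missing categor",
                              if (length(miss) > 1) "ies: " else "y: ",
                              paste(miss, collapse = ", "))
  entries <- entries[cats]
  for (cat in cats) {
    e <- entries[[cat]]
    if (length(e) == 0L) stop("category '", cat, "' has no entries")
    if (any(e != tolower(e))) stop("entries must be lower-case (category '", cat, "')")
    star <- grepl("\\*", e)
    if (any(star & !grepl("^[^*]+\\*$", e))) {
      stop("wildcard '*' allowed only in final position (category '", cat, "')")
    }
  }
  structure(list(categories = cats, entries = entries, version = version),
            class = "affect_lexicon")
}

#' @export
print.affect_lexicon <- function(x, ...) {
  cat("<affect_lexicon ", x$version, ">\n", sep = "")
  for (cat in x$categories) {
    n <- length(x$entries[[cat]])
    cat(" ", format(cat, width = 8), n, "entr", if (n == 1) "y" else "ies", "\n")
  }
  invisible(x)
}

#' Read a lexicon from a YAML file
#'
#' Native lexicon format: a YAML mapping `{category: [entries]}` with the
#' five categories `posemo`, `anxiety`, `anger`, `sadness`, `i`.
#'
#' @param path YAML file path.
#' @param version Version label, defaults to the file name.
#' @return An `affect_lexicon`.
#' @export
read_lexicon_yaml <- function(path, version = basename(path)) {
  entries <- yaml::read_yaml(path)
  entries <- lapply(entries, as.character)
  affect_lexicon(entries, version = version)
}

#' The bundled open affect lexicon
#'
#' A small open vocabulary covering the five categories, seeded from the
#' standard example words for each category (love/nice/sweet,
#' worried/fearful, hate/kill/annoyed, crying/grief/sad, I/me/mine) and
#' extended with common synonyms and inflections. It supports reproducible
#' tests and synthetic studies; analyses of real text should supply the full
#' proprietary dictionary via [read_dic()], with which this scorer is
#' entry-format compatible.
#'
#' @return An `affect_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon_yaml(
    system.file("extdata", "affect_lexicon.yaml", package = "peerforum",
                mustWork = TRUE),
    version = "peerforum-open-0.1"
  )
}

#' Read a `%`-delimited dictionary file
#'
#' Parses the classic dictionary dialect: a header block delimited by two
#' `%` lines containing `<id><TAB><category>` declarations, followed by
#' `<word><TAB><id>...` entry lines. Only the five target categories are
#' retained (recognised header names: `posemo`, `anx`/`anxiety`, `anger`,
#' `sad`/`sadness`, `i`); other categories are ignored, with a message
#' giving the count. A word line referencing an undeclared id is an error.
#'
#' @param path Dictionary file path.
#' @return An `affect_lexicon`.
#' @export
read_dic <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("not a %-delimited dictionary: header block not found")
  header <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  header <- header[nzchar(trimws(header))]
  hparts <- strsplit(trimws(header), "[\t ]+")
  ids <- vapply(hparts, `[[`, character(1), 1L)
  cat_names <- tolower(vapply(hparts, `[[`, character(1), 2L))
  alias <- c(posemo = "posemo", anx = "anxiety", anxiety = "anxiety",
             anger = "anger", sad = "sadness", sadness = "sadness", i = "i")
  mapped <- unname(alias[cat_names])
  ignored <- sum(is.na(mapped))
  if (ignored > 0L) message("read_dic: ignoring ", ignored,
                            " non-target categor", if (ignored > 1) "ies" else "y")
  id_map <- stats::setNames(mapped, ids)
  body <- lines[-seq_len(pct[2])]
  body <- body[nzchar(trimws(body))]
  entries <- list(posemo = character(), anxiety = character(),
                  anger = character(), sadness = character(), i = character())
  for (ln in body) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    word <- tolower(parts[1L])
    wids <- parts[-1L]
    unknown <- setdiff(wids, names(id_map))
    if (length(unknown) > 0L) {
      stop("word '", word, "' references undeclared category id ", unknown[[1L]])
    }
    for (cat in unique(stats::na.omit(id_map[wids]))) {
      entries[[cat]] <- c(entries[[cat]], word)
    }
  }
  empty <- names(entries)[vapply(entries, length, integer(1)) == 0L]
  if (length(empty) > 0L) stop("dictionary covers no words for: ",
                               paste(empty, collapse = ", "))
  affect_lexicon(lapply(entries, unique), version = basename(path))
}

# tokens matching a category's entry set; each token counts once per
# category even if it matches several entries
.match_category <- function(tokens, entries) {
  star <- grepl("\\*$", entries)
  literals <- entries[!star]
  stems <- sub("\\*$", "", entries[star])
  hit <- tokens %in% literals
  for (st in stems) hit <- hit | startsWith(tokens, st)
  hit
}

#' Score a text against the lexicon
#'
#' Computes the category percentage scores: for each category, 100 times the
#' share of tokens matching that category's entries. The denominator is the
#' full token count (dictionary and non-dictionary words alike). A token may
#' contribute to several categories, but counts at most once within each. A
#' zero-length text has `wc = 0` and all scores 0 (flagged unusable by the
#' word-count filter downstream).
#'
#' @param text Character vector of texts.
#' @param lexicon An `affect_lexicon`.
#' @return A tibble with one row per text: `wc` plus the five scores
#'   (`posemo`, `anxiety`, `anger`, `sadness`, `i`), each in `[0, 100]`.
#' @export
#' @examples
#' score_text("I am worried", default_lexicon())
score_text <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "affect_lexicon"))
  toks <- tokenize(text)
  if (length(text) == 1L) toks <- list(toks)
  n <- length(toks)
  wc <- vapply(toks, length, integer(1))
  out <- tibble::tibble(wc = wc)
  for (cat in lexicon$categories) {
    counts <- vapply(toks, function(tk) sum(.match_category(tk, lexicon$entries[[cat]])),
                     numeric(1))
    out[[cat]] <- ifelse(wc > 0L, 100 * counts / wc, 0)
  }
  out
}

#' Score every post in a corpus
#'
#' @param posts Post tibble (needs a `body` column).
#' @param lexicon An `affect_lexicon`.
#' @return `posts` with the `wc` and five score columns appended.
#' @export
score_posts <- function(posts, lexicon) {
  scores <- score_text(posts$body, lexicon)
  if (nrow(posts) == 0L) {
    scores <- scores[0, ]
  }
  tibble::as_tibble(cbind(posts, scores))
}

#' Apply the minimum-word-count reliability filter
#'
#' Dictionary percentage estimates are unreliable for very short texts;
#' analyses keep only posts of at least `min_wc` words (default 25).
#'
#' @param scored Tibble with a `wc` column (e.g. from [score_posts()]).
#' @param min_wc Minimum token count, inclusive.
#' @return The rows with `wc >= min_wc`.
#' @export
filter_min_words <- function(scored, min_wc = 25L) {
  stopifnot("wc" %in% names(scored), min_wc >= 0)
  scored[scored$wc >= min_wc, , drop = FALSE]
}
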