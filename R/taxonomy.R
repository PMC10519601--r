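#' Load a subreddit topic taxonomy
#'
#' Reads a CSV taxonomy mapping subreddit names to a topic path of up to four
#' levels plus two flags: `is_mh` (community with a mental-health focus) and
#' `is_bd` (bipolar-specific community). Names are normalised by lower-casing
#' and trimming; a bipolar-specific entry must also be flagged mental-health.
#'
#' The full research taxonomies in this area list on the order of 150+
#' mental-health subreddits (of which a few dozen are bipolar-specific);
#' those lists are inputs to this function, not shipped verbatim. A small
#' demonstration taxonomy is bundled, see [example_taxonomy_path()].
#'
#' @param path CSV with header `name,level1,level2,level3,level4,is_mh,is_bd`.
#' @return A `subreddit_taxonomy` object: tibble with normalised `name`,
#'   topic levels, logical `is_mh`, `is_bd`, plus a `provenance` attribute.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("name", "level1", "level2", "level3", "level4", "is_mh", "is_bd")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("taxonomy missing column(s): ",
                              paste(miss, collapse = ", "))
  name <- normalise_subreddit(tab$name)
  if (anyDuplicated(name) > 0L) {
    stop("duplicate subreddit name after normalisation: ",
         name[anyDuplicated(name)])
  }
  is_mh <- tab$is_mh %in% c("1", "TRUE", "true")
  is_bd <- tab$is_bd %in% c("1", "TRUE", "true")
  if (any(is_bd & !is_mh)) {
    stop("taxonomy violation: bipolar-specific entries must be flagged is_mh (",
         paste(name[is_bd & !is_mh], collapse = ", "), ")")
  }
  out <- tibble::tibble(
    name = name,
    level1 = tab$level1, level2 = tab$level2,
    level3 = tab$level3, level4 = tab$level4,
    is_mh = is_mh, is_bd = is_bd
  )
  attr(out, "provenance") <- path
  class(out) <- c("subreddit_taxonomy", class(out))
  out
}

normalise_subreddit <- function(x) tolower(trimws(x))

#' Classify subreddits as mental-health or not
#'
#' A subreddit is classified `"MH"` when its normalised name appears in the
#' taxonomy with the mental-health flag; any other name -- including names
#' absent from the taxonomy -- is `"nonMH"`. The mental-health list is the
#' positive filter; the two-way context split is what all downstream
#' analyses consume.
#'
#' @param subreddit Character vector of subreddit names.
#' @param taxonomy A `subreddit_taxonomy` from [load_taxonomy()].
#' @return Character vector, `"MH"` or `"nonMH"`, same length as `subreddit`.
#' @export
#' @examples
#' tax <- load_taxonomy(example_taxonomy_path())
#' classify_context(c("BipolarReddit", "askreddit"), tax)
classify_context <- function(subreddit, taxonomy) {
  stopifnot(inherits(taxonomy, "subreddit_taxonomy"))
  mh_names <- taxonomy$name[taxonomy$is_mh]
  ifelse(normalise_subreddit(subreddit) %in% mh_names, "MH", "nonMH")
}

#' Is a subreddit bipolar-specific?
#'
#' @inheritParams classify_context
#' @return Logical vector.
#' @export
is_bd_subreddit <- function(subreddit, taxonomy) {
  stopifnot(inherits(taxonomy, "subreddit_taxonomy"))
  normalise_subreddit(subreddit) %in% taxonomy$name[taxonomy$is_bd]
}

#' Path to the bundled demonstration taxonomy
#'
#' A small taxonomy covering the four best-known bipolar-specific subreddits,
#' a handful of other mental-health communities, and several general-interest
#' communities. Intended for examples, tests and synthetic corpora; real
#' analyses should load a full research taxonomy.
#'
#' @return File path (string).
#' @export
example_taxonomy_path <- function() {
  system.file("extdata", "taxonomy_demo.csv", package = "peerforum",
              mustWork = TRUE)
}
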