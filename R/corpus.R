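#' Read a JSONL post corpus
#'
#' Reads a line-delimited JSON file of forum posts into a tibble, one post
#' per row, in file order. Each line must be a JSON object with at least the
#' keys `id`, `author`, `subreddit` and `created_utc`; `body` is optional and
#' maps to the empty string when absent. Submissions carrying a separate
#' `title` key have the title folded into `body` with a single newline, so
#' that thread starts and comments share one text field downstream.
#'
#' @param path Path to a JSONL file.
#' @param chunk_size Number of lines read per batch; memory use is bounded by
#'   the batch, not the file.
#' @return A tibble with columns `id`, `author`, `subreddit` (character),
#'   `created_utc` (double, epoch seconds, UTC) and `body` (character).
#' @seealso [write_posts()], [read_attributes()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"id":"a1","author":"u1","subreddit":"bipolar","created_utc":1500000000,"body":"hi"}',
#'   '{"id":"a2","author":"u1","subreddit":"gaming","created_utc":1500086400}'
#' ), f)
#' read_posts(f)
read_posts <- function(path, chunk_size = 10000L) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  required <- c("id", "author", "subreddit", "created_utc")
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  chunks <- list()
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    keep <- nzchar(trimws(lines))
    recs <- vector("list", sum(keep))
    j <- 0L
    for (k in seq_along(lines)) {
      ln <- line_no + k
      if (!keep[k]) next
      rec <- tryCatch(
        jsonlite::fromJSON(lines[k], simplifyVector = TRUE),
        error = function(e) stop("malformed JSON on line ", ln, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      miss <- setdiff(required, names(rec))
      if (length(miss) > 0L) {
        stop("line ", ln, ": missing field ", miss[[1L]], call. = FALSE)
      }
      body <- if (is.null(rec$body)) "" else as.character(rec$body)
      if (!is.null(rec$title) && nzchar(rec$title)) {
        body <- if (nzchar(body)) paste(rec$title, body, sep = "\n") else as.character(rec$title)
      }
      j <- j + 1L
      recs[[j]] <- list(
        id = as.character(rec$id),
        author = as.character(rec$author),
        subreddit = as.character(rec$subreddit),
        created_utc = as.numeric(rec$created_utc),
        body = body
      )
    }
    line_no <- line_no + length(lines)
    if (j > 0L) {
      chunks[[length(chunks) + 1L]] <- do.call(
        rbind, lapply(recs[seq_len(j)], as.data.frame, stringsAsFactors = FALSE)
      )
    }
  }
  out <- if (length(chunks) == 0L) {
    data.frame(id = character(), author = character(), subreddit = character(),
               created_utc = numeric(), body = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, chunks)
  }
  validate_posts(out)
  tibble::as_tibble(out)
}

#' Write a post corpus as canonical JSONL
#'
#' Serialises a post table back to line-delimited JSON with a fixed key order
#' (`id`, `author`, `subreddit`, `created_utc`, `body`), so that
#' `write_posts()` after `read_posts()` is the identity on well-formed
#' corpora and reruns are byte-identical.
#'
#' @param posts A post tibble as returned by [read_posts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  validate_posts(posts)
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(
      list(id = posts$id[i], author = posts$author[i],
           subreddit = posts$subreddit[i],
           created_utc = posts$created_utc[i], body = posts$body[i]),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Site inception: 2005-01-01T00:00:00Z.
.epoch_floor <- 1104537600

validate_posts <- function(posts) {
  stopifnot(is.data.frame(posts))
  need <- c("id", "author", "subreddit", "created_utc", "body")
  miss <- setdiff(need, names(posts))
  if (length(miss) > 0L) stop("post table missing column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(posts) == 0L) return(invisible(posts))
  if (any(!nzchar(posts$id))) stop("post ids must be non-empty")
  if (anyDuplicated(posts$id) > 0L) {
    stop("duplicate post id: ", posts$id[anyDuplicated(posts$id)])
  }
  if (any(posts$created_utc < .epoch_floor)) {
    stop("created_utc before 2005-01-01 (epoch ", .epoch_floor, ")")
  }
  invisible(posts)
}

#' Read a user-attribute table
#'
#' Reads a tab-separated table with header `author`, `age`, `gender` into a
#' per-author attribute tibble. Empty cells become `NA` (attribute unknown);
#' a duplicated author keeps the last row, with a warning. Gender is coded
#' 0 = feminine, 1 = masculine.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `author` (character), `age` (double, years)
#'   and `gender` (integer 0/1), one row per author.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop("attribute file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "",
                           stringsAsFactors = FALSE)
  need <- c("author", "age", "gender")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("attribute table missing column(s): ",
                              paste(miss, collapse = ", "))
  gender_chr <- trimws(ifelse(is.na(tab$gender), "", tab$gender))
  bad <- !(gender_chr %in% c("", "0", "1"))
  if (any(bad)) {
    stop("invalid gender value(s): ", paste(unique(tab$gender[bad]), collapse = ", "),
         " (expected 0, 1 or empty)")
  }
  age <- suppressWarnings(as.numeric(tab$age))
  if (any(!is.na(age) & age <= 0)) stop("age must be positive when present")
  gender <- ifelse(gender_chr == "", NA_integer_, as.integer(gender_chr))
  dup <- duplicated(tab$author, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate author(s) in attribute table, keeping last row: ",
            paste(unique(tab$author[dup]), collapse = ", "))
  }
  keep <- !dup
  tibble::tibble(author = tab$author[keep], age = age[keep], gender = gender[keep])
}

#' Write a user-attribute table
#'
#' @param attributes Tibble with columns `author`, `age`, `gender`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(attributes, path) {
  out <- data.frame(
    author = attributes$author,
    age = ifelse(is.na(attributes$age), "", format(attributes$age, trim = TRUE, scientific = FALSE)),
    gender = ifelse(is.na(attributes$gender), "", as.character(attributes$gender)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
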