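# Tweet corpus container, readers/writers, filtering, deduplication and
# follower-reach accounting.

CORPUS_FIELDS <- c("id", "text", "timestamp", "username", "message_type",
                   "follower_count", "language")

#' Construct a tweet corpus
#'
#' A corpus is an ordered collection of short documents (tweets) for one
#' timepoint, with two summary fields used throughout infoveillance
#' reporting: `n_unique`, the number of messages flagged as original (not
#' retweets), and `reach`, the summed follower count over all messages. The
#' follower sum is the study's proxy for the audience a corpus was
#' disseminated to, which is why it can exceed the number of real users.
#'
#' @param tweets a data frame with columns `id`, `text`, `timestamp`,
#'   `username`, `message_type` (`"unique"` or `"retweet"`), `follower_count`,
#'   `language`, and optionally `location`.
#' @param label corpus label, e.g. `"WAD2014"`.
#' @return an object of class `tweet_corpus`.
#' @export
tweet_corpus <- function(tweets, label = "corpus") {
  tweets <- tibble::as_tibble(tweets)
  missing <- setdiff(CORPUS_FIELDS, names(tweets))
  if (length(missing) > 0) {
    stop("corpus is missing required field(s): ", paste(missing, collapse = ", "))
  }
  if (!"location" %in% names(tweets)) tweets$location <- NA_character_
  tweets$id <- as.character(tweets$id)
  tweets$text <- as.character(tweets$text)
  tweets$username <- as.character(tweets$username)
  tweets$language <- as.character(tweets$language)
  tweets$follower_count <- as.integer(tweets$follower_count)
  tweets$message_type <- as.character(tweets$message_type)
  if (nrow(tweets) > 0) {
    if (any(!nzchar(tweets$text))) stop("tweet text must be non-empty")
    if (any(is.na(tweets$follower_count) | tweets$follower_count < 0)) {
      stop("follower_count must be a nonnegative integer")
    }
    if (!all(tweets$message_type %in% c("unique", "retweet"))) {
      stop("message_type must be 'unique' or 'retweet'")
    }
    if (any(nchar(tweets$text) > 280)) {
      warning("corpus contains message(s) longer than 280 characters")
    }
  }
  structure(
    list(
      label = label,
      tweets = tweets,
      n_unique = sum(tweets$message_type == "unique"),
      reach = sum(as.numeric(tweets$follower_count))
    ),
    class = "tweet_corpus"
  )
}

#' @export
print.tweet_corpus <- function(x, ...) {
  cat(sprintf("<tweet_corpus '%s': %d messages, %d unique, reach %.0f>\n",
              x$label, nrow(x$tweets), x$n_unique, x$reach))
  invisible(x)
}

#' Number of messages in a corpus
#' @param x a `tweet_corpus`.
#' @export
corpus_size <- function(x) {
  stopifnot(inherits(x, "tweet_corpus"))
  nrow(x$tweets)
}

.parse_timestamp <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
  }
  out
}

.format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a tweet corpus from disk
#'
#' Two plain-text layouts are supported: `"delimited"` (header row,
#' comma-separated, RFC-4180 quoting) and `"records"` (one JSON object per
#' line, same field names). Records violating the tweet invariants (empty
#' text, negative follower count, unknown message type) are excluded and
#' counted in the `malformed` attribute of the result rather than silently
#' dropped; timestamps are parsed as ISO-8601, defaulting to UTC.
#'
#' @param path file path.
#' @param format `"delimited"` or `"records"`.
#' @param label corpus label; defaults to the file name.
#' @return a `tweet_corpus`; `attr(, "malformed")` holds the number of
#'   rejected records.
#' @export
read_corpus <- function(path, format = c("delimited", "records"),
                        label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]+$", "", basename(path))
  if (format == "delimited") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    nms <- unique(unlist(lapply(recs, names)))
    df <- as.data.frame(
      lapply(stats::setNames(nms, nms), function(f) {
        vapply(recs, function(r) {
          v <- r[[f]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      }),
      stringsAsFactors = FALSE
    )
  }
  missing <- setdiff(CORPUS_FIELDS, names(df))
  if (length(missing) > 0) {
    stop("corpus file is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"location" %in% names(df)) df$location <- NA_character_
  df$location[is.na(df$location) | !nzchar(df$location)] <- NA_character_
  fc <- suppressWarnings(as.integer(df$follower_count))
  ok <- !is.na(df$text) & nzchar(df$text) &
    !is.na(fc) & fc >= 0 &
    df$message_type %in% c("unique", "retweet")
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " malformed record(s) rejected while reading ", path)
  }
  df <- df[ok, , drop = FALSE]
  df$follower_count <- fc[ok]
  df$timestamp <- .parse_timestamp(df$timestamp)
  corpus <- tweet_corpus(df, label = label)
  attr(corpus, "malformed") <- n_bad
  corpus
}

#' Write a tweet corpus to disk
#'
#' Emits the same layouts [read_corpus()] accepts, so write/read round-trips
#' preserve every field.
#'
#' @param corpus a `tweet_corpus`.
#' @param path output file path.
#' @param format `"delimited"` or `"records"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("delimited", "records")) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  format <- match.arg(format)
  df <- as.data.frame(corpus$tweets)
  df$timestamp <- .format_timestamp(df$timestamp)
  df <- df[, c(CORPUS_FIELDS, "location")]
  if (format == "delimited") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]), auto_unbox = TRUE,
                       na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Keep only tweets in one language
#'
#' Language filtering mirrors the usual infoveillance restriction to a single
#' analysis language; matching is case-insensitive on the language tag and
#' message order is preserved.
#'
#' @param corpus a `tweet_corpus`.
#' @param keep language tag to retain, e.g. `"en"`.
#' @return a filtered `tweet_corpus`.
#' @export
filter_language <- function(corpus, keep = "en") {
  stopifnot(inherits(corpus, "tweet_corpus"))
  sel <- tolower(corpus$tweets$language) == tolower(keep)
  tweet_corpus(corpus$tweets[sel, , drop = FALSE], label = corpus$label)
}

# canonical text: leading "RT @user:" stripped, whitespace normalized,
# case-folded -- used to collapse retweets onto their source message
.canonical_text <- function(text) {
  x <- sub("^\\s*[Rr][Tt]\\s+@\\S+:?\\s*", "", text)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Collapse retweets onto unique tweets
#'
#' A message is kept as unique when its collector flag is `"unique"` or when
#' its canonical text (leading `"RT @user: "` prefix stripped, whitespace
#' normalized, case-folded) has not been seen before. Every other message is
#' collapsed onto the first kept message with the same canonical text, so the
#' message count is conserved: `sum(1 + retweet_counts)` equals the original
#' corpus size. Canonical-text matching is the default because collector
#' exports label retweets inconsistently; `by = "flag"` trusts the
#' `message_type` flag alone.
#'
#' @param corpus a `tweet_corpus`.
#' @param by `"canonical_text"` (default) or `"flag"`.
#' @return a list with `corpus` (the unique tweets, order preserved) and
#'   `retweet_counts` (messages collapsed onto each unique tweet).
#' @export
dedupe_unique <- function(corpus, by = c("canonical_text", "flag")) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  by <- match.arg(by)
  tw <- corpus$tweets
  n <- nrow(tw)
  if (n == 0) {
    return(list(corpus = corpus, retweet_counts = integer(0)))
  }
  if (by == "flag") {
    keep <- tw$message_type == "unique"
    canon <- .canonical_text(tw$text)
    group_first <- match(canon, canon[keep])
  } else {
    canon <- .canonical_text(tw$text)
    first_seen <- !duplicated(canon)
    keep <- tw$message_type == "unique" | first_seen
    group_first <- match(canon, canon[keep])
  }
  if (any(is.na(group_first) & !keep)) {
    # flag-based dedupe can meet retweets with no flagged-unique source;
    # promote their first occurrence so the accounting stays conserved
    orphan <- is.na(group_first)
    keep <- keep | (orphan & !duplicated(canon))
    group_first <- match(canon, canon[keep])
  }
  kept_idx <- which(keep)
  counts <- integer(length(kept_idx))
  collapsed <- which(!keep)
  if (length(collapsed) > 0) {
    tab <- table(group_first[collapsed])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(
    corpus = tweet_corpus(tw[kept_idx, , drop = FALSE], label = corpus$label),
    retweet_counts = counts
  )
}

#' Total follower reach of a corpus
#'
#' Sums `follower_count` over all messages (unique and retweets). This is the
#' corpus dissemination proxy: each message is weighted by the posting
#' account's audience, so the total routinely exceeds the number of distinct
#' users.
#'
#' @param corpus a `tweet_corpus`.
#' @return a nonnegative number.
#' @export
aggregate_reach <- function(corpus) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  sum(as.numeric(corpus$tweets$follower_count))
}

#' Rank accounts by total disseminated reach
#'
#' @param corpus a `tweet_corpus`.
#' @param k number of accounts to return.
#' @return a tibble with `username` and `reach`, ranked by summed follower
#'   count descending; ties broken lexicographically by username.
#' @export
top_disseminators <- function(corpus, k) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a positive integer")
  }
  sums <- tapply(as.numeric(corpus$tweets$follower_count),
                 corpus$tweets$username, sum)
  if (is.null(sums) || length(sums) == 0) {
    return(tibble::tibble(username = character(0), reach = numeric(0)))
  }
  ord <- order(-as.numeric(sums), names(sums))
  out <- tibble::tibble(username = names(sums)[ord],
                        reach = as.numeric(sums)[ord])
  utils::head(out, min(as.integer(k), nrow(out)))
}
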