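# Corpus -> nonnegative term-document matrix: cleaning, tokenization,
# N-gram extraction, stopword removal, Porter stemming, tf / tf-idf
# weighting and column normalization.

# standard English stopword list (snowball-style) plus Twitter artifacts
.BASE_STOPWORDS <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why", "how",
  "all", "any", "both", "each", "few", "more", "most", "other", "some",
  "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
  "very", "s", "t", "can", "will", "just", "don", "should", "now"
)

#' Default English stopword set
#'
#' A standard English stopword list extended with the Twitter-specific
#' artifacts `rt`, `amp`, `http` and `https`.
#'
#' @return character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c(.BASE_STOPWORDS, "rt", "amp", "http", "https")
}

#' Text preparation options
#'
#' Bundles every tunable of the corpus-to-matrix pipeline. Defaults follow
#' common practice for NMF document clustering of short texts: unigrams plus
#' bigrams, tf-idf weighting with unit-Euclidean-norm document columns, and
#' pruning of terms seen in fewer than 3 documents.
#'
#' @param ngram_min,ngram_max inclusive range of N-gram lengths.
#' @param stopwords set of lowercase stopwords removed before stemming.
#' @param min_term_docfreq minimum document frequency for a term to be kept.
#' @param keep_hashtags keep hashtag tokens (without `#`) or drop them.
#' @param weighting `"tfidf"` (default) or raw `"tf"` counts.
#' @param normalize_docs scale each document column to unit Euclidean norm.
#' @return a `prep_options` list.
#' @export
prep_options <- function(ngram_min = 1L, ngram_max = 2L,
                         stopwords = default_stopwords(),
                         min_term_docfreq = 3L, keep_hashtags = TRUE,
                         weighting = c("tfidf", "tf"),
                         normalize_docs = TRUE) {
  weighting <- match.arg(weighting)
  ngram_min <- as.integer(ngram_min)
  ngram_max <- as.integer(ngram_max)
  if (ngram_min < 1L || ngram_max < ngram_min) {
    stop("require 1 <= ngram_min <= ngram_max")
  }
  if (min_term_docfreq < 1L) stop("min_term_docfreq must be >= 1")
  structure(
    list(ngram_min = ngram_min, ngram_max = ngram_max,
         stopwords = tolower(stopwords),
         min_term_docfreq = as.integer(min_term_docfreq),
         keep_hashtags = isTRUE(keep_hashtags), weighting = weighting,
         normalize_docs = isTRUE(normalize_docs)),
    class = "prep_options"
  )
}

#' Clean and tokenize one tweet
#'
#' Case-folds and splits a message into word tokens: URLs, `@`-mentions and
#' a leading `RT` marker are removed; hashtags are retained without the `#`
#' when `keep_hashtags` is `TRUE`, otherwise dropped entirely; remaining
#' punctuation is stripped; standalone numerals are retained.
#'
#' @param text character vector of raw messages.
#' @param keep_hashtags keep hashtag tokens (without `#`)?
#' @return for a single input string, a character vector of tokens; for a
#'   vector input, a list of token vectors.
#' @examples
#' clean_and_tokenize("RT @UNAIDS: End #AIDS by 2030! http://t.co/x")
#' @export
clean_and_tokenize <- function(text, keep_hashtags = TRUE) {
  one <- function(x) {
    x <- tolower(x)
    x <- gsub("https?://\\S+|www\\.\\S+", " ", x)
    x <- gsub("@\\w+", " ", x)
    x <- sub("^\\s*rt\\b", " ", x)
    if (keep_hashtags) {
      x <- gsub("#(\\w+)", " \\1", x)
    } else {
      x <- gsub("#\\w+", " ", x)
    }
    x <- gsub("[^a-z0-9]+", " ", x)
    toks <- strsplit(trimws(x), "\\s+")[[1]]
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Extract contiguous N-grams from a token sequence
#'
#' Emits every contiguous n-gram for each n in `[ngram_min, ngram_max]`
#' (with multiplicity), ordered by n and then position, words joined by a
#' single space.
#'
#' @param tokens character vector of tokens.
#' @param ngram_min,ngram_max inclusive n-gram length range.
#' @return character vector of n-gram terms.
#' @examples
#' extract_ngrams(c("world", "aids", "day"), 1, 2)
#' @export
extract_ngrams <- function(tokens, ngram_min = 1L, ngram_max = 2L) {
  if (ngram_min > ngram_max) stop("require ngram_min <= ngram_max")
  nt <- length(tokens)
  out <- character(0)
  for (n in seq(ngram_min, ngram_max)) {
    if (nt < n) next
    starts <- seq_len(nt - n + 1L)
    grams <- vapply(starts, function(s) {
      paste(tokens[s:(s + n - 1L)], collapse = " ")
    }, character(1))
    out <- c(out, grams)
  }
  out
}

# per-document term multisets: tokenize -> drop stopwords -> stem -> n-grams
.prep_doc_terms <- function(texts, options) {
  lapply(texts, function(txt) {
    toks <- clean_and_tokenize(txt, keep_hashtags = options$keep_hashtags)
    toks <- toks[!(toks %in% options$stopwords)]
    if (length(toks) == 0) return(character(0))
    stems <- porter_stem(toks)
    extract_ngrams(stems, options$ngram_min, options$ngram_max)
  })
}

#' Prepared term sets per document
#'
#' Runs the full text pipeline and returns, for each message, the set of
#' distinct prepared terms it contains. This is the tweet-level containment
#' view used by topic frequency counting.
#'
#' @param corpus a `tweet_corpus`.
#' @param options a [prep_options()] list.
#' @return list of character vectors, one per message.
#' @export
doc_terms <- function(corpus, options = prep_options()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  lapply(.prep_doc_terms(corpus$tweets$text, options), unique)
}

#' Build the term-document matrix of a corpus
#'
#' Per document the pipeline is: [clean_and_tokenize()], stopword removal,
#' [porter_stem()] per token, [extract_ngrams()] over the stemmed tokens,
#' then occurrence counting. Stemming precedes n-gram joining so inflected
#' variants of a phrase collapse to one row. Terms below `min_term_docfreq`
#' are pruned; with tf-idf weighting each count becomes
#' `c * log(n / docfreq)` (terms present in every document therefore vanish
#' and are pruned); with `normalize_docs` each column is scaled to unit
#' Euclidean norm. Documents whose column becomes all-zero are dropped and
#' reported in the `dropped_docs` attribute.
#'
#' @param corpus a `tweet_corpus`.
#' @param options a [prep_options()] list.
#' @return a `term_doc_matrix`: list with `values` (sparse `dgCMatrix`,
#'   terms x documents), `terms`, `doc_ids`, `docfreq` and `weighting`.
#' @export
build_matrix <- function(corpus, options = prep_options()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  if (nrow(corpus$tweets) == 0) stop("corpus is empty")
  term_lists <- .prep_doc_terms(corpus$tweets$text, options)
  doc_ids <- corpus$tweets$id

  all_terms <- unlist(term_lists, use.names = FALSE)
  if (length(all_terms) == 0) {
    stop("all documents are empty after text preparation")
  }
  terms <- unique(all_terms)  # first-occurrence order: deterministic
  i <- match(all_terms, terms)
  j <- rep(seq_along(term_lists), lengths(term_lists))
  values <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(terms), length(term_lists)))

  docfreq <- Matrix::rowSums(values > 0)
  keep <- docfreq >= options$min_term_docfreq
  if (!any(keep)) stop("no term meets min_term_docfreq")
  values <- values[keep, , drop = FALSE]
  terms <- terms[keep]
  docfreq <- docfreq[keep]

  if (options$weighting == "tfidf") {
    n <- ncol(values)
    idf <- log(n / docfreq)
    values <- Matrix::Diagonal(x = idf) %*% values
    nz <- idf > 0
    values <- values[nz, , drop = FALSE]
    terms <- terms[nz]
    docfreq <- docfreq[nz]
    if (length(terms) == 0) stop("no term survives tf-idf weighting")
  }

  col_norms <- sqrt(Matrix::colSums(values^2))
  nonzero_docs <- col_norms > 0
  dropped <- doc_ids[!nonzero_docs]
  if (length(dropped) > 0) {
    message(length(dropped), " document(s) empty after preparation, dropped")
  }
  values <- values[, nonzero_docs, drop = FALSE]
  doc_ids <- doc_ids[nonzero_docs]
  if (ncol(values) == 0) stop("all documents are empty after text preparation")
  if (options$normalize_docs) {
    values <- values %*% Matrix::Diagonal(x = 1 / col_norms[nonzero_docs])
  }

  # drop rows zeroed by document pruning so the no-all-zero-row invariant holds
  row_nz <- Matrix::rowSums(values != 0) > 0
  values <- values[row_nz, , drop = FALSE]
  terms <- terms[row_nz]
  docfreq <- docfreq[row_nz]

  structure(
    list(values = methods::as(methods::as(values, "generalMatrix"), "CsparseMatrix"),
         terms = terms, doc_ids = doc_ids, docfreq = as.integer(docfreq),
         weighting = options$weighting),
    class = "term_doc_matrix",
    dropped_docs = dropped
  )
}

#' @export
print.term_doc_matrix <- function(x, ...) {
  cat(sprintf("<term_doc_matrix: %d terms x %d documents, %s weighting>\n",
              length(x$terms), length(x$doc_ids), x$weighting))
  invisible(x)
}

#' Write a term-document matrix as MatrixMarket plus sidecars
#'
#' Writes `<stem>.mtx` (MatrixMarket coordinate format), `<stem>.terms.txt`
#' and `<stem>.docs.txt` (one entry per line, UTF-8).
#'
#' @param tdm a `term_doc_matrix`.
#' @param stem output path stem (without extension).
#' @return the `.mtx` path, invisibly.
#' @export
write_matrix <- function(tdm, stem) {
  stopifnot(inherits(tdm, "term_doc_matrix"))
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(tdm$values, mtx)
  writeLines(tdm$terms, paste0(stem, ".terms.txt"), useBytes = TRUE)
  writeLines(tdm$doc_ids, paste0(stem, ".docs.txt"), useBytes = TRUE)
  invisible(mtx)
}

#' Read a term-document matrix written by [write_matrix()]
#'
#' @param stem path stem used when writing.
#' @param weighting weighting tag to record on the result.
#' @return a `term_doc_matrix`.
#' @export
read_matrix <- function(stem, weighting = "tfidf") {
  values <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  terms <- readLines(paste0(stem, ".terms.txt"), encoding = "UTF-8")
  doc_ids <- readLines(paste0(stem, ".docs.txt"), encoding = "UTF-8")
  stopifnot(nrow(values) == length(terms), ncol(values) == length(doc_ids))
  structure(
    list(values = methods::as(methods::as(values, "generalMatrix"), "CsparseMatrix"),
         terms = terms, doc_ids = doc_ids,
         docfreq = as.integer(Matrix::rowSums(values != 0)),
         weighting = weighting),
    class = "term_doc_matrix"
  )
}
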