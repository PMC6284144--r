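# Synthetic tweet-corpus generator with a planted hierarchical topic
# structure, plus recovery scoring (adjusted Rand index, purity) against the
# planted labels. The generator is what makes every downstream stage
# testable without access to real Twitter exports.

# balanced binary tree over n_topics leaves; returns list of internal node
# ids with their descendant leaf sets (used to share "node words" between
# sibling subtrees, giving leaves a hierarchical similarity structure)
.topic_tree_plan <- function(n_topics) {
  nodes <- list()
  nid <- 0L
  split <- function(leaves, depth) {
    if (length(leaves) < 2) return(invisible(NULL))
    nid <<- nid + 1L
    nodes[[length(nodes) + 1L]] <<- list(id = nid, leaves = leaves,
                                         depth = depth)
    half <- ceiling(length(leaves) / 2)
    split(leaves[seq_len(half)], depth + 1L)
    split(leaves[-seq_len(half)], depth + 1L)
  }
  split(seq_len(n_topics), 1L)
  nodes
}

# a handful of realistic hashtag-style terms appended to the shared
# vocabulary so end-to-end demos read like the target domain
.DEMO_TAGS <- c("worldaidsday", "hiv", "aids", "endaids", "gettested",
                "knowyourstatus", "redribbon", "hivprevention")

#' Specification of a synthetic tweet corpus
#'
#' Defines the generating process: a balanced binary tree over `n_topics`
#' leaf topics; per leaf a categorical word distribution built from anchor
#' words (terms with zero probability under every other leaf), words shared
#' along the topic tree's internal nodes, and a Zipfian background
#' vocabulary; documents drawn as token mixtures
#' `(1 - background_mix) * topic + background_mix * background`; retweet
#' duplication with `"RT @user: "` prefixes; heavy-tailed (discretized
#' log-normal) follower counts; and timestamps within a single-day window.
#'
#' @param n_topics number of planted leaf topics.
#' @param n_docs number of unique documents.
#' @param background_mix fraction of tokens drawn from the shared background
#'   vocabulary.
#' @param retweet_rate retweet duplicates generated per unique document
#'   (`round(retweet_rate * n_docs)` retweets are added).
#' @param anchors_per_topic anchor words per leaf topic.
#' @param anchor_mass total probability a leaf gives its own anchors.
#' @param node_mass total probability a leaf gives words shared with its
#'   sibling subtree (the non-root ancestor "node words"). The default is 0:
#'   sibling-shared high-weight vocabulary suppresses the mNDCG split score
#'   of exactly the splits that separate siblings, so it is an optional
#'   stress condition rather than part of the standard generating process.
#' @param n_background size of the shared Zipfian vocabulary.
#' @param zipf_s Zipf exponent of the background distribution.
#' @param doc_length_lambda Poisson mean of the token count per document;
#'   lengths are clipped to `[3, 50]`.
#' @param follower_meanlog,follower_sdlog log-normal parameters of the
#'   follower-count distribution (discretized, so aggregate reach is
#'   heavy-tailed as in real dissemination data).
#' @param timestamp_start,timestamp_end the single-day collection window.
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @param label corpus label.
#' @return a `synthetic_spec` list, validated; the per-topic word
#'   distributions are in `$topic_word_dists` (vocabulary x topics), the
#'   background distribution in `$background_dist`, the anchors in
#'   `$anchor_words`.
#' @export
synthetic_spec <- function(n_topics = 4L, n_docs = 1000L,
                           background_mix = 0.2, retweet_rate = 0.3,
                           anchors_per_topic = 3L, anchor_mass = 0.45,
                           node_mass = 0, n_background = 200L,
                           zipf_s = 1.07, doc_length_lambda = 12,
                           follower_meanlog = 4, follower_sdlog = 2,
                           timestamp_start = as.POSIXct("2014-12-01 00:00:00",
                                                        tz = "UTC"),
                           timestamp_end = as.POSIXct("2014-12-01 23:59:59",
                                                      tz = "UTC"),
                           seed = 1L, label = "synthetic") {
  if (n_topics < 1 || n_docs < 1) stop("n_topics and n_docs must be positive")
  if (background_mix < 0 || background_mix > 1) {
    stop("invalid field background_mix: must lie in [0, 1]")
  }
  if (retweet_rate < 0 || retweet_rate > 1) {
    stop("invalid field retweet_rate: must lie in [0, 1]")
  }
  if (anchor_mass + node_mass >= 1) {
    stop("invalid fields anchor_mass/node_mass: must leave background mass")
  }

  anchors <- lapply(seq_len(n_topics), function(k) {
    sprintf("topic%da%d", k, seq_len(anchors_per_topic))
  })
  plan <- .topic_tree_plan(n_topics)
  inner <- Filter(function(nd) nd$id > 1L, plan)  # non-root internal nodes
  node_words <- lapply(inner, function(nd) {
    sprintf("node%dw%d", nd$id, 1:2)
  })
  bg_words <- c(.DEMO_TAGS,
                sprintf("w%04d", seq_len(max(0L, n_background -
                                               length(.DEMO_TAGS)))))
  bg_p <- (seq_along(bg_words))^(-zipf_s)
  bg_p <- bg_p / sum(bg_p)

  vocab <- c(unlist(anchors), unlist(node_words), bg_words)
  V <- length(vocab)
  dists <- matrix(0, V, n_topics, dimnames = list(vocab, NULL))
  for (k in seq_len(n_topics)) {
    dists[anchors[[k]], k] <- anchor_mass / anchors_per_topic
    anc <- which(vapply(inner, function(nd) k %in% nd$leaves, logical(1)))
    if (length(anc) > 0) {
      w <- unlist(node_words[anc])
      dists[w, k] <- node_mass / length(w)
    } else {
      # topics with no non-root ancestor put the node mass into background
      dists[bg_words, k] <- dists[bg_words, k] + node_mass * bg_p
    }
    dists[bg_words, k] <- dists[bg_words, k] +
      (1 - anchor_mass - node_mass) * bg_p
  }
  background <- stats::setNames(numeric(V), vocab)
  background[bg_words] <- bg_p

  spec <- structure(
    list(n_topics = as.integer(n_topics), n_docs = as.integer(n_docs),
         background_mix = background_mix, retweet_rate = retweet_rate,
         anchor_words = anchors, topic_word_dists = dists,
         background_dist = background, vocab = vocab,
         doc_length_lambda = doc_length_lambda,
         follower_meanlog = follower_meanlog,
         follower_sdlog = follower_sdlog,
         timestamp_start = timestamp_start, timestamp_end = timestamp_end,
         seed = as.integer(seed), label = label),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

#' Validate a synthetic corpus specification
#'
#' Checks the generator invariants: every per-topic distribution sums to 1
#' (tolerance 1e-9), each anchor word has at least 10x the probability under
#' its own topic than under any other, and the mixture fractions lie in
#' `[0, 1]`. Errors name the failing field.
#'
#' @param spec a `synthetic_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sums <- colSums(spec$topic_word_dists)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("invalid field topic_word_dists: distributions must sum to 1")
  }
  if (abs(sum(spec$background_dist) - 1) > 1e-9) {
    stop("invalid field background_dist: must sum to 1")
  }
  for (k in seq_len(spec$n_topics)) {
    own <- spec$topic_word_dists[spec$anchor_words[[k]], k]
    other <- spec$topic_word_dists[spec$anchor_words[[k]],
                                   -k, drop = FALSE]
    if (any(apply(other, 1, max) * 10 > own)) {
      stop("invalid field anchor_words: anchors must have >= 10x probability",
           " under their own topic")
    }
  }
  if (spec$background_mix < 0 || spec$background_mix > 1) {
    stop("invalid field background_mix: must lie in [0, 1]")
  }
  if (spec$retweet_rate < 0 || spec$retweet_rate > 1) {
    stop("invalid field retweet_rate: must lie in [0, 1]")
  }
  invisible(spec)
}

#' Sample a synthetic tweet corpus with planted topic labels
#'
#' Draws `n_docs` unique documents (each token from the mixture
#' `(1 - background_mix) * topic + background_mix * background`, topic drawn
#' uniformly over leaves), then adds `round(retweet_rate * n_docs)` retweet
#' duplicates of randomly chosen unique documents, verbatim with an
#' `"RT @<username>: "` prefix. Follower counts, usernames and in-window
#' timestamps are attached per message. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a validated [synthetic_spec()].
#' @return list with `corpus` (a `tweet_corpus`, uniques first then
#'   retweets) and `labels` (integer leaf-topic id per message; retweets
#'   inherit their source's label).
#' @export
sample_corpus <- function(spec) {
  validate_synthetic_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_docs
  topics <- sample.int(spec$n_topics, n, replace = TRUE)
  # support [3, 24] tokens keeps texts inside the 280-character limit
  lens <- pmin(pmax(stats::rpois(n, spec$doc_length_lambda), 3L), 24L)
  n_users <- max(50L, ceiling(n / 10))
  users <- sprintf("user%04d", sample.int(n_users, n, replace = TRUE))

  texts <- character(n)
  for (d in seq_len(n)) {
    L <- lens[d]
    from_bg <- stats::runif(L) < spec$background_mix
    toks <- character(L)
    if (any(from_bg)) {
      toks[from_bg] <- sample(spec$vocab, sum(from_bg), replace = TRUE,
                              prob = spec$background_dist)
    }
    if (any(!from_bg)) {
      toks[!from_bg] <- sample(spec$vocab, sum(!from_bg), replace = TRUE,
                               prob = spec$topic_word_dists[, topics[d]])
    }
    texts[d] <- paste(toks, collapse = " ")
  }

  n_rt <- round(spec$retweet_rate * n)
  src <- if (n_rt > 0) sample.int(n, n_rt, replace = TRUE) else integer(0)
  rt_texts <- if (n_rt > 0) {
    paste0("RT @", users[src], ": ", texts[src])
  } else character(0)
  rt_users <- sprintf("user%04d", sample.int(n_users, n_rt, replace = TRUE))

  total <- n + n_rt
  followers <- as.integer(pmin(
    round(stats::rlnorm(total, spec$follower_meanlog, spec$follower_sdlog)),
    .Machine$integer.max / 2
  ))
  span <- as.numeric(difftime(spec$timestamp_end, spec$timestamp_start,
                              units = "secs"))
  stamps <- spec$timestamp_start + sort(stats::runif(total, 0, span))

  tweets <- tibble::tibble(
    id = sprintf("t%06d", seq_len(total)),
    text = c(texts, rt_texts),
    timestamp = stamps,
    username = c(users, rt_users),
    message_type = c(rep("unique", n), rep("retweet", n_rt)),
    follower_count = followers,
    language = "en",
    location = NA_character_
  )
  list(
    corpus = tweet_corpus(tweets, label = spec$label),
    labels = c(topics, topics[src])
  )
}

#' Write planted labels as a two-column delimited file
#'
#' @param corpus the `tweet_corpus` the labels belong to.
#' @param labels integer topic id per message.
#' @param path output path (tab-separated, columns `id` and `topic`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(corpus, labels, path) {
  stopifnot(inherits(corpus, "tweet_corpus"),
            length(labels) == nrow(corpus$tweets))
  utils::write.table(
    data.frame(id = corpus$tweets$id, topic = labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Score recovery of a planted partition
#'
#' Compares predicted cluster labels with planted topic labels via the
#' adjusted Rand index (1 iff the partitions agree up to relabeling, 0 in
#' expectation under random agreement) and cluster purity (fraction of
#' documents in their cluster's majority topic). Both are invariant to
#' permutation of cluster labels.
#'
#' @param predicted_labels,planted_labels equal-length label vectors
#'   (length >= 2).
#' @return list with `ari` and `purity`.
#' @export
evaluate_recovery <- function(predicted_labels, planted_labels) {
  if (length(predicted_labels) != length(planted_labels)) {
    stop("label sequences must have the same length")
  }
  if (length(predicted_labels) < 2) stop("need at least 2 documents")
  tab <- table(predicted_labels, planted_labels)
  list(
    ari = mclust::adjustedRandIndex(predicted_labels, planted_labels),
    purity = sum(apply(tab, 1, max)) / length(predicted_labels)
  )
}
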