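# Fixtures are built in code so every test is self-contained.

# minimal tweet table; recycles its arguments
make_tweets <- function(text,
                        message_type = "unique",
                        follower_count = 10L,
                        username = "usera",
                        language = "en",
                        timestamp = as.POSIXct("2014-12-01 12:00:00",
                                               tz = "UTC")) {
  n <- length(text)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    text = text,
    timestamp = rep_len(timestamp, n),
    username = rep_len(username, n),
    message_type = rep_len(message_type, n),
    follower_count = rep_len(as.integer(follower_count), n),
    language = rep_len(language, n)
  )
}

make_corpus <- function(text, ..., label = "fixture") {
  tweet_corpus(make_tweets(text, ...), label = label)
}

# 12-tweet two-topic fixture with hand-countable term frequencies
fixture12 <- function() {
  make_corpus(c(
    "stigma ends with facts",            # stigma 1, fact 1, end 1
    "fight stigma today",                # stigma 2, fight 1
    "stigma free world",                 # stigma 3
    "end stigma now",                    # stigma 4, end 2
    "facts fight fear",                  # fact 2, fight 2
    "fight for a cure",                  # fight 3
    "the cure is close",                 # cure 2
    "cure research matters",             # cure 3
    "love and support",                  # support 1
    "support the fight",                 # support 2, fight 4
    "today we remember",                 #
    "facts about treatment"              # fact 3
  ))
}

# independent brute-force oracle for rank-2 NNLS: explicit candidate
# active sets plus a refined grid search over the nonnegative quadrant
nnls2_oracle <- function(W, a) {
  resid <- function(h) sum((W %*% h - a)^2)
  G <- crossprod(W)
  b <- crossprod(W, a)
  cands <- list(c(0, 0))
  if (G[1, 1] > 0) cands <- c(cands, list(c(max(0, b[1] / G[1, 1]), 0)))
  if (G[2, 2] > 0) cands <- c(cands, list(c(0, max(0, b[2] / G[2, 2]))))
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (det > 1e-12) {
    u <- c(G[2, 2] * b[1] - G[1, 2] * b[2],
           G[1, 1] * b[2] - G[1, 2] * b[1]) / det
    if (all(u >= 0)) cands <- c(cands, list(u))
  }
  best <- cands[[which.min(vapply(cands, resid, numeric(1)))]]
  # grid refinement around the best candidate
  lo <- pmax(best - 1, 0); hi <- best + 1
  for (round in 1:4) {
    g1 <- seq(lo[1], hi[1], length.out = 25)
    g2 <- seq(lo[2], hi[2], length.out = 25)
    grid <- as.matrix(expand.grid(g1, g2))
    r <- colSums((W %*% t(grid) - as.numeric(a))^2)
    best_g <- grid[which.min(r), ]
    if (resid(best_g) < resid(best)) best <- best_g
    step <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- pmax(best - step, 0); hi <- best + step
  }
  best
}

demo_spec <- function(...) {
  synthetic_spec(n_topics = 4, n_docs = 300, seed = 11, ...)
}
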