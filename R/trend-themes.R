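# Two-timepoint topic frequency trends and keyword-codebook mapping of
# topic-tree nodes to themes, UNAIDS core action principles and commitment
# areas (Prevention / Treatment or Care / Support).

CORE_ACTIONS <- c(
  "Decrease Vulnerability of Acquiring HIV/AIDS", "Access to Services",
  "Expand Programs", "Safeguard Human Rights", "Partnerships and Alliances",
  "Eliminate Stigma and Discrimination"
)
COMMITMENTS <- c("Prevention", "Treatment or Care", "Support")

#' Tweet-level frequency of a topic term
#'
#' Frequency is defined at the tweet level: the number of messages whose
#' prepared term set contains the term, not the number of token
#' occurrences, so a message repeating a term still counts once.
#'
#' @param corpus a `tweet_corpus`.
#' @param term a stemmed N-gram term (as produced by the prep pipeline).
#' @param prep a [prep_options()] list.
#' @return nonnegative integer count.
#' @export
topic_frequency <- function(corpus, term, prep = prep_options()) {
  sets <- doc_terms(corpus, prep)
  sum(vapply(sets, function(s) term %in% s, logical(1)))
}

#' Aggregated topic frequency table
#'
#' Tweet-level frequencies for every prepared term, keeping terms tweeted at
#' least `min_count` times (default 35, the aggregation threshold used for
#' single-day corpora of this kind), sorted descending with lexicographic
#' tie-break.
#'
#' @param corpus a `tweet_corpus`.
#' @param prep a [prep_options()] list.
#' @param min_count minimum tweet-level frequency to report.
#' @return tibble with `term` and `frequency`.
#' @export
frequency_table <- function(corpus, prep = prep_options(), min_count = 35L) {
  if (min_count < 1) stop("min_count must be >= 1")
  sets <- doc_terms(corpus, prep)
  counts <- table(unlist(sets, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) {
    return(tibble::tibble(term = character(0), frequency = integer(0)))
  }
  ord <- order(-as.integer(counts), names(counts))
  tibble::tibble(term = names(counts)[ord],
                 frequency = as.integer(counts)[ord])
}

#' Compare topic frequencies between two timepoints
#'
#' Joins two frequency tables and classifies each term's trend. Rates are
#' expressed per 10,000 unique tweets so corpora of different sizes are
#' comparable. In `"normalized"` mode (the default for cross-year
#' comparison) a term increases when `rate_b > rate_a * (1 + stable_band)`,
#' decreases when `rate_b < rate_a * (1 - stable_band)`, and is stable
#' otherwise; `"raw"` mode applies the same band to the raw counts. A term
#' present only in the later table is `"new"`, only in the earlier one
#' `"absent"`.
#'
#' @param table_a,table_b frequency tables from [frequency_table()] for the
#'   earlier and later timepoint.
#' @param n_unique_a,n_unique_b unique-tweet counts of the two corpora.
#' @param mode `"normalized"` or `"raw"`.
#' @param stable_band half-width of the relative no-change band.
#' @return tibble of trend records: `term`, `freq_a`, `freq_b`, `rate_a`,
#'   `rate_b`, `direction`.
#' @export
compare_periods <- function(table_a, table_b, n_unique_a, n_unique_b,
                            mode = c("normalized", "raw"),
                            stable_band = 0.25) {
  mode <- match.arg(mode)
  if (stable_band < 0) stop("stable_band must be >= 0")
  if (n_unique_a <= 0 || n_unique_b <= 0) {
    stop("unique-tweet counts must be positive")
  }
  terms <- union(table_a$term, table_b$term)
  fa <- table_a$frequency[match(terms, table_a$term)]
  fb <- table_b$frequency[match(terms, table_b$term)]
  in_a <- !is.na(fa)
  in_b <- !is.na(fb)
  fa[!in_a] <- 0L
  fb[!in_b] <- 0L
  ra <- fa / n_unique_a * 1e4
  rb <- fb / n_unique_b * 1e4
  xa <- if (mode == "normalized") ra else as.numeric(fa)
  xb <- if (mode == "normalized") rb else as.numeric(fb)
  direction <- ifelse(!in_a, "new",
               ifelse(!in_b, "absent",
               ifelse(xb > xa * (1 + stable_band), "increase",
               ifelse(xb < xa * (1 - stable_band), "decrease", "stable"))))
  out <- tibble::tibble(term = terms, freq_a = fa, freq_b = fb,
                        rate_a = ra, rate_b = rb, direction = direction)
  out[order(-(out$freq_a + out$freq_b), out$term), ]
}

# each keyword goes through the same pipeline as corpus text (tokenize,
# drop stopwords, stem) and multiword keywords are joined into one n-gram
# so they match the bigram terms the prep pipeline emits
.stem_keywords <- function(words, stopwords = default_stopwords()) {
  out <- vapply(words, function(w) {
    toks <- clean_and_tokenize(w)
    toks <- toks[!(toks %in% stopwords)]
    if (length(toks) == 0) NA_character_ else
      paste(porter_stem(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  unique(out[!is.na(out)])
}

#' Construct a theme codebook
#'
#' @param entries a data frame with columns `theme`, `keywords` (list column
#'   of character vectors, or `;`-separated strings), `core_action` (one of
#'   the six UNAIDS core action principles) and `commitment` (`"Prevention"`,
#'   `"Treatment or Care"` or `"Support"`). Keywords are cleaned and
#'   Porter-stemmed on construction so they match prepared terms.
#' @return a `codebook` tibble with a `keywords` list column of stems.
#' @export
codebook <- function(entries) {
  entries <- tibble::as_tibble(entries)
  req <- c("theme", "keywords", "core_action", "commitment")
  missing <- setdiff(req, names(entries))
  if (length(missing) > 0) {
    stop("codebook is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(entries$theme)) stop("theme names must be unique")
  if (!all(entries$core_action %in% CORE_ACTIONS)) {
    stop("unknown core_action; must be one of: ",
         paste(CORE_ACTIONS, collapse = "; "))
  }
  if (!all(entries$commitment %in% COMMITMENTS)) {
    stop("unknown commitment; must be one of: ",
         paste(COMMITMENTS, collapse = "; "))
  }
  kw <- entries$keywords
  if (!is.list(kw)) kw <- strsplit(as.character(kw), ";\\s*")
  entries$keywords_raw <- lapply(kw, as.character)
  entries$keywords <- lapply(kw, .stem_keywords)
  class(entries) <- c("codebook", class(entries))
  entries
}

#' Packaged default theme codebook
#'
#' Encodes the 19 World AIDS Day tweet themes with their published example
#' keywords, each mapped to a UNAIDS core action principle and a 2030-goal
#' commitment area. The keyword sets cover only the published example words
#' per theme; the original assignments were expert judgments, so users
#' analysing their own corpora should extend this codebook.
#'
#' @return a `codebook`.
#' @export
default_codebook <- function() {
  e <- function(theme, core_action, commitment, kw) {
    list(theme = theme, core_action = core_action, commitment = commitment,
         keywords = list(kw))
  }
  rows <- list(
    e("Informational Resources from Governmental Organizations",
      "Decrease Vulnerability of Acquiring HIV/AIDS", "Prevention",
      c("infographics", "aids gov", "white house")),
    e("Halt Infections",
      "Decrease Vulnerability of Acquiring HIV/AIDS", "Prevention",
      c("accessible", "affordable", "vaccine", "partnerships", "epidemic",
        "averted")),
    e("AIDS-Free Generation",
      "Decrease Vulnerability of Acquiring HIV/AIDS", "Prevention",
      c("close the gap", "aids free gen", "children", "generation")),
    e("Prevent HIV/AIDS",
      "Decrease Vulnerability of Acquiring HIV/AIDS", "Prevention",
      c("aids prevention", "hiv facts", "prevention")),
    e("Treatment for HIV/AIDS", "Access to Services", "Treatment or Care",
      c("access", "children", "pregnant", "women", "services",
        "closing the gap", "treat", "people")),
    e("Save Lives: Infected and At Risk", "Access to Services",
      "Treatment or Care", c("cure", "treatment for all", "save lives")),
    e("Impact of the HIV/AIDS Pandemic", "Access to Services",
      "Treatment or Care",
      c("millions", "lives", "avert", "infections", "world")),
    e("Efforts for Targeted HIV/AIDS Eradication", "Expand Programs",
      "Treatment or Care",
      c("facts", "wipe", "homophobia", "join", "eradication")),
    e("Fast Track the End of the Pandemic", "Expand Programs",
      "Treatment or Care",
      c("end", "epidemic", "unaids", "fast track", "response", "assessing")),
    e("Spread HIV/AIDS Awareness", "Safeguard Human Rights", "Support",
      c("sending", "amfar", "awareness", "spread", "end aids")),
    e("Recognition of the Pandemic", "Safeguard Human Rights", "Support",
      c("unaware", "united states", "aware", "disease")),
    e("Honor People Living with HIV/AIDS (PLWH)", "Safeguard Human Rights",
      "Support",
      c("honor", "memory", "continuing", "lost", "affected", "positive",
        "statement")),
    e("Expression of HIV/AIDS Solidarity and Consciousness",
      "Safeguard Human Rights", "Support",
      c("wear", "ribbon", "tee shirt", "solidarity")),
    e("Combat HIV/AIDS", "Safeguard Human Rights", "Support",
      c("fight", "today", "support", "cure", "love", "helping")),
    e("Support PLWH", "Safeguard Human Rights", "Support",
      c("sending", "support", "living", "people")),
    e("Commitment to End the Pandemic", "Partnerships and Alliances",
      "Support", c("renew", "vow", "longer", "statements", "make")),
    e("Celebrities or Industries", "Partnerships and Alliances", "Support",
      c("cosmetics", "viva glam", "aids fund", "kasper", "rappers",
        "victoria beckham")),
    e("Reduce Stigma", "Eliminate Stigma and Discrimination", "Support",
      c("lgbt", "stigma", "end stigma")),
    e("Discrimination of PLWH", "Eliminate Stigma and Discrimination",
      "Support", c("discrimination", "living", "people", "plwh"))
  )
  codebook(do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(theme = r$theme, keywords = r$keywords,
                   core_action = r$core_action, commitment = r$commitment)
  })))
}

#' Read a codebook from a structured text file
#'
#' One record per theme: tab-separated columns `theme`, `keywords`
#' (`;`-separated), `core_action`, `commitment`, with a header row.
#'
#' @param path input path.
#' @return a `codebook`.
#' @export
read_codebook <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  codebook(df)
}

#' Write a codebook to a structured text file
#'
#' @param cb a `codebook`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  df <- data.frame(
    theme = cb$theme,
    keywords = vapply(cb$keywords_raw, paste, character(1), collapse = ";"),
    core_action = cb$core_action,
    commitment = cb$commitment
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a node's top terms to a codebook theme
#'
#' Assigns the theme whose stemmed keyword set has the largest intersection
#' with the node's top terms (term-by-term; multiword keywords match
#' bigram terms), provided the intersection has at least `min_overlap`
#' terms. A tie between themes yields no assignment, flagged for manual
#' review.
#'
#' @param node_top_terms ranked term list of a topic-tree node.
#' @param cb a `codebook`.
#' @param min_overlap minimum keyword overlap for an assignment.
#' @return a one-row tibble with `theme`, `core_action`, `commitment`,
#'   `overlap` and `review` (TRUE when a tie was flagged), or `NULL` when no
#'   theme qualifies.
#' @export
apply_codebook <- function(node_top_terms, cb, min_overlap = 1L) {
  stopifnot(inherits(cb, "codebook"))
  if (nrow(cb) == 0) stop("codebook is empty")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  overlaps <- vapply(cb$keywords, function(kw) {
    length(intersect(kw, node_top_terms))
  }, integer(1))
  best <- max(overlaps)
  if (best < min_overlap) return(NULL)
  hits <- which(overlaps == best)
  if (length(hits) > 1) {
    out <- tibble::tibble(theme = NA_character_, core_action = NA_character_,
                          commitment = NA_character_, overlap = best,
                          review = TRUE)
    attr(out, "tied_themes") <- cb$theme[hits]
    return(out)
  }
  tibble::tibble(theme = cb$theme[hits], core_action = cb$core_action[hits],
                 commitment = cb$commitment[hits], overlap = best,
                 review = FALSE)
}

.assign_tree_themes <- function(tree_nodes, cb, min_overlap) {
  # tree_nodes: list of (node_id, depth, top_terms)
  recs <- lapply(tree_nodes, function(nd) {
    hit <- apply_codebook(nd$top_terms, cb, min_overlap)
    if (is.null(hit) || isTRUE(hit$review)) return(NULL)
    data.frame(theme = hit$theme, depth = nd$depth, node_id = nd$node_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

.tree_node_view <- function(tree) {
  if (inherits(tree, "topic_tree")) {
    lapply(unname(tree$nodes), function(nd) {
      list(node_id = nd$node_id, depth = nd$depth, top_terms = nd$top_terms)
    })
  } else if (is.data.frame(tree)) {
    stopifnot(all(c("node_id", "depth", "top_terms") %in% names(tree)))
    lapply(seq_len(nrow(tree)), function(i) {
      list(node_id = tree$node_id[i], depth = tree$depth[i],
           top_terms = tree$top_terms[[i]])
    })
  } else {
    stop("tree must be a topic_tree or a node data frame")
  }
}

#' Theme degree levels across two topic trees
#'
#' For every codebook theme assigned in either tree, reports the depth
#' ("degree level", root = 1) of its node in each tree and the level shift
#' `delta = depth_b - depth_a` when present in both. A positive delta means
#' the theme moved deeper in the later tree — a decrease in prominence.
#' Themes found in only one tree are reported with `NA` in the other. A
#' theme assigned to more than one node within a single tree is an error
#' listing the conflict.
#'
#' @param tree_a,tree_b `topic_tree` objects (or data frames with columns
#'   `node_id`, `depth` and a `top_terms` list column) for the earlier and
#'   later timepoint.
#' @param cb a `codebook`.
#' @param min_overlap minimum keyword overlap passed to [apply_codebook()].
#' @return tibble with `theme`, `core_action`, `commitment`, `depth_a`,
#'   `depth_b`, `delta`.
#' @export
theme_depth_table <- function(tree_a, tree_b, cb, min_overlap = 1L) {
  stopifnot(inherits(cb, "codebook"))
  assign_one <- function(tree, tag) {
    df <- .assign_tree_themes(.tree_node_view(tree), cb, min_overlap)
    if (is.null(df)) {
      return(data.frame(theme = character(0), depth = integer(0)))
    }
    dup <- unique(df$theme[duplicated(df$theme)])
    if (length(dup) > 0) {
      conf <- df[df$theme %in% dup, ]
      stop("theme(s) assigned to multiple nodes in tree ", tag, ": ",
           paste(sprintf("%s (nodes %s)", unique(conf$theme),
                         vapply(split(conf$node_id, conf$theme), paste,
                                character(1), collapse = ",")),
                 collapse = "; "))
    }
    df
  }
  da <- assign_one(tree_a, "a")
  db <- assign_one(tree_b, "b")
  themes <- union(da$theme, db$theme)
  depth_a <- da$depth[match(themes, da$theme)]
  depth_b <- db$depth[match(themes, db$theme)]
  idx <- match(themes, cb$theme)
  tibble::tibble(
    theme = themes,
    core_action = cb$core_action[idx],
    commitment = cb$commitment[idx],
    depth_a = depth_a,
    depth_b = depth_b,
    delta = depth_b - depth_a
  )
}
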