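# End-to-end orchestration: configuration, the read -> filter -> dedupe ->
# matrix -> tree -> trends -> themes pipeline, run manifests, and tree
# rendering (DOT / indented text).

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated object. For a single
#' corpus the pipeline stops after the frequency table; with two corpora
#' (an earlier and a later timepoint) it additionally compares trends and
#' theme degree levels. All randomness flows from the single `seed`.
#'
#' @param input_a path of the (earlier) corpus file.
#' @param input_b optional path of the later corpus file.
#' @param format corpus file format, `"delimited"` or `"records"`.
#' @param language language tag to keep.
#' @param prep a [prep_options()] list.
#' @param max_leaves,min_node_docs,m_top,tol,max_iter clustering parameters,
#'   see [hier_cluster()].
#' @param min_count,trend_mode,stable_band trend parameters, see
#'   [frequency_table()] and [compare_periods()].
#' @param codebook_path optional path of a codebook file; default uses
#'   [default_codebook()].
#' @param out_dir output directory for all artifacts.
#' @param seed integer seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_a, input_b = NULL,
                            format = c("delimited", "records"),
                            language = "en", prep = prep_options(),
                            max_leaves = 8L, min_node_docs = 5L,
                            m_top = 10L, tol = 1e-4, max_iter = 200L,
                            min_count = 35L,
                            trend_mode = c("normalized", "raw"),
                            stable_band = 0.25, codebook_path = NULL,
                            out_dir = "tweettree_out", seed = 1L) {
  format <- match.arg(format)
  trend_mode <- match.arg(trend_mode)
  stopifnot(inherits(prep, "prep_options"))
  if (max_leaves < 1) stop("max_leaves must be >= 1")
  if (min_node_docs < 2) stop("min_node_docs must be >= 2")
  if (m_top < 1) stop("m_top must be >= 1")
  if (tol <= 0 || max_iter < 1) stop("invalid convergence parameters")
  if (min_count < 1) stop("min_count must be >= 1")
  if (stable_band < 0) stop("stable_band must be >= 0")
  structure(
    list(input_a = input_a, input_b = input_b, format = format,
         language = language, prep = prep,
         max_leaves = as.integer(max_leaves),
         min_node_docs = as.integer(min_node_docs),
         m_top = as.integer(m_top), tol = tol,
         max_iter = as.integer(max_iter), min_count = as.integer(min_count),
         trend_mode = trend_mode, stable_band = stable_band,
         codebook_path = codebook_path, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.process_one <- function(path, tag, config, manifest_env) {
  t0 <- Sys.time()
  corpus <- .stage(paste0("read[", tag, "]"),
                   read_corpus(path, format = config$format))
  corpus <- .stage(paste0("filter_language[", tag, "]"),
                   filter_language(corpus, config$language))
  dd <- .stage(paste0("dedupe[", tag, "]"), dedupe_unique(corpus))
  uniq <- dd$corpus
  tdm <- .stage(paste0("build_matrix[", tag, "]"),
                build_matrix(uniq, config$prep))
  tree <- .stage(paste0("hier_cluster[", tag, "]"),
                 hier_cluster(tdm, max_leaves = config$max_leaves,
                              min_node_docs = config$min_node_docs,
                              m_top = config$m_top, seed = config$seed,
                              tol = config$tol,
                              max_iter = config$max_iter))
  freq <- .stage(paste0("frequency_table[", tag, "]"),
                 frequency_table(uniq, config$prep, config$min_count))

  od <- config$out_dir
  mtx_stem <- file.path(od, paste0(tag, "_matrix"))
  write_matrix(tdm, mtx_stem)
  tree_path <- file.path(od, paste0(tag, "_tree.json"))
  tree_to_json(tree, tree_path)
  labels <- flat_clusters(tree)
  labels_path <- file.path(od, paste0(tag, "_labels.tsv"))
  utils::write.table(data.frame(id = tdm$doc_ids, leaf = labels),
                     labels_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  freq_path <- file.path(od, paste0(tag, "_frequencies.csv"))
  utils::write.csv(as.data.frame(freq), freq_path, row.names = FALSE)

  manifest_env$stages[[tag]] <- list(
    input = path, messages = corpus_size(corpus) + attr(corpus, "malformed"),
    kept = corpus_size(corpus), unique = corpus_size(uniq),
    reach = aggregate_reach(corpus), terms = length(tdm$terms),
    documents_clustered = length(tdm$doc_ids),
    leaves = length(tree_leaves(tree)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_env$artifacts[[tag]] <- list(
    matrix = paste0(mtx_stem, ".mtx"), tree = tree_path,
    labels = labels_path, frequencies = freq_path
  )
  list(corpus = uniq, tdm = tdm, tree = tree, freq = freq)
}

#' Run the full topic-tree pipeline
#'
#' Executes read, language filter, retweet deduplication, matrix
#' construction, hierarchical clustering and frequency aggregation for one
#' or two corpora; with two corpora it also writes the trend comparison and
#' the theme degree-level table. Every artifact path, parameter and
#' per-stage count is recorded in a JSON manifest, and identical
#' configuration plus inputs yield identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  env <- new.env()
  env$stages <- list()
  env$artifacts <- list()

  a <- .process_one(config$input_a, "a", config, env)
  if (!is.null(config$input_b)) {
    b <- .process_one(config$input_b, "b", config, env)
    cb <- if (is.null(config$codebook_path)) default_codebook() else
      .stage("read_codebook", read_codebook(config$codebook_path))
    trends <- .stage("compare_periods", compare_periods(
      a$freq, b$freq, corpus_size(a$corpus), corpus_size(b$corpus),
      mode = config$trend_mode, stable_band = config$stable_band
    ))
    trends_path <- file.path(config$out_dir, "trends.csv")
    utils::write.csv(as.data.frame(trends), trends_path, row.names = FALSE)
    depth_tab <- .stage("theme_depth_table",
                        theme_depth_table(a$tree, b$tree, cb))
    depth_path <- file.path(config$out_dir, "theme_depths.csv")
    utils::write.csv(as.data.frame(depth_tab), depth_path,
                     row.names = FALSE)
    env$artifacts$comparison <- list(trends = trends_path,
                                     theme_depths = depth_path)
  }

  manifest <- list(
    parameters = list(
      format = config$format, language = config$language,
      ngram_min = config$prep$ngram_min, ngram_max = config$prep$ngram_max,
      min_term_docfreq = config$prep$min_term_docfreq,
      keep_hashtags = config$prep$keep_hashtags,
      weighting = config$prep$weighting,
      normalize_docs = config$prep$normalize_docs,
      max_leaves = config$max_leaves,
      min_node_docs = config$min_node_docs, m_top = config$m_top,
      tol = config$tol, max_iter = config$max_iter,
      min_count = config$min_count, trend_mode = config$trend_mode,
      stable_band = config$stable_band, seed = config$seed
    ),
    stages = env$stages,
    artifacts = env$artifacts,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render an exported topic tree
#'
#' Reads a tree JSON written by [tree_to_json()] and renders it either as a
#' DOT digraph (for graph layout tools) or as an indented text outline, one
#' line per node with id, depth, document count and top terms.
#'
#' @param json_path path of the tree JSON.
#' @param format `"dot"` or `"text"`.
#' @return character vector of rendering lines.
#' @export
render_tree <- function(json_path, format = c("dot", "text")) {
  format <- match.arg(format)
  nodes <- tryCatch(
    jsonlite::fromJSON(json_path, simplifyDataFrame = FALSE),
    error = function(e) {
      stop("malformed tree JSON at ", json_path, ": ", conditionMessage(e))
    }
  )
  lab <- function(nd) {
    sprintf("n%d [d%d, %d docs] %s", nd$node_id, nd$depth, nd$doc_count,
            paste(utils::head(unlist(nd$top_terms), 5), collapse = " "))
  }
  if (format == "dot") {
    lines <- c("digraph topic_tree {", "  node [shape=box];")
    for (nd in nodes) {
      lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$node_id,
                                gsub("\"", "'", lab(nd))))
    }
    for (nd in nodes) {
      for (ch in unlist(nd$child_ids)) {
        lines <- c(lines, sprintf("  n%d -> n%d;", nd$node_id, ch))
      }
    }
    c(lines, "}")
  } else {
    by_id <- stats::setNames(nodes, vapply(nodes, function(nd) {
      as.character(nd$node_id)
    }, character(1)))
    out <- character(0)
    walk <- function(id) {
      nd <- by_id[[as.character(id)]]
      out <<- c(out, paste0(strrep("  ", nd$depth - 1), lab(nd)))
      for (ch in unlist(nd$child_ids)) walk(ch)
    }
    roots <- Filter(function(nd) is.null(nd$parent_id), nodes)
    for (r in roots) walk(r$node_id)
    out
  }
}
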