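# Hierarchical rank-2 NMF: exact two-column nonnegative least squares,
# alternating rank-2 factorization, mNDCG node-splitting score, and the
# greedy frontier algorithm that grows the binary topic tree.

# Vectorized exact rank-2 NNLS: for every column a of A solve
#   min_{h >= 0} ||W h - a||_2,  W is m x 2.
# The minimizer lies on one of three candidate active sets: the
# unconstrained 2x2 normal-equation solution (when nonnegative), or one of
# the two single-column projections max(0, w_j'a / ||w_j||^2). Residuals are
# compared through f(h) = h'Gh - 2 h'b, which differs from the true squared
# residual by the constant ||a||^2.
.nnls_rank2_multi <- function(W, A) {
  G <- crossprod(W)
  if (G[1, 1] == 0 && G[2, 2] == 0) {
    stop("both columns of W are zero: degenerate rank-2 NNLS problem")
  }
  B <- as.matrix(Matrix::crossprod(W, A))
  n <- ncol(B)
  H <- matrix(0, 2, n)

  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  feas <- rep(FALSE, n)
  if (det > 1e-12 * max(G[1, 1], G[2, 2])^2) {
    u1 <- (G[2, 2] * B[1, ] - G[1, 2] * B[2, ]) / det
    u2 <- (G[1, 1] * B[2, ] - G[1, 2] * B[1, ]) / det
    feas <- u1 >= 0 & u2 >= 0
    H[1, feas] <- u1[feas]
    H[2, feas] <- u2[feas]
  }
  rest <- which(!feas)
  if (length(rest) > 0) {
    c1 <- if (G[1, 1] > 0) pmax(0, B[1, rest] / G[1, 1]) else rep(0, length(rest))
    c2 <- if (G[2, 2] > 0) pmax(0, B[2, rest] / G[2, 2]) else rep(0, length(rest))
    f1 <- c1^2 * G[1, 1] - 2 * c1 * B[1, rest]
    f2 <- c2^2 * G[2, 2] - 2 * c2 * B[2, rest]
    use1 <- f1 <= f2  # tie -> first column
    H[1, rest[use1]] <- c1[use1]
    H[2, rest[!use1]] <- c2[!use1]
  }
  H
}

#' Exact rank-2 nonnegative least squares
#'
#' Solves `min ||W h - a||_2` subject to `h >= 0` for a two-column design
#' `W`, exactly, by evaluating the three candidate active sets: the
#' unconstrained 2x2 normal-equation solution if it is nonnegative,
#' otherwise the better of the two single-column projections
#' `max(0, w_j' a / ||w_j||^2)`.
#'
#' @param W nonnegative numeric matrix with 2 columns, at least one nonzero.
#' @param a nonnegative numeric vector, `length(a) == nrow(W)`.
#' @return nonnegative numeric 2-vector `h`.
#' @examples
#' nnls_rank2(diag(2), c(3, 4))
#' @export
nnls_rank2 <- function(W, a) {
  W <- as.matrix(W)
  if (ncol(W) != 2) stop("W must have exactly 2 columns")
  if (length(a) != nrow(W)) stop("length(a) must equal nrow(W)")
  as.numeric(.nnls_rank2_multi(W, matrix(a, ncol = 1)))
}

.frob2 <- function(A) sum(A^2)

# ||A - WH||_F^2 without forming WH densely
.residual2 <- function(A, W, H, normA2) {
  WtA <- as.matrix(Matrix::crossprod(W, A))
  normA2 - 2 * sum(WtA * H) + sum(crossprod(W) * tcrossprod(H))
}

#' Rank-2 nonnegative matrix factorization
#'
#' Alternating minimization for `A ~ W H` with `W` (terms x 2) and `H`
#' (2 x documents) nonnegative; each half-step solves the exact rank-2
#' NNLS subproblem column-wise (for `H` on the columns of `A`, for `W` via
#' the transposed problem), so the squared Frobenius objective is
#' non-increasing. `W` is initialized by a deterministic NNDSVD-style rule:
#' the leading two singular directions of `A` are computed by power
#' iteration (started from the row-sum vector, which is order-independent),
#' the second direction is replaced by whichever of its positive or negative
#' parts carries more mass, and seeded uniform noise of magnitude 1e-6 is
#' added. The factorization is therefore reproducible from `seed` and
#' equivariant under document permutation. On return the columns of `W`
#' have unit Euclidean norm with the scale absorbed into `H`.
#'
#' @param A nonnegative matrix (dense or `Matrix` sparse), terms x documents,
#'   with at least 2 documents and at least 2 nonzero rows.
#' @param seed integer seed for the initialization noise.
#' @param tol relative objective-decrease tolerance for convergence.
#' @param max_iter maximum number of alternating iterations.
#' @return a `rank2_factorization`: list with `W`, `H`, `objective_trace`
#'   (squared Frobenius residual per iteration, starting at the
#'   initialization), `iterations` and `converged`.
#' @export
rank2_nmf <- function(A, seed = 1L, tol = 1e-4, max_iter = 200L) {
  if (is.null(dim(A)) || nrow(A) < 1 || ncol(A) < 2) {
    stop("degenerate submatrix: need >= 2 documents; mark node a permanent leaf")
  }
  nz_rows <- Matrix::rowSums(A != 0) > 0
  if (sum(nz_rows) < 2) {
    stop("degenerate submatrix: need >= 2 terms with nonzero rows; ",
         "mark node a permanent leaf")
  }

  if (sum(Matrix::colSums(A^2)) == 0) {
    stop("degenerate submatrix: all documents zero; mark node a permanent leaf")
  }

  m <- nrow(A)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # NNDSVD-style init: leading two singular directions by power iteration
  # on AA', deflating the first; the start vector (row sums) and the
  # iteration are invariant to document order
  normalize <- function(x) {
    nx <- sqrt(sum(x^2))
    if (nx > 0) x / nx else x
  }
  power_dir <- function(u0, deflate = NULL, iters = 30L) {
    u <- normalize(u0)
    for (i in seq_len(iters)) {
      v <- as.numeric(Matrix::crossprod(A, u))
      u_new <- as.numeric(A %*% v)
      if (!is.null(deflate)) {
        u_new <- u_new - deflate * sum(deflate * u_new)
      }
      if (sum(u_new^2) == 0) break
      u <- normalize(u_new)
    }
    u
  }
  r <- as.numeric(Matrix::rowSums(A))
  u1 <- power_dir(r)
  # deterministic seeded start off u1's span for the second direction
  u2_start <- r + stats::runif(m, -1, 1) * max(abs(r))
  u2_start <- u2_start - u1 * sum(u1 * u2_start)
  u2 <- power_dir(u2_start, deflate = u1)
  u2p <- pmax(u2, 0)
  u2n <- pmax(-u2, 0)
  w2 <- if (sum(u2p^2) >= sum(u2n^2)) u2p else u2n
  W <- cbind(pmax(u1, 0), normalize(w2)) +
    matrix(stats::runif(2 * m, 0, 1e-6), m, 2)

  normA2 <- .frob2(A)
  H <- .nnls_rank2_multi(W, A)
  trace <- .residual2(A, W, H, normA2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Wt <- .nnls_rank2_multi(t(H), Matrix::t(A))
    W <- t(Wt)
    if (all(W == 0)) break
    H <- .nnls_rank2_multi(W, A)
    obj <- .residual2(A, W, H, normA2)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (prev <= 0 || (prev - obj) / max(prev, .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
  }

  d <- sqrt(colSums(W^2))
  scale <- ifelse(d > 0, d, 1)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale

  structure(
    list(W = W, H = H, objective_trace = pmax(trace, 0),
         iterations = iter, converged = converged),
    class = "rank2_factorization"
  )
}

#' Partition documents between the two children of a split
#'
#' Column `j` goes to the left child `L` when `H[1, j] >= H[2, j]` (ties to
#' `L`), else to the right child `R`; `L` is the child whose topic vector is
#' the first column of `W`.
#'
#' @param H nonnegative 2 x n matrix.
#' @return list with integer index vectors `L` and `R`.
#' @export
assign_children <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) != 2) stop("H must have 2 rows")
  left <- H[1, ] >= H[2, ]
  list(L = which(left), R = which(!left))
}

#' Top-weighted terms of a topic vector
#'
#' @param topic_vector nonnegative numeric term-weight vector.
#' @param m_top number of terms to return.
#' @param terms optional character vector naming the entries; when supplied
#'   the term strings are returned, otherwise indices.
#' @return the `m_top` largest-weight entries in descending order; ties are
#'   broken by vocabulary (index) order.
#' @export
top_terms <- function(topic_vector, m_top, terms = NULL) {
  if (m_top < 1) stop("m_top must be >= 1")
  ord <- order(-topic_vector, seq_along(topic_vector))
  idx <- ord[seq_len(min(m_top, length(topic_vector)))]
  if (is.null(terms)) idx else terms[idx]
}

#' mNDCG well-separatedness score of a candidate split
#'
#' For a ranked list `t_1..t_m` scored against the sibling list `S`, the
#' gain of `t_i` is 0 when `t_i` is shared with `S` and 1 otherwise;
#' `DCG = sum(gain_i / log2(i + 1))`, `IDCG = sum(1 / log2(i + 1))`, and
#' `mNDCG = DCG / IDCG`. The split score is the product of the two sibling
#' mNDCGs, so it is 1 for disjoint top-term lists and 0 for identical ones.
#'
#' With the default `match = "unigram"`, a term counts as shared when any of
#' its constituent words occurs among the sibling list's constituent words,
#' so an n-gram built from the sibling's head word is not treated as
#' evidence of separation (n-gram vocabularies otherwise inflate the score
#' of spurious splits whose children differ only in term combinations).
#' `match = "exact"` compares whole term strings; the two rules coincide on
#' unigram lists.
#'
#' @param left_top,right_top ranked term lists of equal length.
#' @param match `"unigram"` (constituent-word sharing, default) or
#'   `"exact"` (whole-string sharing).
#' @return a number in `[0, 1]`.
#' @export
split_score <- function(left_top, right_top, match = c("unigram", "exact")) {
  match <- match.arg(match)
  m <- length(left_top)
  if (m != length(right_top)) stop("top-term lists must have the same length")
  if (m < 1) stop("top-term lists must be non-empty")
  disc <- 1 / log2(seq_len(m) + 1)
  idcg <- sum(disc)
  shared <- if (match == "exact") {
    function(x, sibling) x %in% sibling
  } else {
    function(x, sibling) {
      sib_words <- unique(unlist(strsplit(sibling, " ", fixed = TRUE)))
      vapply(strsplit(x, " ", fixed = TRUE),
             function(w) any(w %in% sib_words), logical(1))
    }
  }
  mndcg <- function(x, sibling) sum(disc[!shared(x, sibling)]) / idcg
  mndcg(left_top, right_top) * mndcg(right_top, left_top)
}

# trial rank-2 split of one node; NULL when the node cannot be split
.trial_split <- function(A, doc_idx, min_node_docs, m_top, terms, seed,
                         tol, max_iter) {
  if (length(doc_idx) < max(2L, 2L * 1L)) return(NULL)
  sub <- A[, doc_idx, drop = FALSE]
  row_keep <- which(Matrix::rowSums(sub != 0) > 0)
  if (length(row_keep) < 2) return(NULL)
  sub <- sub[row_keep, , drop = FALSE]
  fac <- tryCatch(
    rank2_nmf(sub, seed = seed, tol = tol, max_iter = max_iter),
    error = function(e) NULL
  )
  if (is.null(fac)) return(NULL)
  part <- assign_children(fac$H)
  if (length(part$L) < min_node_docs || length(part$R) < min_node_docs) {
    return(NULL)
  }
  # lift W columns back to the full term space
  m <- nrow(A)
  wL <- numeric(m); wL[row_keep] <- fac$W[, 1]
  wR <- numeric(m); wR[row_keep] <- fac$W[, 2]
  topL <- top_terms(wL, m_top, terms)
  topR <- top_terms(wR, m_top, terms)
  list(
    L_docs = doc_idx[part$L], R_docs = doc_idx[part$R],
    wL = wL, wR = wR, topL = topL, topR = topR,
    score = split_score(topL, topR)
  )
}

#' Hierarchical rank-2 NMF topic tree
#'
#' Greedy frontier construction of a binary topic tree. Starting from a root
#' holding every document, each current leaf (not marked permanent) gets a
#' trial rank-2 NMF split scored by [split_score()]; the leaf with the
#' highest score is split into its two children, and the frontier is
#' rescored. A trial split that would give a child fewer than
#' `min_node_docs` documents (or a degenerate submatrix) marks the leaf
#' permanent. Construction stops when the leaf count reaches `max_leaves` or
#' no splittable leaf remains, so the tree is detected from the data and
#' need not be balanced. Depths count the root as degree level 1.
#'
#' @param A a `term_doc_matrix` (or plain nonnegative matrix with terms as
#'   rows).
#' @param max_leaves maximum number of leaves.
#' @param min_node_docs minimum documents per node for a split to stand.
#' @param m_top number of top terms kept per node and used by the score.
#' @param seed integer seed (fanned out deterministically per node).
#' @param tol,max_iter convergence controls passed to [rank2_nmf()].
#' @return a `topic_tree`: list with `nodes` (per-node lists), `root_id`,
#'   `terms`, `doc_ids` and the parameters.
#' @export
hier_cluster <- function(A, max_leaves = 8L, min_node_docs = 5L, m_top = 10L,
                         seed = 1L, tol = 1e-4, max_iter = 200L) {
  if (inherits(A, "term_doc_matrix")) {
    terms <- A$terms; doc_ids <- A$doc_ids; mat <- A$values
  } else {
    mat <- A
    terms <- if (!is.null(rownames(A))) rownames(A) else
      paste0("term", seq_len(nrow(A)))
    doc_ids <- if (!is.null(colnames(A))) colnames(A) else
      paste0("doc", seq_len(ncol(A)))
  }
  if (is.null(dim(mat)) || nrow(mat) == 0 || ncol(mat) == 0) {
    stop("empty term-document matrix")
  }
  if (max_leaves < 1) stop("max_leaves must be >= 1")
  if (min_node_docs < 2) stop("min_node_docs must be >= 2")
  n <- ncol(mat)

  node_seed <- function(id) {
    as.integer((as.numeric(seed) * 1000003 + id * 7919) %% 2147483647)
  }

  root_vec <- as.numeric(Matrix::rowSums(mat))
  nodes <- list()
  nodes[["1"]] <- list(
    node_id = 1L, parent_id = NA_integer_, child_ids = integer(0),
    doc_indices = seq_len(n), topic_vector = root_vec,
    top_terms = top_terms(root_vec, m_top, terms),
    split_score = NA_real_, depth = 1L, is_permanent_leaf = FALSE
  )
  trials <- list()
  next_id <- 2L

  get_trial <- function(id) {
    key <- as.character(id)
    if (!is.null(trials[[key]])) return(trials[[key]])
    node <- nodes[[key]]
    tr <- .trial_split(mat, node$doc_indices, min_node_docs, m_top, terms,
                       seed = node_seed(id), tol = tol, max_iter = max_iter)
    trials[[key]] <<- if (is.null(tr)) list(permanent = TRUE) else tr
    trials[[key]]
  }

  repeat {
    leaf_ids <- vapply(nodes, function(nd) {
      if (length(nd$child_ids) == 0) nd$node_id else NA_integer_
    }, integer(1))
    leaf_ids <- sort(leaf_ids[!is.na(leaf_ids)])
    if (length(leaf_ids) >= max_leaves) break

    best_id <- NA_integer_
    best_score <- -Inf
    for (id in leaf_ids) {
      key <- as.character(id)
      if (nodes[[key]]$is_permanent_leaf) next
      tr <- get_trial(id)
      if (isTRUE(tr$permanent)) {
        nodes[[key]]$is_permanent_leaf <- TRUE
        next
      }
      nodes[[key]]$split_score <- tr$score
      if (tr$score > best_score) {  # ties: smaller node_id (ids ascend)
        best_score <- tr$score
        best_id <- id
      }
    }
    if (is.na(best_id)) break

    key <- as.character(best_id)
    tr <- trials[[key]]
    parent <- nodes[[key]]
    idL <- next_id; idR <- next_id + 1L
    next_id <- next_id + 2L
    nodes[[key]]$child_ids <- c(idL, idR)
    nodes[[as.character(idL)]] <- list(
      node_id = idL, parent_id = parent$node_id, child_ids = integer(0),
      doc_indices = tr$L_docs, topic_vector = tr$wL, top_terms = tr$topL,
      split_score = NA_real_, depth = parent$depth + 1L,
      is_permanent_leaf = FALSE
    )
    nodes[[as.character(idR)]] <- list(
      node_id = idR, parent_id = parent$node_id, child_ids = integer(0),
      doc_indices = tr$R_docs, topic_vector = tr$wR, top_terms = tr$topR,
      split_score = NA_real_, depth = parent$depth + 1L,
      is_permanent_leaf = FALSE
    )
  }

  structure(
    list(nodes = nodes, root_id = 1L, terms = terms, doc_ids = doc_ids,
         max_leaves = as.integer(max_leaves),
         min_node_docs = as.integer(min_node_docs),
         m_top = as.integer(m_top), seed = as.integer(seed)),
    class = "topic_tree"
  )
}

#' @export
print.topic_tree <- function(x, ...) {
  n_leaf <- sum(vapply(x$nodes, function(nd) length(nd$child_ids) == 0,
                       logical(1)))
  cat(sprintf("<topic_tree: %d nodes, %d leaves, %d documents>\n",
              length(x$nodes), n_leaf, length(x$doc_ids)))
  invisible(x)
}

#' Leaf nodes of a topic tree
#' @param tree a `topic_tree`.
#' @return list of leaf node records.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "topic_tree"))
  Filter(function(nd) length(nd$child_ids) == 0, tree$nodes)
}

#' Flat cluster labels from a topic tree
#'
#' Labels each document with the id of the leaf whose document set contains
#' it; leaf document sets partition the corpus, so every document receives
#' exactly one label.
#'
#' @param tree a `topic_tree`.
#' @return integer vector of leaf node ids, one per document.
#' @export
flat_clusters <- function(tree) {
  stopifnot(inherits(tree, "topic_tree"))
  n <- length(tree$doc_ids)
  labels <- rep(NA_integer_, n)
  for (nd in tree_leaves(tree)) {
    labels[nd$doc_indices] <- nd$node_id
  }
  labels
}

#' Export a topic tree as JSON
#'
#' One record per node with `node_id`, `parent_id`, `child_ids`, `depth`,
#' `doc_count`, `top_terms` with weights, and `split_score`.
#'
#' @param tree a `topic_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
tree_to_json <- function(tree, path) {
  stopifnot(inherits(tree, "topic_tree"))
  ids <- sort(vapply(tree$nodes, `[[`, integer(1), "node_id"))
  recs <- lapply(ids, function(id) {
    nd <- tree$nodes[[as.character(id)]]
    idx <- match(nd$top_terms, tree$terms)
    list(
      node_id = nd$node_id,
      parent_id = if (is.na(nd$parent_id)) NULL else nd$parent_id,
      child_ids = as.integer(nd$child_ids),
      depth = nd$depth,
      doc_count = length(nd$doc_indices),
      top_terms = as.character(nd$top_terms),
      top_term_weights = round(nd$topic_vector[idx], 8),
      split_score = if (is.na(nd$split_score)) NULL else nd$split_score
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
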