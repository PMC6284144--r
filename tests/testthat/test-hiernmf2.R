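# Rank-2 NNLS, alternating rank-2 NMF, the mNDCG split score, and the
# greedy binary topic tree.

test_that("nnls_rank2 solves the easy orthonormal cases exactly", {
  W <- diag(2)
  expect_equal(nnls_rank2(W, c(3, 4)), c(3, 4))
  expect_equal(nnls_rank2(W, c(0, 2)), c(0, 2))
  expect_error(nnls_rank2(matrix(0, 3, 2), c(1, 1, 1)), "degenerate")
  expect_error(nnls_rank2(matrix(1, 3, 3), 1:3), "2 columns")
})

test_that("nnls_rank2 matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    W <- matrix(stats::runif(12), 6, 2)
    if (i %% 3 == 0) W[, 2] <- W[, 1] * 2  # collinear columns
    a <- stats::runif(6)
    h <- nnls_rank2(W, a)
    h0 <- nnls2_oracle(W, a)
    expect_true(all(h >= 0))
    r <- sum((W %*% h - a)^2)
    r0 <- sum((W %*% h0 - a)^2)
    expect_lt(abs(r - r0), 1e-10)
  }
})

test_that("rank2_nmf recovers exact nonnegative rank-2 structure", {
  set.seed(5)
  W0 <- matrix(stats::runif(16), 8, 2)
  H0 <- matrix(stats::runif(12), 2, 6)
  A <- W0 %*% H0
  fac <- rank2_nmf(A, seed = 1, tol = 1e-10, max_iter = 500)
  rel <- sqrt(sum((A - fac$W %*% fac$H)^2) / sum(A^2))
  expect_lte(rel, 1e-6)
  expect_true(all(fac$W >= 0))
  expect_true(all(fac$H >= 0))
  wn <- sqrt(colSums(fac$W^2))
  expect_equal(unname(wn), c(1, 1), tolerance = 1e-9)
})

test_that("a repeated single column is captured with near-zero residual", {
  A <- matrix(rep(c(1, 2, 3), 4), nrow = 3)
  fac <- rank2_nmf(A, seed = 2)
  expect_lte(sqrt(sum((A - fac$W %*% fac$H)^2)), 1e-9)
})

test_that("objective trace is non-increasing on random matrices", {
  set.seed(77)
  for (i in 1:5) {
    A <- matrix(stats::rexp(20 * 15), 20, 15)
    fac <- rank2_nmf(A, seed = i, tol = 1e-12, max_iter = 60)
    tr <- fac$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * tr[1]))
    expect_lte(tr[length(tr)], tr[1])
  }
})

test_that("degenerate submatrices are rejected with leaf guidance", {
  expect_error(rank2_nmf(matrix(1, 3, 1)), "permanent leaf")
  expect_error(rank2_nmf(matrix(c(1, 0, 0, 2, 0, 0), 3, 2)),
               "permanent leaf")
})

test_that("assign_children partitions by H rows with ties to L", {
  expect_equal(assign_children(matrix(c(1, 0, 0, 1), 2, 2)),
               list(L = 1L, R = 2L))
  expect_equal(assign_children(matrix(c(0.5, 0.5), 2, 1))$L, 1L)
  H <- matrix(c(0.9, 0.1,
                0.2, 0.7,
                0.4, 0.4,
                0.1, 0.9), nrow = 2)
  # hand argmax: cols 1 and 3 left (col 3 tie), cols 2 and 4 right
  expect_equal(assign_children(H), list(L = c(1L, 3L), R = c(2L, 4L)))
})

test_that("top_terms ranks by weight with vocabulary-order ties", {
  terms <- c("t0", "t1", "t2")
  expect_equal(top_terms(c(0.9, 0.1, 0.5), 2, terms), c("t0", "t2"))
  expect_equal(top_terms(c(0.2, 0.2, 0.1), 2, terms), c("t0", "t1"))
  expect_equal(top_terms(c(0.1, 0.3), 10, c("a", "b")), c("b", "a"))
})

test_that("split_score closed forms hold", {
  expect_equal(split_score(c("a", "b", "c"), c("d", "e", "f")), 1.0)
  expect_equal(split_score(c("a", "b", "c"), c("a", "b", "c")), 0.0)
  # lists sharing only each other's rank-1 term; hand DCG:
  # mNDCG = (1/log2(3) + 1/2) / (1 + 1/log2(3) + 1/2), squared
  s <- split_score(c("a", "x", "y"), c("a", "p", "q"))
  hand <- ((1 / log2(3) + 1 / 2) / (1 + 1 / log2(3) + 1 / 2))^2
  expect_equal(s, hand, tolerance = 1e-12)
  expect_lt(abs(s - 0.2816), 1e-3)
  expect_error(split_score(c("a", "b"), "a"), "same length")
})

test_that("unigram matching treats shared constituents as overlap", {
  # "aids day" shares the word "aids" with the sibling's unigram
  expect_lt(split_score(c("aids day", "x", "y"), c("aids", "p", "q")), 1)
  expect_equal(
    split_score(c("aids day", "x", "y"), c("aids", "p", "q"),
                match = "exact"),
    1.0
  )
})

test_that("max_leaves = 1 yields a root-only tree", {
  cp <- fixture12()
  tdm <- build_matrix(cp, prep_options(min_term_docfreq = 1))
  tree <- hier_cluster(tdm, max_leaves = 1)
  expect_length(tree$nodes, 1)
  expect_equal(unique(flat_clusters(tree)), 1L)
})

test_that("disjoint vocabularies split into the exact block partition", {
  txt <- c(rep("apple banana cherry", 6), rep("xray yankee zulu", 5))
  txt <- paste(txt, rep(c("date fig", "whiskey victor"),
                        c(6, 5)), seq_along(txt))  # avoid dedupe collapse
  cp <- make_corpus(txt)
  tdm <- build_matrix(cp, prep_options(ngram_max = 1, min_term_docfreq = 1,
                                       weighting = "tf"))
  tree <- hier_cluster(tdm, max_leaves = 2, min_node_docs = 2, seed = 3)
  labels <- flat_clusters(tree)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:6])), 1)
  expect_equal(length(unique(labels[7:11])), 1)
  expect_false(labels[1] == labels[7])
})

test_that("flat cluster label sizes equal the leaf document sets", {
  spec <- demo_spec()
  out <- sample_corpus(spec)
  tdm <- build_matrix(dedupe_unique(out$corpus)$corpus, prep_options())
  tree <- hier_cluster(tdm, max_leaves = 4, seed = 9)
  labels <- flat_clusters(tree)
  expect_false(anyNA(labels))
  sizes <- table(labels)
  for (leaf in tree_leaves(tree)) {
    expect_equal(unname(sizes[as.character(leaf$node_id)]),
                 length(leaf$doc_indices), ignore_attr = TRUE)
  }
})

test_that("tree invariants hold across randomized configurations", {
  set.seed(2024)
  cfgs <- expand.grid(n_docs = c(80, 160), max_leaves = c(1, 3, 6),
                      seed = c(4, 13))
  for (i in seq_len(nrow(cfgs))) {
    spec <- synthetic_spec(n_topics = 3, n_docs = cfgs$n_docs[i],
                           seed = cfgs$seed[i])
    out <- sample_corpus(spec)
    tdm <- build_matrix(dedupe_unique(out$corpus)$corpus, prep_options())
    tree <- hier_cluster(tdm, max_leaves = cfgs$max_leaves[i],
                         min_node_docs = 4, seed = cfgs$seed[i])
    n <- length(tree$doc_ids)
    leaves <- tree_leaves(tree)
    expect_lte(length(leaves), cfgs$max_leaves[i])
    # leaves partition all documents
    all_docs <- sort(unname(unlist(lapply(leaves, `[[`, "doc_indices"))))
    expect_equal(all_docs, seq_len(n))
    expect_equal(tree$nodes[[as.character(tree$root_id)]]$depth, 1L)
    for (nd in tree$nodes) {
      expect_true(length(nd$child_ids) %in% c(0L, 2L))
      if (length(nd$child_ids) == 2) {
        kids <- lapply(as.character(nd$child_ids),
                       function(k) tree$nodes[[k]])
        expect_equal(sort(c(kids[[1]]$doc_indices, kids[[2]]$doc_indices)),
                     sort(nd$doc_indices))
        expect_equal(length(intersect(kids[[1]]$doc_indices,
                                      kids[[2]]$doc_indices)), 0)
        for (k in kids) expect_equal(k$depth, nd$depth + 1L)
      }
    }
  }
})

test_that("clustering is equivariant under document permutation", {
  spec <- demo_spec()
  out <- sample_corpus(spec)
  tdm <- build_matrix(dedupe_unique(out$corpus)$corpus, prep_options())
  tree1 <- hier_cluster(tdm, max_leaves = 4, seed = 6)
  lab1 <- flat_clusters(tree1)

  set.seed(99)
  perm <- sample(ncol(tdm$values))
  tdm2 <- tdm
  tdm2$values <- tdm$values[, perm, drop = FALSE]
  tdm2$doc_ids <- tdm$doc_ids[perm]
  tree2 <- hier_cluster(tdm2, max_leaves = 4, seed = 6)
  lab2 <- flat_clusters(tree2)

  expect_equal(mclust::adjustedRandIndex(lab2, lab1[perm]), 1)
})

test_that("tree JSON export round-trips node structure", {
  spec <- demo_spec()
  out <- sample_corpus(spec)
  tdm <- build_matrix(dedupe_unique(out$corpus)$corpus, prep_options())
  tree <- hier_cluster(tdm, max_leaves = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  nodes <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_length(nodes, length(tree$nodes))
  counts <- vapply(nodes, `[[`, numeric(1), "doc_count")
  expect_equal(sum(counts[vapply(nodes, function(nd) {
    length(unlist(nd$child_ids)) == 0
  }, logical(1))]), length(tree$doc_ids))
})
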