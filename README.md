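# tweettree

Hierarchical rank-2 NMF topic trees and two-timepoint trend analysis for
tweet corpora.

`tweettree` is an infoveillance toolkit for studying public health sentiment
in short social-media documents — the motivating application is World AIDS
Day tweet analysis, where two single-day corpora a year apart are compared
for shifts in what the public talks about and how prominently. It covers the
full pipeline: corpus ingestion with retweet and follower-reach accounting,
text preparation into a term-document matrix, hierarchical topic discovery
by recursive rank-2 nonnegative matrix factorization, topic frequency trend
comparison between timepoints, and mapping of discovered topic clusters to
UNAIDS core action principles through a keyword codebook. A synthetic
corpus generator with planted topic structure makes every stage testable
without access to real Twitter data.

## The method

Documents are prepared by case-folding, URL/mention stripping, stopword
removal, Porter stemming, and N-gram extraction (unigrams + bigrams by
default), then assembled into a nonnegative term-document matrix
*A* ∈ ℝ^(m×n) with tf-idf weights and unit-norm document columns.

The topic hierarchy is a binary tree grown greedily. Each candidate node
split solves a rank-2 NMF

> min ‖A − W H‖²_F  subject to W ≥ 0 (m×2), H ≥ 0 (2×n)

by alternating exact nonnegative least squares: for a two-column design the
NNLS minimizer lies on one of three active sets (the unconstrained 2×2
normal-equation solution, or one of the two single-column projections), so
each half-step is solved exactly and the objective is monotone
non-increasing. Documents go to the left or right child by the larger of
their two H coefficients. Each frontier leaf's candidate split is scored by
a modified NDCG on the children's top-m term lists: terms shared with the
sibling get gain 0, unshared terms gain 1, discounted by 1/log₂(rank+1),
and the node score is the product of the two children's normalized DCGs —
1 for perfectly separated topics, 0 for identical ones. The leaf with the
highest score is split, until `max_leaves` is reached or no splittable leaf
remains, so the tree is detected from the data and need not be balanced.
The depth of a node is its "degree level" (root = 1); a theme whose node
moves deeper between years has lost prominence.

Trends are computed at tweet level (a topic's frequency is the number of
tweets containing the term, not token occurrences), thresholded at 35
tweets, normalized per 10,000 unique tweets, and classified as
increase / decrease / stable / new / absent between the two corpora.

## Worked example

Two synthetic World-AIDS-Day-style corpora (the later one twice the size,
as in real year-over-year collections), clustered and compared:

```r
library(tweettree)

spec14 <- synthetic_spec(n_docs = 800,  seed = 2014, label = "WAD2014")
spec15 <- synthetic_spec(n_docs = 1600, seed = 2015, label = "WAD2015")
y14 <- sample_corpus(spec14)
y15 <- sample_corpus(spec15)

y14$corpus
#> <tweet_corpus 'WAD2014': 1040 messages, 800 unique, reach 535228>

top_disseminators(y14$corpus, 3)
#>   username reach
#> 1 user0010 75541
#> 2 user0043 64700
#> 3 user0041 42135

uniq <- dedupe_unique(y14$corpus)$corpus
tdm  <- build_matrix(uniq, prep_options())
tdm
#> <term_doc_matrix: 811 terms x 800 documents, tfidf weighting>

tree <- hier_cluster(tdm, max_leaves = 4, seed = 1)
tree
#> <topic_tree: 7 nodes, 4 leaves, 800 documents>

planted <- y14$labels[match(tdm$doc_ids, y14$corpus$tweets$id)]
unlist(evaluate_recovery(flat_clusters(tree), planted))
#>       ari    purity
#> 0.9807208 0.9925000
```

The corpus print shows 1040 messages of which 800 are unique (the rest are
`RT @user:` duplicates) and a summed follower reach of 535,228 — the
audience-weighted dissemination proxy, which on real data runs into the
billions. The tree recovered the four planted topics almost exactly
(adjusted Rand index 0.98 against the ground-truth labels; purity 0.99).

Frequency trends between the two years, rates per 10,000 unique tweets:

```r
prep1 <- prep_options(ngram_max = 1, min_term_docfreq = 1, weighting = "tf")
fa <- frequency_table(uniq, prep1)                            # min_count = 35
fb <- frequency_table(dedupe_unique(y15$corpus)$corpus, prep1)
head(compare_periods(fa, fb, 800, 1600), 5)
#>           term freq_a freq_b rate_a  rate_b direction
#> 1 worldaidsdai    620   1281 7750.0 8006.25    stable
#> 2          hiv    395    852 4937.5 5325.00    stable
#> 3          aid    304    592 3800.0 3700.00    stable
#> 4       endaid    247    443 3087.5 2768.75    stable
#> 5      gettest    199    393 2487.5 2456.25    stable
```

Raw counts roughly double with the corpus, but the normalized rates are
flat — exactly what the `stable` classification should say when only the
collection volume changed. Terms are stems ("worldaidsdai" is the Porter
stem of the #WorldAIDSDay hashtag). `theme_depth_table()` then compares the
degree levels of codebook themes between the two years' trees, and
`run_pipeline()` executes all of the above from corpus files to a manifest
of artifacts.

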