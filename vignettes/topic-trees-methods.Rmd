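---
title: "Topic trees from tweet corpora: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic trees from tweet corpora: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweettree)
```

`tweettree` analyses corpora of short social-media documents collected at
two timepoints — the motivating design is a pair of single-day World AIDS
Day tweet collections a year apart — and asks two questions: *what topics
does the public tweet about, organized hierarchically*, and *how did each
topic's volume and prominence change between the timepoints*. This
vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was
genuinely open.

## The corpus model

A corpus is an ordered collection of tweets with id, text, timestamp,
username, message type (`unique` or `retweet`), follower count and
language tag. Two summary statistics drive reporting:

* **unique tweets** — messages that are not retweet duplicates;
* **reach** — the sum of follower counts over *all* messages. Each message
  is weighted by the posting account's audience, so reach is a
  dissemination proxy and routinely exceeds any real user count; the
  package deliberately calls it "reach" rather than "users".

Retweet deduplication works on *canonical text*: the leading
`RT @user:` prefix is stripped, whitespace is normalized and case is
folded. A message is kept as unique when its collector flag says `unique`
or when its canonical text is first-seen; every other message collapses
onto the first kept message with the same canonical text, so message
count is conserved (`sum(1 + retweet_counts)` equals the corpus size).
Canonical-text matching is the default because collector exports label
retweets inconsistently; `by = "flag"` trusts the flag alone. The
280-character limit is enforced as a warning, not a rejection, since
historical corpora mix 140- and 280-character eras.

## Text preparation

Each document is case-folded; URLs, `@`-mentions and a leading `RT`
marker are removed; hashtags are kept without `#` (they often carry the
topical signal in health campaigns); punctuation is stripped and
standalone numerals retained. Stopwords are removed *before* stemming,
using a standard English list plus the Twitter artifacts `rt`, `amp`,
`http`, `https`. Tokens are then stemmed with a faithful implementation
of the classic Porter (1980) affix-removal algorithm — including its
original behaviour of mapping a final `y` after a vowel-bearing stem to
`i` (`day → dai`), which modern revisions changed — and N-grams are
extracted over the *stemmed* tokens, so inflected variants of a phrase
collapse to one term. Word-level N-grams are used throughout; a
character-level mode is not implemented.

The term-document matrix defaults are the standard recipe for NMF
document clustering of short texts:

| parameter | default | why |
|---|---|---|
| `ngram_min..ngram_max` | 1..2 | bigrams capture campaign phrases ("fast track", "close the gap") without exploding the vocabulary |
| `min_term_docfreq` | 3 documents | single/double-occurrence terms are mostly typos and URLs shards |
| `weighting` | tf-idf, `c · log(n / df)` | down-weights campaign-wide ubiquitous terms; a term in every document vanishes and is pruned |
| `normalize_docs` | unit Euclidean column norm | makes long and short tweets comparable and is required for balanced NMF splits |

Documents whose column becomes all-zero after preparation are dropped and
reported, never silently lost.

## Rank-2 NMF and the topic tree

The hierarchy is built by recursive bisection. One split solves

$$\min_{W \ge 0,\, H \ge 0} \lVert A - W H \rVert_F^2,
\qquad W \in \mathbb{R}^{m \times 2},\ H \in \mathbb{R}^{2 \times n},$$

by alternating exact nonnegative least squares. The two-column structure
is what makes exactness cheap: for each column $a$ of $A$, the minimizer
of $\lVert W h - a \rVert_2$ over $h \ge 0$ lies on one of three candidate
active sets — the unconstrained $2 \times 2$ normal-equation solution when
it is nonnegative, else the better of the two single-column projections
$\max(0, w_j^\top a / \lVert w_j \rVert^2)$. Both half-steps (for $H$
column-wise, for $W$ through the transposed problem) are exact, so the
objective trace is non-increasing by construction; the package records it
per iteration and tests the monotonicity. Iteration stops when the
relative objective decrease falls below `tol` (default `1e-4`, suitable
for clustering; drive it to `1e-10` with a larger `max_iter` when
near-exact factorizations are needed) or after `max_iter` (default 200)
iterations. On return the columns of $W$ are unit-normalized with the
scale absorbed into $H$.

**Initialization.** $W$ is initialized by a deterministic NNDSVD-style
rule: the two leading singular directions of $A$ are computed by power
iteration started from the row-sum vector, the second direction is
replaced by whichever of its positive or negative parts carries more
mass, and seeded uniform noise of magnitude `1e-6` is added. Seeding two
random document columns was considered and rejected: position-based
sampling breaks the desirable property that permuting the documents
permutes the clustering (the power iteration and row sums are
order-independent, so the NNDSVD rule keeps it), and spectral starts are
markedly more reliable on tf-idf matrices whose columns all have norm 1.

**Document assignment.** Column $j$ goes to the left child when
$H_{1j} \ge H_{2j}$ (ties left, so the rule is total and deterministic);
the left child is the topic whose vector is the first column of $W$.

**Split scoring.** A candidate split is scored by comparing the two
children's top-`m_top` term lists (default 10) with a modified NDCG: a
term shared with the sibling has gain 0, an unshared term gain 1,
discounted by $1/\log_2(i+1)$ at rank $i$, normalized by the ideal DCG,
and the node score is the *product* of the two children's values — 1 for
perfectly separated children, 0 for identical ones. The exact gain
schedule is this package's concrete choice, and one detail matters in an
N-gram vocabulary: by default a term counts as shared when any of its
constituent words occurs among the sibling's constituent words. Matching
whole strings instead (`match = "exact"`) lets a child whose list is
padded with bigram variants of the sibling's head word score as
"perfectly separated", which rewards splits that subdivide a single topic
by token co-occurrence noise; constituent matching removes that failure
mode and coincides with exact matching on unigram lists.

**Greedy growth.** The tree starts at a root holding every document
(depth, or "degree level", 1). Each frontier leaf gets a trial split and
score, cached until the leaf itself changes; the highest-scoring leaf is
split (ties go to the earliest-created node), and growth stops at
`max_leaves` leaves or when no leaf is splittable — the structure is
detected from the data and need not be balanced. A trial split that would
give a child fewer than `min_node_docs` documents (default 5), or a
degenerate submatrix (fewer than two documents or two nonzero term rows),
marks the leaf *permanent* instead of splitting it; this is the outlier
guard that keeps tiny noise clusters from fragmenting the frontier.

## Trends and the theme codebook

A topic's frequency is defined at tweet level: the number of tweets whose
prepared term set contains the term, so repetition within one tweet does
not inflate it. The frequency table keeps terms tweeted at least
`min_count = 35` times. Because the two corpora typically differ in size,
`compare_periods()` defaults to *normalized* mode: rates per 10,000 unique
tweets, classified `increase`/`decrease` outside a relative
`stable_band` (default 0.25, since qualitative "moderate decline" bands
are not standardized) and `stable` inside it; `raw` mode applies the same
band to counts for comparability with volume-based reports. Terms present
in only one table are `new` or `absent`.

The packaged codebook maps 19 themes to the six UNAIDS core action
principles and the three 2030-commitment areas (Prevention, Treatment or
Care, Support). Keywords go through the same tokenize–stopword–stem
pipeline as corpus text, with multiword keywords joined into bigram
terms. `apply_codebook()` assigns the theme with the largest keyword
intersection (at least `min_overlap`), and flags ties for manual review
rather than guessing — automated keyword matching deliberately does not
replace expert qualitative coding, and the packaged keyword sets cover
only published example words per theme, so users analysing real corpora
should extend them. `theme_depth_table()` compares each assigned theme's
degree level between two trees; a positive delta means the theme moved
deeper — less prominent — in the later tree. Degree levels count the root
as 1.

## The synthetic corpus generator

Real single-day tweet collections are rarely redistributable, so the
generator plants a known structure that exercises every pipeline stage:

* `n_topics` leaf topics on a balanced binary tree, drawn uniformly per
  document;
* per-topic categorical word distributions: `anchors_per_topic` anchor
  words (default 3) receiving `anchor_mass` (default 0.45) that have zero
  probability under every other topic, the rest of the mass on a shared
  Zipfian background vocabulary (exponent 1.07, 200 words, topped by a
  handful of realistic hashtag-style terms for readable demos);
* per-token mixing: `background_mix` (default 0.2) of tokens come from
  the background regardless of topic;
* document lengths Poisson(`doc_length_lambda = 12`) clipped to 3–24
  tokens so texts respect the 280-character limit;
* retweet duplication at `retweet_rate` (default 0.3): verbatim copies
  with an `RT @user:` prefix, inheriting the source's planted label;
* discretized log-normal follower counts (meanlog 4, sdlog 2), giving the
  heavy-tailed audience distribution that makes aggregate reach dwarf the
  corpus size, and timestamps inside a single-day window.

Everything is reproducible from one seed. `evaluate_recovery()` scores a
clustering against the planted labels with the adjusted Rand index and
cluster purity, both invariant to label permutation.

An optional `node_mass` parameter plants extra words shared by sibling
subtrees. Its default is 0 for a reason worth recording: high-weight
vocabulary shared between sibling topics suppresses the mNDCG score of
exactly the splits that separate those siblings, while within-topic
splits keep scoring well, so the greedy priority can invert. This is a
real limitation of top-term-overlap split scoring, and the parameter is
kept as a stress condition for studying it rather than as part of the
standard generating process.

What the generator does *not* emulate: topic correlation through shared
non-anchor vocabulary beyond the background, bursty or viral cascades,
multilingual text, bot traffic, or any follower-network diffusion.
Passing the planted-recovery tests therefore shows the pipeline recovers
clean mixture structure; it does not certify performance on real corpora,
where topics overlap more and label noise has no ground truth.

## Problem sizes and determinism

The test suite validates the solver against a brute-force oracle on
200 random 6×2 instances, monotonicity on 50 random 50×40 matrices,
planted recovery at 1200 documents and 4 topics, and tree invariants over
randomized configurations of 100–220 documents — sizes chosen so the full
pipeline behaviour (dedupe → matrix → tree → trends) is exercised
end-to-end with comfortably reproducible margins. All randomness flows
from explicit integer seeds: generation from the spec seed, each node's
factorization from a seed fanned out deterministically from the tree
seed, so identical configuration and inputs yield byte-identical
artifacts (the pipeline manifest records every parameter and seed for
that purpose).

## Known limitations

* The split score looks only at top-term overlap; sibling topics that
  share their most prominent vocabulary can be kept merged past
  `max_leaves` (see `node_mass` above).
* Exact equivalence with other implementations of hierarchical rank-2
  NMF is not claimed: scoring schedules, outlier rules and stopping
  criteria differ across implementations, and this package documents its
  own choices instead.
* Keyword codebook assignment is a deterministic stand-in for expert
  coding; ties are surfaced, not resolved.
* Trend classification has no significance test — with single-day
  corpora the sampling unit is the collection day, and two days cannot
  support one; the stable band is an honest effect-size threshold
  instead.
* Language filtering trusts the collector's language tag; no detection
  is performed.
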