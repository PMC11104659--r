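---
title: "Mining craving mentions in recovery-forum posts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining craving mentions in recovery-forum posts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cravingminer analyses posts from online sobriety forums — communities
where people with alcohol-related problems describe their daily lives,
including episodes of craving (the strong desire to drink that is a key
relapse-associated symptom of alcohol use disorder). The package answers
three questions about such a corpus: which posts mention a craving, in
which contexts (places, company, emotions, times) distinct authors
mention them, and which broader themes the craving posts fall into.
Because public forum dumps cannot be redistributed and no labelled
craving corpus exists, the package ships a synthetic corpus generator
with complete ground truth; every stage of the pipeline is exercised and
scored against that truth.

```{r setup, eval = FALSE}
library(cravingminer)
```

## Corpus model and cleaning

A post is a forum submission: an id, an author, a title, a body, a UTC
timestamp, optionally a UTC offset, and optionally a sobriety badge
("author flair") counting days since the author's last drink. Posts are
read from JSON Lines (`read_posts()`), one submission object per line;
unparseable lines are counted and skipped rather than failing the run.
Cleaning (`clean_posts()`) drops posts whose body is a deletion sentinel
(`[deleted]`/`[removed]`, the convention of public forum dumps) and
posts whose combined title+body is shorter than 60 characters — too
short to describe a craving episode. The length rule counts raw
characters of the combined text, before any tokenisation, because it is
a rule about posts, not token streams. Titles are analysed together with
bodies throughout: forum titles often carry the key phrase ("3 weeks in
and craving hard"), and every downstream stage uses the same
title+space+body text, so counts are consistent across stages.

Preprocessing for the statistical models (`tokenize_posts()`) lowercases,
splits on any non-alphanumeric character, keeps tokens of length two or
more, removes a fixed 180-term English stopword list shipped with the
package, and lemmatises with a deterministic suffix-stripping rule table
(also shipped): plural `-s`/`-es`/`-ies`, `-ing` and `-ed`, with
consonant doubling undone (`quitting` to `quit`) and a minimum stem
length per rule so that, for example, `cravings` maps to `craving` while
`craving` itself is left intact (the `-ing` rule demands a five-letter
stem). Rules apply once per token, first match wins. A rule table rather
than a statistical lemmatiser keeps preprocessing fully reproducible,
testable by hand, and free of model downloads; the cost is that
irregular forms (`drank`, `worse`) are not normalised, which matters
little here because the lexicons enumerate the surface forms they need.

## Craving detection: lexicon, expansion, word-form pattern

Craving posts are found with a curated lexicon compiled into a word-form
pattern, not a supervised classifier — there is no labelled training
corpus to learn from. The six seed synonyms are *craving*, *trigger*,
*relapse*, *urge*, *desire* and *temptation*. The lexicon can be widened
by embedding expansion (`expand_lexicon()`): for each seed, the top-`k`
cosine neighbours above `min_score` join the list, optionally
intersected with a manual allowlist (curation). Defaults are `k = 10`
and `min_score = 0.35`; both are configuration keys, since the right
values depend on corpus size and embedding quality. On the synthetic
corpus, whose filler text is statistically random around the planted
terms, expansion necessarily admits noise neighbours — the tests
therefore score the seed lexicon, and the pipeline reports what the
expanded lexicon retrieves. On real corpora curation is the step that
keeps expansion honest.

`compile_pattern()` turns a lexicon into one case-insensitive regular
expression that matches a token whose stem is a lexicon term, allowing a
closed set of morphological prefixes (`re-`, `un-`, `non-`, `anti-`,
`pre-`, `de-`, `ex-`, `over-`, `self-`), inflectional suffixes (`-s`,
`-es`, `-ed`, `-d`, `-ing(s)`, `-er(s)`, `-ion(s)`, with final-consonant
doubling and e-drop, so `urging` and `relapsing` match), and membership
in hyphenated compounds (`alcohol-craving`). Matching is word-boundary
aware: a stem never matches as an interior substring of an unrelated
word, so a lexicon containing `bar` does not fire on `barely`. A closed
affix set was chosen over "any characters around the stem" precisely to
keep that guarantee. `filter_corpus()` applies the pattern and reports
the retrieval rate; on an empty corpus the rate is flagged undefined
rather than silently zero.

Evaluation (`evaluate_binary()`) scores predictions against a labelled
set with accuracy `(TP+TN)/N`, precision `TP/(TP+FP)` and recall
`TP/(TP+FN)`, computed from exact integer counts and rounded to four
decimals; an undefined ratio is reported as `NA`, never coerced to 0.

## Word embeddings

Similarity queries use skip-gram embeddings with negative sampling,
trained from scratch (`train_embeddings()`): for each (centre, context)
pair within a dynamic window (effective size uniform on 1..`window`),
the model pushes the pair's vectors together and `negatives` sampled
words (unigram^0.75 distribution) apart. Defaults: 100 dimensions,
window 5, 5 negatives, 5 epochs, initial learning rate 0.025 decayed
linearly. Training is single-threaded and deterministic given the seed —
reproducibility is worth more here than the speed of asynchronous
updates — and frequent-word subsampling is disabled for the same reason.
Similarities are cosines of the input vectors (the conventional choice,
fixed so results are stable), reported as percentages in
`similarity_report()`. Multiword lexicon terms (`living room`) can be
pre-joined into single tokens during preprocessing so they have
embeddings.

The generator `generate_synonym_corpus()` plants a pair of tokens used
interchangeably in identical contexts inside otherwise themed sentences;
a sound trainer must score the planted pair above the 95th percentile of
random pairs, which is exactly what the recovery tests assert.

## Craving contexts

Context analysis asks *how many distinct authors* mention each context,
not how many posts: one prolific author should not count twenty times.
`group_by_author()` concatenates each author's posts in timestamp order;
`match_contexts()` then matches 21 curated context term lists — 8
locations (home, university/school, work, restaurant/bar, party,
workout, supermarket, airport), 8 emotions (anxious/worried, sad,
stressed, tired, frustrated/angry, happy, proud, bored) and 5 social
categories (alone, friend(s), family, partner, colleague(s)) — at exact
word boundaries, with multiword terms matching as adjacent tokens.
Exact matching (not affix matching) is the default because the lists
already enumerate the inflections they intend (`working`, `worked`), and
affix matching would over-fire (`ex` occurs inside unrelated words).
Some terms belong to two lists deliberately (`wife` to family and
partner, `lonely` to sad and alone), so multi-category matches are
expected and asserted. `author_percentages()` reports matched authors
per category as a percentage to two decimals. Test-set evaluation
(`evaluate_contexts()`) is per post and per category, each category an
independent binary problem, because labelled sets are labelled post by
post. An optional extended registry adds substance (nicotine) and
mental-health (depression, anxiety) lists; those lists are this
package's own defaults, supplied for users who need those groups.

These percentages are co-occurrence statistics: a matched context is
evidence of association with craving mentions, not of causation.

## Temporal structure and sobriety badges

`temporal_profile()` bins posts by local hour (UTC shifted by the
per-post offset; posts without an offset are binned in UTC and counted
separately — how a real platform's local times would be recovered is
outside this package's scope, so the offset field is an explicit input),
by weekday and by month, and histograms the sobriety-badge day counts.
Posting about cravings decays roughly exponentially with days sober,
with spikes on milestone days (one month, 100 days, one year).
`flair_decay_fit()` estimates the decay rate as the negated slope of a
least-squares fit of log bin count on day, excluding milestone bins
(days 30, 31, 100, 365, 366 by default — the spike days and the
day-after bins that inherit mass) and weighting bins by their count.
The weighting is a numerical necessity, not a tuning knob: under Poisson
noise the log of a small count is strongly biased (a long tail of
single-post bins flattens the slope by ~15% at realistic sizes), and
count weights are the standard variance-stabilising correction. On
noiseless geometric counts the fit recovers the rate to machine
precision, milestone spikes leave it unchanged by construction, and on
20,000 simulated badge-wearers it recovers the generating rate within
ten percent.

## Topic model

Themes are clustered with latent Dirichlet allocation fitted by
collapsed Gibbs sampling (`lda_fit()`), the simplest sampler whose
bookkeeping can be verified exactly: every sweep resamples each token's
topic from `P(z=k) ∝ (n_dk + α)(n_kw + β)/(n_k + Vβ)`, and the
topic-word counts must always re-add to the corpus counts (asserted in
the tests). Point estimates of the topic-word matrix φ and
document-topic matrix θ average the smoothed count ratios over
post-burn-in samples (defaults: 500 sweeps, 300 burn-in, thinning 10;
fitting priors default to α = 50/K, β = 0.01, common heuristics). The
sampler uses its own xorshift generator, so fits are bit-reproducible
given the seed. Empty documents are tolerated (uniform θ row).

Held-out quality is measured by perplexity (`lda_perplexity()`):
`exp(−Σ log p(w|d)/N)` with `p(w|d) = Σ_k θ'_dk φ_kw` and θ′ obtained by
fold-in Gibbs sampling with φ fixed. For model selection
(`lda_select_k()`) the package uses *document-completion* scoring: θ′ is
estimated on alternate tokens of each validation document and the
likelihood evaluated on the remaining tokens. Whole-document fold-in
lets a model with surplus topics adapt θ′ to the very tokens being
scored, which rewards large K almost unconditionally; completion
scoring removes that advantage, and with a sparse document prior
(α = 0.1, appropriate for short posts touching few themes) the
validation minimum lands at the generating topic count on synthetic
corpora. A uniform φ over V words has perplexity exactly V under either
scoring — the closed form the tests pin down.

Topic quality is scored by NPMI coherence (`npmi_coherence()`): for each
pair of a topic's top words, `log(p_ij/(p_i p_j)) / (−log p_ij)` with
document-level co-occurrence probabilities and ε-smoothing
(`ε = 1e−12`) applied uniformly, averaged over pairs. Words always
co-occurring score exactly 1, independent words 0 (to first order in ε),
never co-occurring pairs approach −1. Documents, not sliding windows,
are the co-occurrence unit, matching the bag-of-words input.
`lda_summarize()` reports each topic's twelve highest-probability words
(ties broken lexicographically), its coherence, and its share of the
vocabulary — the percentage of distinct words whose highest-probability
topic it is, ties to the lowest index, so shares partition the
vocabulary and sum to 100. Topics are reported in decreasing coherence
order. The vocabulary-share definition is one reading of "percentage of
words belonging to a topic"; it was chosen because it is a partition
(no double counting) and is stable under relabelling.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure of a sobriety
forum at its documented scale: 70% of authors write exactly one post
(the rest 2 + geometric(0.5), putting ~15% at two posts); post length is
Poisson with mean 105 words (floored at 20 so every post survives
cleaning); 16% of posts carry a planted craving mention; filler text is
drawn from an LDA generative model over a synthetic vocabulary (w0001…),
so the same corpus exercises topic recovery and, being disjoint from all
lexicon terms, guarantees collision-free filter evaluation; craving
terms are planted as the bare stem, stem+"s", stem+"ing" or an
"alcohol-" compound (probabilities 0.55/0.15/0.15/0.15), exercising the
affix rules; per-author context planting follows per-category
probabilities defaulting to the author percentages such a forum
exhibits (work 49.6%, anxious 45.0%, home 39.0%, …, airport 2.1%);
posting hours are drawn with a 3:1 intensity ratio for the 13:00–23:00
local window; badges are present for 80% of authors with day counts
geometric (p = 0.02) times a 5× milestone weight on days 30/100/365.
Context injections sample only terms unique to their category within the
registry, so planted rates are exactly recoverable; deliberately shared
terms (`wife`) are exercised by dedicated fixtures instead. Every post
carries its ground-truth labels and topic mixture, and every author an
RNG stream keyed by (seed, author index), so corpora are reproducible
and stable under author-count changes.

What the generator does *not* emulate: grammar, discourse, markdown,
spelling variation, topic drift over time, author styles, or any
correlation between contexts and craving labels. Passing recovery tests
therefore shows the machinery is correct — patterns match what they
should, estimators recover planted parameters at the stated sizes — not
that the pipeline's real-corpus percentages are accurate; those depend
on lexicon curation and labelling, which is why the package mirrors the
test-set evaluation workflow.

## Numerical and design choices, in brief

* Exact integer arithmetic for all confusion-matrix ratios; four-decimal
  rounding only at the end; undefined ratios are `NA`.
* Percentages round half away from zero (the convention of printed
  reports).
* Ties: nearest-neighbour lists and top-word lists break score ties
  lexicographically; vocabulary argmax ties go to the lowest topic index.
* All samplers (Gibbs, fold-in, skip-gram) use dedicated deterministic
  RNGs seeded from user seeds via a string-keyed hash; R's global RNG is
  left untouched except where `set.seed` semantics are the documented
  interface.
* Problem sizes in the test-suite recovery checks: 5,000 authors
  (~8,000 posts) for filter and context recovery, 20,000 badge draws for
  the decay fit, topic corpora of 1,000 documents × 80 tokens over a
  200-term vocabulary for LDA recovery (five seeds), and ten 3,000-
  sentence corpora for embedding recovery. These sizes keep every
  recovery interval tight at desk scale.
* The pipeline entry point is `run_pipeline()`: stages communicate
  through plain-text artifacts (JSONL/CSV), a manifest records the seed
  and the MD5 of every artifact, reruns are byte-identical, a failing
  stage leaves a `<stage>.failed` marker, and unknown configuration keys
  are rejected before any stage runs.

## Known limitations

Lexicon filtering cannot see negation ("no cravings today" matches), and
the affix rules are English-specific. Context percentages inherit every
bias of the underlying forum (self-selection, anonymity, unverifiable
claims). The lemmatiser's rule table is deliberately small; rare
irregular inflections pass through unchanged. Embedding expansion on
small corpora is noisy and needs curation. None of the outputs are
causal claims about craving triggers.
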