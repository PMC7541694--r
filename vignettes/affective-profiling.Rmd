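---
title: "Embedding-based affective profiling of books: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based affective profiling of books}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentibook)
```

## The model

sentibook implements an unsupervised, multivariate sentiment analysis for
book-length texts built on a vector space model (VSM) of word meaning. A
word's affective value is not read off a human-rated word list; it is
computed geometrically, from the word's position in an embedding space
relative to a set of *label* words:

* **AAP (affective-aesthetic potential).** For a word with vector $w$, a
  set $P$ of positive labels and a set $N$ of negative labels,
  $$\mathrm{AAP}(w) \;=\; \frac{1}{|P|}\sum_{p \in P}\cos(w, p)
  \;-\; \frac{1}{|N|}\sum_{n \in N}\cos(w, n).$$
  As a difference of two means of cosines it lies in $[-2, 2]$. Higher
  values indicate a higher potential for positive affective and aesthetic
  responses. The canonical configuration uses 120 labels, two sets of 60;
  the label identities are corpus- and language-specific, so they are a
  required user input (`label_config()`), with small documented toy sets
  used throughout the tests.
* **Discrete emotion scores.** Six features — anger, disgust, fear,
  happiness, sadness, surprise — are each the plain cosine between the word
  vector and one single emotion label word, hence in $[-1, 1]$.
* **Sentence scores.** The sentence is the unit of analysis. A sentence's
  AAP is the unweighted mean of the word AAPs over its *content words*
  (nouns, verbs, adjectives, adverbs — the only tokens that are scored);
  POS-conditional means (AAP of nouns only, etc.) and per-emotion means are
  computed the same way. Each sentence also counts its positive
  ($\mathrm{AAP} > 0$) and negative ($\mathrm{AAP} < 0$) words; words with
  AAP exactly zero count as neither (the inequalities are strict by
  design).
* **Book and corpus profiles.** A book profile holds 18 features: six
  lexical statistics (sentences, words/sentence, tokens, types, mean word
  length in letters, type–token ratio) and twelve affective ones (AAP, four
  POS-conditional AAPs, six emotions, PNR). The **PNR**
  (positive/negative ratio) summarizes a positivity — "Pollyanna" — bias:
  values above 1 mean positive words outnumber negative ones.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| positive/negative label sets | `label_config()` | user-supplied | define the valence contrast; validated against the vocabulary before any scoring starts |
| lookup chain | `vector_lookup()` | exact → lower-case → lemma | deterministic; maximizes coverage without guessing |
| PNR mode | `aggregate_book(pnr_mode=)` | `"sum"` | ratio of summed counts is robust to sentences with zero negative words; `"mean"` (mean of per-sentence ratios) is the switchable alternative |
| smoothing window | `build_arc(window=)` | `max(3, round(0.1 n))`, odd | centered moving average; window 1 is the identity |
| histogram bins | `aap_histogram(bins=)` | 40 equal-width | half-open `[a,b)`, last bin closed |
| 4PL vs linear | `fit_valence_curve()` | 4PL | rating scales are bounded, so responses compress toward the ends |

Dispersions: book profiles report both sd and sem companions for every
sentence-aggregated affect feature, and corpus summaries report mean, sd
and sem across books, so either convention of a "±" column can be read off
directly. Sentence means enter book means unweighted by sentence length.

## Ingestion choices

Sentence segmentation is punctuation-driven with an abbreviation guard
list. A token is a maximal alphabetic run (internal hyphens allowed);
numerals and punctuation are tagged OTHER unconditionally. Types are
case-folded tokens; word length counts letters only. Token counts include
all word tokens, not just content words (punctuation excluded) — a
documented, configurable convention, since lexical statistics are
tokenizer-dependent.

POS tagging sits behind a minimal contract — a deterministic function from
word tokens to (lemma, POS class in {NOUN, VERB, ADJ, ADV, OTHER}) — with a
bundled lexicon-based tagger (`lexicon_tagger()`). This keeps the test
suite free of external binaries and makes every tagged corpus exactly
reproducible; adapters to richer external taggers can implement the same
contract.

Out-of-vocabulary content words are *not scorable*: excluded from every
mean, but counted, and summarized corpus-wide as the hit-rate (fraction of
content-word tokens whose vector resolves). An unresolvable *label* is
different — that is a configuration defect, and the pipeline refuses to
start.

## The synthetic study conditions

The generator (`synthetic_spec()` and friends) plants known structure so
every stage of the analysis has an oracle:

* **Embedding space.** One coordinate axis is the valence axis. Pool words
  sit at $\pm$`affect_strength` along it plus isotropic Gaussian noise
  (`noise_sd`). The 60 positive labels sit near the positive axis and each
  negative label is the *exact mirror image* of a positive label through
  the hyperplane orthogonal to the axis — so reflecting any word vector
  through that hyperplane negates its AAP exactly, not just in
  expectation. Six emotion labels are fixed random directions. Vectors are
  deliberately not unit-normalized, so the cosine's scale invariance is
  exercised by construction.
* **Books.** Each content-word slot draws from the positive pool with
  probability $p$, else the negative pool, giving the analytic oracle
  $\mathrm{PNR} \to p/(1-p)$. One function word is interleaved per three
  content words so content filtering does real work. POS classes are
  assigned round-robin over the pool vocabulary (word index mod 4) rather
  than per slot: the deterministic lexicon tagger requires one POS per
  surface form, and the vocabulary-level round-robin preserves the
  balanced POS marginal a slot-level scheme would aim for.
* **Ratings.** 90 words are sampled, their AAP pushed through a
  4-parameter logistic (defaults: asymptotes 1.5/4.5 inside the 5-point
  scale, slope 2, inflection 0), Gaussian noise added, and the result
  clipped to the scale. The default slope is deliberately gentle so the
  transition region is sampled by the bimodal synthetic AAP distribution
  and all four parameters stay identifiable from noise-free data.
  When a target population $R^2$ is requested, the noise sd is solved for
  with censored-normal moments, i.e. the calibration accounts for the
  clipping (naively using
  $\sigma^2 = \mathrm{Var}(\text{signal})(1-R^2)/R^2$ overshoots the
  realized $R^2$, because censoring at the scale ends truncates the
  noise).

Default conditions: dimension 50, vocabulary 1000, three books of 100
sentences with 8 content words each, `affect_strength` 1.0, `noise_sd`
0.2. The planted-bias recovery checks run at $p \in \{0.3, 0.5, 0.7\}$
with 200-sentence books, and the rating-recovery simulation uses 200
Monte-Carlo replicates of 90 words — sizes at which the binomial and CLT
error bands used by the tests are tight enough to be informative while the
whole suite stays quick.

What the generator does **not** emulate: Zipfian token frequencies, real
distributional-semantic geometry (polysemy, hubness, anisotropy),
discourse structure, or any correlation between a word's valence and its
frequency. Passing the planted-structure tests therefore demonstrates that
the pipeline's arithmetic and bookkeeping are right, not that any
particular real corpus shows a positivity bias.

## Numerical choices

* Cosines are clamped to $[-1, 1]$ against floating-point rounding; zero
  vectors raise an error rather than silently scoring 0.
* Label matrices are row-normalized once, so sentence scoring is two
  matrix–vector products per word set.
* 4PL fitting uses Levenberg–Marquardt least squares with data-driven
  starts (asymptotes from the rating range, inflection at the median
  predictor) and up to 10 deterministically jittered restarts taken only
  when a start fails; parameters are box-constrained, with the slope
  magnitude capped far beyond step-function resolution, because clipped,
  sparsely sampled transition regions otherwise let the slope diverge.
  $R^2 = 1 - SS_{res}/SS_{tot}$ for both model kinds (stated explicitly
  since nonlinear-$R^2$ conventions differ), and
  $R^2_{adj} = 1 - (1-R^2)(n-1)/(n-k-1)$.
* Arc gaps (sentences with no scorable word) are linearly interpolated
  before smoothing; edge gaps take the nearest defined value. The raw
  series keeps its NA gaps.
* Ties in the top-$k$ word extraction break alphabetically; duplicate
  embedding-file entries keep the first vector with a warning; degenerate
  inputs (empty book, all-OOV book, zero negative words) raise classed
  errors or flagged infinities, never silent drops.

## Limitations

The analysis is sufficiency-style: it predicts how a text *could* be
experienced given the geometry of one embedding space and one label
configuration. Scores from different embedding spaces are not directly
comparable; label-set choice is consequential and entirely the user's;
emotion scores do not exclude a label word occurring in the scored
sentence (documented, since the alternative is defensible); and
sentence-mean AAP ignores possible interactions between word classes
(e.g., adjective–noun dominance effects), which is exactly the kind of
question the POS-conditional features are exported to let users study.
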