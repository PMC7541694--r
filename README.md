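# sentibook

Embedding-based multivariate sentiment analysis for book-length texts.

Computational studies of literature keep finding a *Pollyanna effect*: human
language, including fiction, uses positive words more often than negative
ones. Testing that on whole books needs word-level affect scores that do not
depend on hand-curated rating lists. sentibook computes them geometrically,
from any word-embedding (vector space) model, and aggregates them into the
sentence-, book- and corpus-level statistics used in affective text
analytics: the tool is aimed at computational literary studies, digital
humanities and psycholinguistics work on positivity bias, emotional
narrative arcs and reader-response prediction.

## The model

For a content word with vector $w$, positive label set $P$ and negative
label set $N$ (canonically 60 + 60 label words), the
**affective-aesthetic potential** is

$$\mathrm{AAP}(w) = \tfrac{1}{|P|}\textstyle\sum_{p\in P}\cos(w,p)
 - \tfrac{1}{|N|}\textstyle\sum_{n\in N}\cos(w,n) \in [-2,2],$$

complemented by six **discrete-emotion scores** $\cos(w, \ell_e)$ for single
labels $\ell_e \in$ {anger, disgust, fear, happiness, sadness, surprise}.
Sentences average their content words (nouns, verbs, adjectives, adverbs
only, with POS-conditional means); books average their sentences and report
the **PNR**, the ratio of positive ($\mathrm{AAP}>0$) to negative
($\mathrm{AAP}<0$) word counts — above 1 means a positivity bias. Computed
AAP is cross-validated against human valence ratings with linear and
4-parameter-logistic fits (adjusted $R^2$).

A fully deterministic synthetic generator (embedding space with a planted
valence axis, books with a controllable positive-word proportion $p$,
ratings from a known logistic curve) makes the whole pipeline testable with
analytic oracles such as $\mathrm{PNR} \to p/(1-p)$.

## Worked example

Score a synthetic book with a planted 70% positive-word bias and
cross-validate ratings generated at a population R² of 0.68:

```r
library(sentibook)

spec  <- synthetic_spec(positive_proportion = 0.7, seed = 2026)
space <- generate_embedding_space(spec)
book  <- generate_book(spec, space, 1)

scored  <- score_book(book, space$labels, space$table)
profile <- aggregate_book(scored, compute_corpus_stats(book),
                          book_id = book$book_id)
round(profile[, c("aap", "aap_noun", "aap_adjective",
                  "happiness", "fear", "pnr")], 3)
#>     aap aap_noun aap_adjective happiness  fear   pnr
#> 1 0.384    0.352         0.313    -0.018 0.044  2.39

build_arc(scored)
#> <emotional_arc> aap over 100 sentences (window 11); 100.0% above zero

ratings <- generate_ratings(spec, space, target_r2 = 0.68)
fit_valence_curve(ratings$aap, ratings$data$rating, "logistic")
#> <valence_fit> logistic fit, n = 90: R2 = 0.6614, R2_adj = 0.6455
#>   lower   upper   slope    xmid
#>  1.7686  4.0064  3.6659 -0.1120
```

The book's mean sentence AAP (0.384) is positive, its PNR of 2.39 sits near
the analytic oracle `expected_pnr(0.7) = 7/3 ≈ 2.33`, and the whole smoothed
narrative arc lies above the zero line — the planted positivity bias is
recovered end to end. The logistic fit recovers an adjusted R² close to the
0.68 the rating noise was calibrated to.

Real corpora run through the same functions: `read_word_vectors()` for
word2vec/fastText `.vec` files, `read_label_config()` for the label sets,
`read_corpus()` + `lexicon_tagger()` for manifest-listed UTF-8 books, and
`run_pipeline()` for one-shot TSV/JSON reporting. A thin command-line
wrapper with `score` / `arc` / `validate` / `synth` subcommands is installed
at `inst/cli/sentibook.R`.

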