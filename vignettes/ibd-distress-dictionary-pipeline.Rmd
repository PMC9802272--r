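---
title: "Dictionary-based analysis of IBD and distress discourse on social media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based analysis of IBD and distress discourse on social media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdtopics)
```

## The problem

People living with inflammatory bowel disease (IBD) — chiefly Crohn's
disease and ulcerative colitis — discuss their illness extensively on public
social media, and a substantial share of that discourse is distress-related:
fear of flares, treatment struggles, social stigma. Characterizing *which*
aspects of the disease co-occur with expressed distress requires classifying
tens of thousands of short, informal posts, a scale at which manual coding
alone is impractical. The standard instrument in health infodemiology for
this task is the term-based computational dictionary: curated keyword lists
per construct, applied to normalized text, validated against human coders.

`ibdtopics` implements that full workflow as a reusable package: corpus
ingestion and cleaning, a distress lexicon filter, classification into eight
non-mutually-exclusive IBD topics (*symptoms*, *medication*, *nutrition*,
*procedures*, *marijuana*, *stigma*, *ostomy*, *intimacy*) with
false-positive phrase elimination, intercoder reliability, topic
co-occurrence network analysis, and descriptive reporting. Because real
platform corpora are not redistributable, the package also ships a seeded
synthetic corpus generator with gold labels, so every stage is testable end
to end without any download.

## Text normalization and matching semantics

All matching operates on a normalized token stream: text is lower-cased,
URLs are replaced by a sentinel token, apostrophes are stripped within words
("Crohn's" → "crohns") and tokens are maximal alphanumeric runs. Each token
retains its character span in the original text, which is what makes
span-level false-positive suppression possible.

Three match modes exist, and which one applies where is a deliberate design
choice rather than an implementation accident:

* **Relevance keywords** match as *substrings* of the joined normalized
  text. The umbrella keyword "crohn" must catch "crohns", "crohnsdisease"
  and hashtag compounds; an exact-token rule would silently miss most
  mentions.
* **Distress unigrams and topic terms** match as *exact tokens*. A
  substring rule here would let short terms fire inside unrelated words
  ("scared" in "scaredy-cat" is the mild case; "pot" inside "potato" is the
  fatal one). Hashtag-compound coverage is recovered selectively through
  per-entry `substring_terms` overrides.
* **Phrases** (distress bigrams, exclusion contexts, false-positive
  entries, multi-word topic terms) match as *consecutive* normalized
  tokens. "Word co-occurrence" is read as adjacency; gappy matching would
  make suppression spans ill-defined.

## Cleaning rules

The cleaning stage mirrors standard practice for platform archive dumps:
posts must contain at least one IBD keyword and no exclusion-context phrase
(the classic traps being *Investor's Business Daily* and animal IBD
diagnoses); Twitter retweets are removed using the metadata flag when
present and the `"rt @"` prefix as a fallback; and same-user duplicates are
collapsed to the earliest-timestamped copy. Two choices here were open and
are resolved as follows: duplicates keep the *earliest* copy (the original,
under the usual reposting dynamics), and posts with an empty author field
are never deduplicated against each other — in anonymized corpora an empty
author is an unknown, not a shared identity. Every filter returns a report
satisfying `retained + removed = input`, and the retweet/dedup filters
commute on non-pathological corpora; both properties are enforced by tests.

## Topic classification and false-positive elimination

For each topic, all dictionary matches are collected with their spans. The
false-positive dictionary is then applied *per topic*: an FP phrase match
suppresses any topic match whose span overlaps it. A topic is assigned iff
at least one match survives. The canonical example: "tired" is a symptoms
term, but "I'm tired of explaining my disease" is not a symptoms post —
the FP phrase "tired of explaining" suppresses the match. If the same post
also mentions "constant diarrhea", symptoms survives through the
non-overlapping span.

Elimination could equally be implemented as a post-level veto (any FP
phrase occurrence drops the topic entirely). Both semantics are
implemented; span overlap is the default because it preserves genuine
co-mentions, and `fp_mode = "veto"` provides the stricter variant. The
package does not claim either as *the* historically used rule — published
descriptions of FP elimination rarely pin this down — but the default is
the one with the better failure mode.

## Reliability

Reliability uses Krippendorff's alpha at the nominal level, the only level
consistent with binary present/absent topic codes, in the
coincidence-matrix formulation: every unit with `m ≥ 2` non-missing labels
contributes each ordered pair of its values with weight `1/(m − 1)`;
`α = 1 − D_o/D_e` with observed disagreement from the off-diagonal
coincidence mass and expected disagreement from category marginals. This
handles missing labels and any number of coders, including a "computer"
coder for human-vs-machine comparison after adjudication. When only one
category occurs, `D_e = 0` and alpha is reported as undefined (with a
warning) rather than 1 — reporting perfect reliability on a degenerate
sample would overstate what was measured. Percent agreement is provided
for the complete two-coder case only. The implementation is tested against
an independent brute-force pair-enumeration oracle to `1e-12` on hundreds
of small random matrices.

The validation sampler reproduces the purposive design used to validate
dictionary classifiers: per topic, a seeded without-replacement draw of 60
classifier-positive and 60 classifier-negative posts (8 × 120 = 960 stratum
draws). A post drawn for several strata appears once in the aggregated
sample but is recorded in every stratum ledger. The seed is an explicit
plan parameter so draws are reproducible.

Per-topic reliability is computed as eight separate binary matrices and
summarized by mean and range, matching the conventional reporting style
for multi-topic coding studies.

## Co-occurrence network

Only posts with two or more topics contribute to the network; each such
post adds 1 to every unordered pair of its topics, so total edge weight
equals `Σ_p C(k_p, 2)` — an identity checked on random inputs. Centrality
is node *strength* (weighted degree, the sum of incident edge weights).
Degree-based centrality language from directed-network analysis cannot
apply literally to symmetric co-occurrence edges, so strength is the
interpretation used here, with an unweighted-degree variant behind a flag.
Ties in rankings break lexicographically. Export formats are GraphML and
DOT (via igraph, with node `strength` and edge `weight` attributes) and a
weight-sorted edge-list CSV, plus the 8 × 8 co-occurrence matrix.

## Descriptive reporting

The summary report reproduces the shape of standard corpus-characteristics
tables: users and posts-per-user (M ± SD), hyperlink counts, post types,
subreddit and hashtag rankings, per-topic prevalence, and the
single/multi-topic distribution. Two conventions matter and are validated
against a published table of printed integers shipped with the package:

* **Percentages** are computed from stored integer counts, rounded half-up
  to whole percent, with nonzero proportions that round to 0 rendered
  `"<1%"`. This pair of rules reproduces every printed topic percentage in
  the reference tables from their integer numerators and denominators.
* **Means and SDs** are reported to 2 decimals; SD defaults to the sample
  (n − 1) convention, switchable to population.

One known inconsistency in the reference tables is documented rather than
asserted: the printed Reddit mean of 2.12 posts/user is not derivable from
the printed counts (40 625 / 18 891 = 2.15), while the Twitter pair
(40 306 / 20 665 = 1.95) is consistent and is the one used in tests.

## The synthetic generator

The pipeline is purely lexical, so the generator emulates lexical structure
only: it does not attempt realistic prose, user networks, or timestamp
dynamics beyond a monotone sequence. Each post is assembled from an IBD
opener phrase, one signal term per gold topic, a distress marker iff the
gold distress flag is set, an optional false-positive trap phrase
(independent of gold labels), and neutral filler; Twitter posts respect the
280-character limit, falling back to a compact token form and erroring if
the mandatory planted terms cannot fit. On top of the base posts it appends
the material the cleaning filters exist to remove: same-user duplicates,
retweet copies (flagged, or `"RT @user:"`-prefixed with text rebuilt from
the source's planted pieces so gold labels stay consistent), and off-topic
posts. In strict mode the per-topic signal vocabularies are pairwise
disjoint and disjoint from filler, distress markers and trap tokens, which
makes exact recovery (precision = recall = 1) a construction guarantee the
tests can assert; "confusable" mode leaks off-gold dictionary terms into
posts at a configurable rate to exercise precision < 1 paths.

Topic assignment has two modes because two natural calibration targets
cannot hold simultaneously. The default draws each topic independently
Bernoulli(prevalence), so every configured prevalence is an exact marginal
— this is the mode under which recovered prevalences are tested against
exact binomial 99% intervals. Supplying `multi_topic_mixing` (e.g.
`truncated_geometric(0.5)` over counts 0–4) instead draws the per-post
topic count from that distribution and fills it by prevalence-weighted
sampling without replacement — this is the mode under which the gold
topic-count distribution is tested by chi-square goodness of fit. A single
mode cannot deliver both configurable exact marginals and a configurable
count law, so the package makes the choice explicit rather than
approximate.

Default rates follow the published platform characteristics where they
exist (hashtag rate 0.31, hyperlink rates 0.04/0.25 for Reddit/Twitter,
per-topic prevalences from the published Reddit topic proportions) and
conservative small values where they do not (duplicates 2%, retweets 5%,
off-topic 2%, distress 80%). All randomness flows from the single config
seed through one RNG stream, and the caller's RNG state is restored, so
identical configs yield byte-identical corpora.

What passing tests on synthetic corpora do **not** show: recall against
real-world paraphrased or implied distress, robustness to misspellings,
slang drift, or sarcasm, and the adequacy of any particular keyword list.
The shipped lexicons are deliberately small, assembled from the vocabulary
this domain uses in print, and are a schema demonstration: substantive use
requires dropping in full curated dictionaries via the same YAML surface.

## Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to run in
about a minute on one core: strict-recovery corpora use 2000 posts per
platform (binomial 99% intervals at n = 2000 are ±2–3 percentage points at
the prevalences used, tight enough to detect calibration errors);
false-positive elimination uses 1000 posts per platform at trap rate 0.1;
alpha is checked against the oracle on hundreds of matrices up to 12 units
× 3 coders × 3 categories; network conservation on 500 random assignment
collections. These sizes are statements about statistical sufficiency, not
performance limits — the classifier handles the full-scale corpora (tens
of thousands of posts) in well under a minute.

## Limitations

* Dictionary classification is bounded by its lexicon: constructs carried
  by context rather than keywords (stigma, intimacy especially) are
  under-captured, and no stemming, spelling correction or embedding-based
  matching is attempted.
* The FP mechanism is phrase-based; it cannot suppress a spurious match
  that has no characteristic surrounding phrase.
* Alpha is reported without confidence intervals; a bootstrap is a natural
  extension point but is not implemented.
* The generator's text realism is minimal by design; it validates the
  pipeline's mechanics, not its field performance.
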