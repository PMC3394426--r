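---
title: "Methods: string similarity for abbreviation full-form clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: string similarity for abbreviation full-form clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbrsim)
```

## The clustering task

An *A-pair* is an (abbreviation, full form) record extracted from the
literature. Every two A-pairs sharing an abbreviation are candidates for
denoting the same concept; the gold answer is equality of their concept
identifiers (in real data, a thesaurus CUI; in synthetic data, the
generator's concept ID). The task is cast as a binary decision per
candidate pair: declare a match when a string similarity of the two full
forms passes a threshold. All of `abbrsim` is organized around that
decision — computing similarities, sweeping thresholds, and asking whether
chemical and non-chemical names should be thresholded separately.

The package assumes that full forms are short phrases (a few words), that
case carries no meaning (all measures lower-case internally), and that
gold concept labels are given. It does not attempt chemical named-entity
recognition: the chemical/non-chemical flag is an input column.

## The measures and their parameters

**Length-normalized edit distance.** Levenshtein distance divided by the
longer length, `d = ed/max(n1, n2)`, in [0, 1]. Two empty strings are
assigned distance 0 (the raw formula is 0/0, but the inputs are identical).
This is the only *distance* in the package; matches are predicted *below*
its threshold, strictly.

**Weighted edit distance.** Identical, except that inserting or deleting a
letter `c` in 'a'..'z' costs `w[c]`. Substitutions stay at cost 1, and so do
characters outside the 26 letters (spaces, hyphens), because the learned
weight vector is deliberately restricted to letter insertions/deletions.
With unit weights the reduction to the unweighted measure is exact,
bit-for-bit — the test suite asserts this, and it anchors the weight
optimizer's starting point. Weights above 1 are permitted (the search range
is configurable) but the [0, 1] default keeps the normalized value in
[0, 1].

**Monge-Elkan alignment score.** A local (Smith-Waterman-Gotoh) alignment
with character scores {5, 3, −3}: 5 for identical characters, 3 for
distinct characters sharing an equivalence class ({d,t}, {g,j}, {l,r},
{m,n}, {b,p,v}, {a,e,i,o,u}), −3 otherwise; a gap of length k costs
`g(k) = α + βk` with α = 5, β = 1. Two genuinely open choices had to be
settled here:

- *Direction.* The score is computed as a maximum-score alignment. The
  measure is used with "greater than" thresholds and must assign identical
  strings the top score, which a minimum-sum reading cannot do; alignment
  literature and the {5, 3, −3}/{5, 2, −5} matrices (rewarding matches,
  penalizing mismatches) only make sense under maximization.
- *Scaling.* The raw score is mapped to [0, 1] by dividing by
  `match_score · min(n1, n2)` — the score of a perfect alignment of the
  shorter string — and clipping negatives to 0. No other scaling constant
  reproduces s(s, s) = 1 without reference to the pair being scored. The
  divisor is part of `monge_elkan_params()` users can inspect; the
  alternative historical matrix {5, 2, −5} is available there too.

Empty strings are rejected (the scaling denominator would be 0).

**SoftTFIDF.** Token-level TF-IDF cosine similarity with approximate token
matching: token w of s1 participates when its best Jaro-Winkler partner in
s2 reaches the cutoff `a = 0.9`, contributing
`V(w, s1) · V(w*, s2) · s'(w, w*)` where `w*` is the maximizing partner.
`V` is the L2-normalized `log(TF + 1) · log(IDF)` weight (natural logs);
IDF is corpus size over document frequency, computed by
`build_corpus_stats()` over the set of full forms being clustered. Three
conventions close gaps in the usual formula:

- the second factor is evaluated at `w*` (the formula's `V(w, s2)` is
  undefined when w is not a token of s2);
- tokens unseen in the corpus statistics fall back to document frequency 1
  (maximal IDF) rather than erroring, so held-out strings can be scored;
- tokens occurring in *every* corpus string have IDF 1, hence log IDF = 0
  and zero weight; a string made only of such tokens scores 0 against
  everything, including itself. Self-similarity is exactly 1 otherwise.

**Bigram Dice coefficient.** `2·c_n/(n1 + n2)` with `c_n` the *multiset*
intersection count of length-n substrings (each occurrence can be matched
at most once, so repeated bigrams cannot inflate the count) and n = 2 by
default. The denominator uses the character lengths `n1 + n2`, under which
identical strings of length L score `2(L−1)/(2L) < 1`; this intentionally
asymmetric-looking convention is kept as the default because the
evaluation layer only compares scores of the same measure against one
threshold, where a monotone transformation is harmless. The conventional
n-gram-count denominator `2·c_n/((n1−n+1) + (n2−n+1))` is available via
`denominator = "ngram"`.

**Jaro and Jaro-Winkler.** Jaro counts characters matching within a window
of `min(n1, n2)/2` positions (the classical definition uses max; the min
form is kept as specified for this pipeline) and discounts transpositions
(T = half the number of matched characters appearing in different order,
the standard completion of the definition). Jaro-Winkler adds
`min(p, 4)/10 · (1 − jaro)` for a common prefix of length p; the cap at 4
is forced by the requirement that the score never exceed 1. These two are
not first-class clustering measures here; they serve as SoftTFIDF's
secondary similarity and are exported because they are useful on their own.

## The evaluation layer

`generate_candidates()` emits each abbreviation group's unordered pairs in
a deterministic sort order. `evaluate_at()` uses strict inequalities
(score < t for distances, > t for similarities). Precision is defined as 0
when nothing is predicted, recall as 0 without gold positives, F as 0 when
either component is 0.

Three threshold grids are offered: coarse (0–1 by 0.05), fine (0.900–0.995
by 0.005, for SoftTFIDF whose informative range is compressed near 1), and
*observed* — every distinct score in the data plus one sentinel beyond the
loosest score so the all-predicted operating point is reachable. Best-F
selection (`best_f_point()`) defaults to the observed grid: fixed grids
cannot contain the exact maximizing cutoffs, which in practice are ratios
of small integers realized by the data. Ties in F break toward the
stricter threshold; fixed-recall selection ties break toward the smaller
prefix. Both rules are arbitrary but deterministic, and documented so
results are exactly reproducible.

`threshold_at_recall()` implements the fixed-recall rule by scanning every
prefix of the best-score-first ranking (ties in score ordered by
abbreviation and full forms) and choosing the prefix whose recall is
*closest* to the target — not the first to reach it — mirroring how one
reads a threshold off a recall curve. `compare_split_vs_mixed()` reports
four rows: per-subset fixed-recall selections ("chemical", "other"), the
union of those two prediction sets evaluated against the pooled gold
("all"), and the single-threshold selection on the concatenated set
("mixed"). The "all" row's semantics were an open choice; the
union-of-predictions reading is implemented because it is exactly what a
deployed split-threshold matcher would output, and its recall is reported
alongside so nothing is hidden by the pooling.

## Learning the weight vector

`optimize_weights()` performs one pass of coordinate descent over the 26
letters in alphabetical order, starting from all-ones. For each letter it
tries every candidate value in `seq(0, 1, by = 0.1)` (plus the incumbent),
rescoring all pairs and taking the best F over the observed-threshold
sweep, then fixes the best value before moving on. Three choices were
genuinely open:

- *Search range [0, 1].* Costs above 1 would price an insertion above a
  substitution, which the minimization can always avoid; every useful
  weight is a discount. The upper bound is configurable for exploration.
- *Single pass, no convergence loop.* The procedure is a diagnostic of
  which letters the data treats as cheap, not a global optimizer; repeated
  passes would drift further into the (deliberately reproduced) optimism
  of optimizing and evaluating on the same pair set.
- *Per-candidate best-F.* Each candidate value is judged by its best F over
  thresholds rather than at a fixed threshold; this is the only reading
  that makes values comparable, since changing a weight rescales all
  scores.

Because the incumbent value is always among the candidates, the trace's
best F is non-decreasing by construction — the suite tests this invariant
rather than assuming it.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults define the study conditions: 300 chemical and
300 non-chemical concepts, on average 3 spelling variants per concept
(`1 + Poisson(2)`), collision groups of on average 3 concepts per
abbreviation, a 0.4 probability that a chemical concept has a one-edit
near-miss neighbor, and benign variant edits at per-character rate 0.05.
This yields roughly 10^3–10^4 candidate pairs per subset — a deliberate
miniature of real abbreviation corpora, which run one to two orders of
magnitude larger, sized so the whole experiment runs in seconds on one
CPU. The test suite
and the acceptance script state their own sizes: the oracle-equivalence
checks run exhaustively over all strings up to length 4 on a three-letter
alphabet plus ≥ 1000 random pairs per measure, and the ordinal findings
are evaluated over 10 generator seeds.

Chemical names are built from a small morpheme grammar (multiplier
prefixes, hydrocarbon stems, functional suffixes, connector words), so a
stem swap such as eth → meth reproduces the one-edit concept change that
motivates the whole analysis. Same-concept variants apply hyphen/space
swaps, plural inflection and at most one benign character insertion per
variant; for chemical names those insertions never touch compound tokens,
so variants cannot collide with near-miss neighbors. Non-chemical names
are drawn from a packaged biomedical word list; an optional
letter-frequency balancing mode tilts word sampling toward the chemical
letter profile, so aggregate letter frequencies of the two classes can be
made close while their sequence structure still differs.

The generator is honest about what it does not model. Real non-chemical
full forms include near-synonymous phrases with large surface distance and
unrelated phrases with coincidental overlap; here, non-chemical negatives
are independent random phrases and are therefore easier to separate than
in real data (the non-chemical best-F values on synthetic data approach 1,
where real corpora sit far lower). The qualitative contrasts — the
chemical subset demanding a stricter threshold, split thresholds beating a
shared one at fixed recall, planted noise letters receiving discounted
weights — are the claims the synthetic benchmark supports; absolute
precision/recall levels on it say nothing about real corpora. Digits and
Greek letters are excluded from generated names so the 26-letter weight
vector covers every weighted character.

## Degenerate inputs and numerical notes

- Empty strings: valid for the edit distances (distance = other length;
  0 for two empties), rejected by `monge_elkan()` (undefined scaling) and
  by `soft_tfidf()` (no tokens).
- Scores are compared with exact floating-point equality when grouping
  ties; tied scores only arise from identical arithmetic, so this is
  stable.
- `generate_dataset()` seeds R's RNG from `config$seed`; identical configs
  give byte-identical datasets, and `run_experiment()` likewise seeds from
  its config.
- Candidate generation, sweeps and prefix scans are all deterministic
  given the data; no step depends on hash or insertion order.

## Known limitations

- The weight optimizer evaluates on its training pairs, reproducing the
  original single-set protocol; learned weights are descriptive, not
  validated out-of-sample.
- SoftTFIDF is not exactly symmetric when the best token partner differs
  between directions; the suite asserts its self-similarity and
  non-negativity rather than symmetry.
- Pairwise match decisions are not closed into clusters (no transitive
  closure); conflicting pairwise decisions are left as-is.
- The morpheme grammar is a caricature of systematic nomenclature — rich
  enough to create one-edit concept changes, far too small to represent
  real naming conventions.
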