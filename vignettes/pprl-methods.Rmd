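---
title: "Parameter and threshold estimation for privacy-preserved record linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter and threshold estimation for privacy-preserved record linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprlink)
```

## The problem

Probabilistic record linkage decides, for a pair of person records, whether
they belong to the same individual by summing per-field evidence weights and
comparing the total against a threshold. Setting those weights and the
threshold normally relies on inspecting samples of the data. When the data
are privacy-preserved — every identifying field irreversibly encoded before
release — no such inspection is possible, so both the match parameters and
the threshold must be *estimated from the encoded records themselves*.
`pprlink` implements that estimation pipeline end to end, together with a
synthetic person-record generator so the whole chain can be validated
against a known truth.

## Encoding model

Each record's fields are encoded independently:

* **Bloom-filter fields** (first name, middle name, last name, address,
  suburb): the normalised value (uppercased, punctuation stripped,
  whitespace collapsed) is split into padded bigrams, and each bigram sets
  `num_hashes` bit positions obtained by keyed double hashing
  (`position_i = (g1 + i·g2) mod length_bits`, with `g1`, `g2` two
  independent keyed hashes of the bigram). Defaults: 1000 bits, 30 hashes,
  `q = 2`, padding on. Similar values share bigrams and therefore bits, so
  the Sørensen-Dice coefficient of two filters approximates the bigram
  overlap of the underlying strings.
* **Token fields** (sex, date-of-birth components, postcode): a keyed hash
  of the normalised value, compared for exact equality only.
* **Blocking keys**: surname Soundex + first initial (strategy A) and full
  date of birth + sex (strategy B), emitted as keyed hashes so the encoded
  file leaks no phonetic codes or dates. Candidate pairs are the union of
  within-block pairs over both strategies.

A missing or empty plaintext field is missing in the encoding — never an
all-zero filter — and a missing encoding propagates to the *missing*
comparison state. The keyed hash is a salted 64-bit FNV-1a with an avalanche
finalisation; it is non-cryptographic, but every hash in the pipeline is
keyed by the linkage secret, so the encodings cannot be regenerated by
dictionary attack without it.

## The comparison and scoring model

Pairs are scored under the Fellegi-Sunter model with conditional
independence across fields. For field $f$, $m_f$ is the probability that a
true-match pair agrees on $f$ and $u_f$ the probability that a non-match
pair does; the weights are

$$w^{a}_f = \log_2\frac{m_f}{u_f}, \qquad
  w^{d}_f = \log_2\frac{1-m_f}{1-u_f}.$$

Base-2 logs put the weights on the bits scale, matching the entropy
("discriminating power") convention in which an evenly split sex field
carries exactly 1.00 bit. A token field contributes $w^a_f$ or $w^d_f$; a
missing comparison contributes 0. A Bloom field with Dice similarity $s$
contributes through a Winkler-style partial-agreement curve: full $w^d_f$
below the lower anchor (default 0.8), rising linearly to the full $w^a_f$ at
$s = 1$. For *tabulation* (the EM input) the same similarity is discretised
into agree ($s \ge 0.8$) versus disagree; scoring stays continuous. The
bridge between the trinary tabulation and the continuous scoring is a
modelling choice: partial weights are applied at scoring only, and the
agree-cutoff is deliberately equal to the curve's lower anchor so the two
views coincide at the state boundary.

## Parameter estimation: EM with missing states

Every candidate pair yields a vector of per-field states
(agree/disagree/missing), and the counts of each of the at most $3^n$
combinations form the sufficient statistic. The classical two-class EM is
extended with explicit missing-state probabilities $m_{m,f}$ and $u_{m,f}$:
a true-match pair presents combination $j$ with probability

$$\mathrm{recall}_j = \prod_f
  \begin{cases} m_f & \text{agree} \\ 1 - m_f - m_{m,f} & \text{disagree} \\
  m_{m,f} & \text{missing} \end{cases}$$

and $\mathrm{fpr}_j$ analogously with $u$. The E-step computes the posterior
match probability of each combination,
$p_j = p\,\mathrm{recall}_j / (p\,\mathrm{recall}_j + (1-p)\,\mathrm{fpr}_j)$;
the M-step re-estimates every parameter as the corresponding share of the
posterior match (or non-match) mass. Starting values are $m = 0.8$,
$u = 0.1$, $m_m = u_m = 0.1$; the algorithm is insensitive to these so long
as $m$ starts above $u$. The starting match proportion is unspecified in
that tradition; `pprlink` uses $p = 0.01$ (configurable), a typical blocked
de-duplication starting point. Convergence is declared when the largest
absolute parameter change falls below `tol = 1e-6` (cap 1000 iterations),
and the observed-data log-likelihood
$\sum_j c_j \log\!\big(p\,\mathrm{recall}_j + (1-p)\,\mathrm{fpr}_j\big)$ is
recorded every iteration — on non-degenerate tables it is non-decreasing,
the classic EM guarantee, and the test suite asserts this.

**Why u comes from somewhere else.** The EM sees only blocked pairs, and
blocking removes almost all non-matches, biasing the EM's $u$ upward. The
adopted parameter set therefore keeps EM's $m$, $m_m$ and $p$ but replaces
$u$, $u_m$ with Jaro's frequency-based estimator computed on the *unblocked*
records: $u_f = \sum_v c_v(c_v-1) / \big(N_f(N_f-1)\big)$ over the value
counts of the $N_f$ records non-missing on $f$, and
$u_{m,f} = 1 - N_f(N_f-1)/\big(N(N-1)\big)$, the unordered-pair probability
that at least one value is missing. Two subtleties:

* The Jaro formula is *conditional* on both values being present. The EM
  model's $u$ is unconditional (missing is a separate state), so at adoption
  the conditional estimate is rescaled to $u_f (1 - u_{m,f})$. Without this
  the trinary probabilities can sum past 1 for low-cardinality fields with
  heavy missingness.
* For Bloom fields the value counts use exact-filter equality (identical
  plaintext implies identical filter). This ignores near-match agreement and
  so slightly underestimates $u$ for those fields — a documented
  conservatism.

The adopted set is used consistently everywhere downstream: weights, pair
scoring, and the recall/fpr of the threshold-estimation space.

## Threshold estimation

All $3^n$ combinations are enumerated — observed ones keep their counts,
unseen ones enter with count zero but non-zero recall/fpr — and each gets a
weight (sum of $w^a_f$ / $w^d_f$ / 0 by state). The estimated total true
matches is the final posterior mass $\sum_j p_j c_j$; the total comparison
space of a de-duplication is $N(N-1)/2$; false matches are the difference.
Apportioning these totals by recall/fpr gives per-combination
$TP_j$ and $FP_j$, and cumulative sums down the weight ordering give
predicted precision, recall and F-measure at every candidate threshold. The
selected threshold is the one with the highest predicted F-measure.

Numerical conventions, chosen where the procedure is otherwise
underdetermined:

* Candidate thresholds are the distinct real-valued combination weights
  (finer is never worse); `integer_thresholds = TRUE` gives the
  whole-number grid instead.
* Matching uses `score >= threshold` (flag `strict_gt` flips it), so the
  selected threshold is itself attainable.
* Ties in predicted F-measure break toward the *smaller* threshold,
  favouring recall.
* Above the top weight the selection is empty: precision is defined as 1,
  recall 0, F-measure 0.
* Weights within `1e-12` of a threshold count as at it: with symmetric
  parameters an (agree, disagree) pattern can have weight exactly zero in
  exact arithmetic but a few ulp off in floating point, and the tolerance
  keeps such mathematical ties tied.
* Parameters are clipped to `[1e-6, 1 - 1e-6]` at every M-step (rescaling
  `m + m_m` back under 1 if clipping broke it), so separable data — e.g. an
  error-free master file — produce large but finite weights.

## The synthetic generator

The generator emulates the structure of an administrative master file:
individuals are drawn with a configurable duplicate-count distribution
(default truncated geometric, $p = 0.4$, max 10, mean ≈ 2.5 records per
person, a typical hospital-admissions shape), and every identifying field is
drawn from a frequency table. The bundled tables are fully synthetic —
syllable-assembled names with shifted-Zipf rank weights tuned to realistic
skew (top surname ≈ 1% of mass, top given name ≈ 1.6%, top suburb ≈ 2%) —
so value-frequency structure, Soundex collisions and bigram overlap behave
like real name data without shipping any real person data. Addresses are
templated `number street-name street-type` strings; dates of birth use a
mildly non-uniform year distribution over 1920–2009 and uniform month/day.

Corruption applies, per (record, field) cell, two independent Bernoulli
draws at the configured error rate: one sets the cell to missing, the other
(when the first did not fire) applies an operator drawn from the configured
mix — keyboard-adjacent typo, single-edit misspelling, truncation of 1–3
trailing characters, or replacement from the field's table. Sex flips and
date components are redrawn/digit-substituted within valid ranges so values
stay parseable. Identifiers (`record_id`, `entity_id`) are never touched, so
the truth mapping of a corrupted file equals its master's.

What the generator does *not* emulate: family structure (shared surnames and
addresses within households), correlation between fields (suburb–postcode
consistency, sex-specific given names), seasonal or cohort effects in dates,
and real-world missingness patterns that concentrate in particular fields
(e.g. middle name) rather than falling uniformly. Passing tests therefore
demonstrate the estimators' correctness under conditional independence and
realistic marginal skew — not performance on any particular real
administrative collection.

## Problem sizes used in validation

The test suite validates the error-free end-to-end condition at 50,000
records (the package's chosen large-scale validation size; it runs in well
under a minute), quality-degradation and threshold-accuracy properties at
8,000 records across error rates {0, 1, 5, 10, 20}% with three generator
seeds, and EM parameter recovery on simulated 6-field state tables of
100,000 pairs across ten seeds. `scripts/acceptance.R` re-runs the 50,000
record error-free pipeline plus 5% and 10% corrupted variants at 20,000
records.

## Known limitations

* Conditional independence across fields is assumed throughout; correlated
  fields (suburb and postcode, say) double-count evidence.
* The EM needs a substantial match proportion among candidate pairs;
  blocked de-duplication of files with very few duplicates will fit poorly,
  and no small-sample safeguard beyond the degeneracy errors is provided.
* Frequency-based $u$ for Bloom fields undercounts near-match agreement
  (exact-filter equality only).
* No one-to-one assignment or transitive closure is applied to the matched
  pairs; the output is a pair list, not entity clusters.
* The Bloom encoding provides practical, keyed obfuscation but no formal
  privacy guarantee; cryptanalysis resistance of Bloom-filter PPRL is out of
  scope.
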