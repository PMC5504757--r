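# pprlink — probabilistic privacy-preserving record linkage

Health and administrative data collections often need to be linked (or
de-duplicated) at the person level without any party ever seeing names,
dates of birth or addresses. In privacy-preserving record linkage (PPRL)
the data custodian irreversibly encodes each identifying field — Bloom
filters for fuzzy fields, keyed hash tokens for exact ones — before release,
and all linkage runs on the encoded records.

That creates a hard problem: probabilistic linkage needs per-field match
parameters and a decision threshold, and the usual way to get them (clerical
inspection of samples) is impossible on encrypted data. **pprlink**
implements a complete estimation pipeline that works entirely on the encoded
records:

* **Fellegi-Sunter scoring.** Each field comparison contributes
  `w_agree = log2(m/u)` on agreement and `w_disagree = log2((1-m)/(1-u))` on
  disagreement, where `m` is the probability that records of the same person
  agree on the field and `u` the probability that records of different
  people do. Bloom-filter fields are compared with the Sørensen-Dice
  coefficient `2|A∩B| / (|A|+|B|)` and scored through a Winkler-style
  piecewise-linear partial-agreement curve; missing comparisons score zero.
* **Extended EM estimation.** Field comparisons are tabulated into
  agree/disagree/missing state combinations over the blocked candidate
  pairs, and an EM algorithm extended with explicit missing-state
  probabilities (`m_m`, `u_m`) estimates `m`, `u`, `m_m`, `u_m` and the
  match proportion `p` — no truth data involved. Because blocking starves
  the non-match class, the adopted `u` comes instead from Jaro's
  value-frequency estimator on the unblocked records.
* **Threshold estimation.** The full `3^n` field-state space is enumerated;
  each combination gets a weight, and the estimated true/false match totals
  are apportioned over it (`TP_j = TrueMatches · recall_j`,
  `FP_j = FalseMatches · fpr_j`), yielding a predicted
  precision/recall/F-measure at every candidate threshold. The threshold
  with the highest predicted F-measure is selected.
* **Synthetic data + evaluation.** A generator produces person datasets with
  a known duplicate structure and configurable error injection (missingness,
  typos, misspellings, truncation, replacement), so the whole pipeline is
  testable against ground truth; evaluation utilities compute
  precision/recall/F-measure and RMSE comparisons against a truth set.

## Worked example

De-duplicate a synthetic dataset of 5,000 records carrying 5% injected
error, estimating every parameter on the encrypted records only:

```r
library(pprlink)

master <- generate_master(generator_config(5000, seed = 42))
noisy  <- corrupt_dataset(master, corruption_config(0.05, seed = 43))

result <- pprl_deduplicate(noisy, bloom_params(secret_key = "demo-key"),
                           truth = truth_from_dataset(master))
result
#> <pprl_result>
#>   5000 records, 7,701 candidate pairs, 896 observed field-state combinations
#>   EM: 7 iterations (converged: TRUE), estimated match proportion p = 0.7433
#>   chosen threshold 16.0838 -> 5,719 matched pairs
#>   at threshold: precision 0.9998, recall 0.8444, F 0.9155 | best achievable F 0.9158
```

The EM ran on 7,701 blocked candidate pairs (out of 12.5M possible
comparisons) and estimated that 74% of them are true matches. The chosen
threshold of 16.08 — selected purely from the predicted quality curve,
without ever consulting the truth — achieves a realised F-measure of 0.9155,
against a best achievable 0.9158 had the threshold been tuned with full
knowledge of the truth. The fitted weights are on the usual bits scale:

```r
head(result$weights, 4)
#>                   field   w_agree w_disagree
#> first_name   first_name 7.9392903  -3.803626
#> middle_name middle_name 7.8431037  -2.699504
#> last_name     last_name 8.6034639  -3.614085
#> sex                 sex 0.8894327  -1.747144
```

A surname agreement is worth 8.6 bits of evidence; agreeing on sex only 0.9
(half the population agrees on it by chance, `u ≈ 0.5`).

Individual steps are exposed too — `encode_dataset()`, `candidate_pairs()`,
`compare_pairs()`, `tabulate_states()`, `run_em()`,
`estimate_u_frequencies()`, `quality_curve()`, `run_linkage()`,
`evaluate_linkage()` — and a command-line front end over them is installed
at `inst/cli/pprlink.R` (`generate`, `corrupt`, `encode`, `estimate`,
`threshold`, `link`, `evaluate`, `profile`, `sample`).

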