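# phenorbp

Phenotype-driven disease ranking over an HPO-like ontology. Given the set of
phenotypic abnormalities observed in a patient, `phenorbp` scores every
disease in an annotated corpus and returns a ranked differential — the task a
clinician faces when a rare hereditary disease must be recognised from its
clinical features alone.

## Who it is for

Bioinformaticians and method developers working with the Human Phenotype
Ontology (HPO) and disease–phenotype annotation corpora (e.g. OMIM-derived
HPOA files) who need either (a) a phenotype-to-disease ranking engine, or
(b) a reproducible benchmark harness comparing ranking methods on simulated
patients under realistic corruptions (noisy extra findings, imprecisely
recorded terms).

## The methods

**RelativeBestPair (RBP).** Let D(t) be the set of diseases annotated by
term t or any of its descendants and N_t = |D(t)|. The per-term disease
score is

    S(D | t) = 1/N_t  if D ∈ D(t),   0 otherwise

which sums to exactly 1 over the corpus for each term. A query
{t₁, …, tₙ} scores disease D as

    Sim(D | t₁…tₙ) = Σᵢ min(α, S(D | tᵢ)),   α = 0.01 by default

The cap α stops a single highly specific term (large 1/N_t) from dominating
the sum: nine terms that each agree with a disease at 0.005 should outweigh
one term that supports a different disease at 0.1.

**Seven classical measures** are provided for comparison — Resnik, Lin,
Jiang–Conrath, Relevance, information coefficient, graph IC (simGIC) and
Wang — each combined over term sets with the one-sided best-match average

    sim(Q → D) = (1/|Q|) Σ_{t₁∈Q} max_{t₂∈D} sim(t₁, t₂)

Information content is IC(t) = −log(N_t / N) in natural-log units.
Tied disease scores receive the average of the ranks their block spans.

**Patient simulator.** From disease profiles with per-phenotype frequencies,
each phenotype is kept with probability equal to its frequency (redrawn
until ≥ 3 survive). Corruptions: *noise* adds ⌈n/2⌉ annotated terms
unrelated to the true disease; *imprecision* replaces each term with a
uniformly chosen proper ancestor (root excluded); *noise+imprecise* applies
imprecision first, then noise.

## Worked example

```r
library(phenorbp)
set.seed(42)
ont <- gen_ontology(n_terms = 80, max_parents = 2)
ann <- gen_annotations(ont, n_diseases = 10, terms_per_disease = c(4, 6),
                       freq_range = c(0.6, 1))
idx <- build_index(ont, ann$direct)

cohort <- generate_cohort(ann$profiles, ont, idx, per_disease = 5,
                          variant = "clean", seed = 7)
cohort[[1]]
#> phen_patient OMIM:600001_p01 [clean] true disease OMIM:600001: T:0060, T:0028, T:0053, T:0076

head(rank_diseases(idx, ont, cohort[[1]]$terms, method = "rbp"), 3)
#>       disease score rank
#> 1 OMIM:600001  0.04  1.0
#> 2 OMIM:600006  0.01  3.5
#> 3 OMIM:600008  0.01  3.5
```

The true disease matches all four query terms, each capped at α = 0.01
(score 0.04, rank 1); the runners-up match one term each and tie at the
average of ranks 2–5. Corrupting the same cohorts shows the expected
degradation of top-1 recovery (out of 50 patients):

```r
for (v in c("clean", "noise", "imprecise", "noise+imprecise")) {
  ch <- generate_cohort(ann$profiles, ont, idx, per_disease = 5,
                        variant = v, seed = 7)
  ev <- evaluate_cohort(ch, idx, ont, method = "rbp")
  cat(sprintf("%-16s top-1 %2d/50\n", v, ev$topk[["1"]]))
}
#> clean            top-1 50/50
#> noise            top-1 46/50
#> imprecise        top-1  4/50
#> noise+imprecise  top-1  2/50
```

Noise barely hurts RBP (unrelated terms add at most α to wrong diseases),
while imprecision hurts most (ancestor terms support many diseases at once).

Real data plug in the same way: `parse_obo("hp.obo")`,
`parse_annotations("phenotype.hpoa", ont)` (both HPOA dialects are
auto-detected, OMIM namespace by default), then `build_index()` and
`rank_diseases()`. A thin command-line front end with `rank`, `simulate`
and `benchmark` subcommands is installed at `inst/scripts/phenorbp`.

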