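---
title: "Ranking diseases from phenotype queries: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking diseases from phenotype queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorbp)
```

## The problem

A patient presents with a handful of phenotypic abnormalities, each encoded
as a term of an ontology whose terms are linked to more general terms by
`is_a` edges (a rooted DAG, possibly with multiple parents per term).
Diseases are annotated with the terms they are known to exhibit. The task is
to order all diseases in the corpus by how well they explain the query term
set. Two families of methods are implemented: the RelativeBestPair score,
which works directly on disease sets, and seven classical term–term
similarity measures combined by a one-sided best-match average.

## Annotation propagation and information content

All corpus statistics derive from the *true-path rule*: a disease directly
annotated to a term is implicitly annotated to every ancestor of that term.
`build_index()` therefore computes, for every term t, the disease closure
D(t) — the diseases annotated by t or any descendant — and from its size
N_t the information content

$$\mathrm{IC}(t) = -\log\frac{N_t}{N}$$

with N the number of annotated diseases. IC is 0 at the root (whose closure
is the whole corpus) and non-decreasing from root to leaf.

**Log base.** Natural log. Ratio-type measures (Lin and its derivatives)
are base-invariant, but Resnik and Jiang–Conrath values are not, so the
base is pinned and recorded in the index (`log_base = "e"`) and in every
CLI output header.

## RelativeBestPair

The per-term disease score is $S(D\mid t) = 1/N_t$ if $D \in D(t)$ and 0
otherwise; for each term these scores form a unit mass spread evenly over
the diseases the term supports (they sum to exactly 1, a property the test
suite checks exhaustively). A query scores a disease as
$\sum_i \min(\alpha, S(D \mid t_i))$.

**α (default 0.01).** The cap on any single term's contribution. Without
it, one rare term annotating very few diseases can dominate the sum and
override the agreement of many common terms. In a large OMIM-scale corpus a
term annotates on the order of 150 diseases, giving typical per-term scores
near 1/150 ≈ 0.0067, so 0.01 caps only the unusually specific terms.
Values in roughly 0.001–0.03 behave similarly; α is exposed on every entry
point and validated to (0, 1]. Query terms with no annotated descendant
carry no information about any disease and contribute 0 (with a log
message) rather than aborting a clinical query.

## The classical measures

Resnik (IC of the most informative common ancestor, MICA), Lin,
Jiang–Conrath (similarity transform $1/(1+\mathrm{dist})$), Relevance,
information coefficient, graph IC and Wang. Three readings had to be fixed:

* **Graph IC.** The usual printed form of this measure is sometimes
  reproduced with identical numerator and denominator, which would make it
  constantly 1. It is implemented as the standard simGIC
  intersection-over-union of ancestor IC sums,
  $\sum_{t \in A(t_1)\cap A(t_2)} IC(t) \big/ \sum_{t \in A(t_1)\cup A(t_2)} IC(t)$,
  with ancestor sets inclusive of the terms themselves, and 0 when the
  union sum is 0 (both terms the root).
* **Wang.** S-values follow the max-product recursion with edge weight
  `w_e = 0.8` by default (configurable in (0,1)). The summation set in the
  similarity ratio is taken as the intersection of the *full* ancestor
  subgraphs (anchor terms included) so that self-similarity is exactly 1;
  the literal proper-ancestors-only reading, under which sim(t,t) < 1, is
  available via `strict = TRUE`.
* **Lin's 0/0.** When both terms are the root, IC(t₁)+IC(t₂) = 0 and Lin is
  defined as 0; Relevance and the information coefficient inherit this.

MICA ties (several common ancestors sharing the maximal IC) are broken by
lexicographically smallest term id, purely for reproducibility.

**Set combination.** The one-sided best-match average matches each *query*
term against its best counterpart in the disease's term set and averages
over the query only — the direction that fits diagnosis, where the patient
need not exhibit everything the disease can cause. The disease's term set
is its **direct** annotation set by default; matching against the closed
set (annotations plus all ancestors) is available via `use_closure = TRUE`.
Direct is the conventional reading and keeps the disease signature
specific; the closure variant systematically inflates similarity through
shallow shared ancestors. A disease with an empty term set scores 0 with a
warning rather than erroring, so full-corpus scans never abort.

## Ranking

Scores are sorted descending; tied diseases receive the mean of the integer
ranks their block spans, so rank sums are always M(M+1)/2 — a conservative
convention under which a two-way tie at the top (rank 1.5) does *not* count
as a top-1 hit. Secondary sort key is the disease id, making output
byte-for-byte reproducible.

## The patient simulator

`simulate_patient()` emulates case generation from disease profiles with
per-phenotype population frequencies: an integer is drawn uniformly on
{0, …, 99} and the phenotype is kept iff the draw is below frequency × 100,
so the keep probability equals the frequency exactly. (Drawing on the
closed range {0, …, 100} instead would bias every frequency by 1/101.) The
draw is repeated — never truncated or padded — until at least three
phenotypes survive (`min_terms = 3`), with a bounded retry budget so
degenerate profiles fail loudly.

**Imprecision** replaces each term with a uniformly chosen *proper*
ancestor, excluding the root: a term carried by every patient has no
discriminative value, and including it would only pad queries with dead
weight. A term whose only proper ancestor is the root is kept unchanged.
**Noise** adds ⌈n/2⌉ distinct terms ("half as many", rounded up for odd n;
`round_up = FALSE` gives ⌊n/2⌋) sampled uniformly from annotated, non-root
terms unrelated to the true disease. "Unrelated" defaults to: outside the
disease's closed annotation term set (its direct terms and all their
ancestors); a stricter mode also excludes ancestors of the present terms
and a looser mode excludes only direct annotations. When both corruptions
are requested, imprecision runs first and the noise count is taken from the
post-imprecision term count.

Each patient draws from its own RNG substream derived deterministically
from the cohort seed, so cohorts are reproducible and a patient's data do
not depend on how many patients were generated before it.

**What the generator does and does not emulate.** Synthetic ontologies are
random rooted DAGs (each term parented uniformly among earlier terms) and
disease profiles are uniform samples of non-root terms with independent
frequencies. Real ontologies have heavier-tailed branching and depth
distributions, and real disease phenotypes co-occur and cluster in organ
systems. Passing tests on these fixtures therefore establishes the
*correctness* of the scoring and simulation machinery and the *direction*
of method differences, not clinical performance on real HPO/OMIM corpora —
for that, feed real files through `parse_obo()` / `parse_annotations()`.

## Numerical and degenerate-input conventions

* OBO ingestion keeps only `is_a` edges (other relationship lines are
  counted and warned about), drops obsolete stanzas from the DAG while
  retaining their ids, maps `alt_id`s to their owners, and validates
  acyclicity, defined targets and a unique root (overridable for
  nonstandard files, which also disables root-reachability checks).
* Terms with N_t = 0 cannot carry IC; they raise an error when scored
  directly and are skipped (with a warning) inside set-level scoring.
* All validation errors name an offending element (a cycle member, the
  undefined target, the candidate roots).

## Problem sizes in the test suite

The suite verifies the implementation against independent brute-force
oracles (naive recursive DFS, direct formula transcriptions with no
caching) on 100 random DAGs of up to 40 terms and 10 diseases, checks
simulator calibration at 10⁴ replicates (keep rates within 3 binomial
standard errors), exercises planted-disease recovery on branch-separated
fixtures where every method must rank the true disease first, and checks
the qualitative degradation ordering (clean ≥ noise ≥ imprecision variants
for RBP top-1 recovery) on a 40-disease corpus with overlapping
annotations. These sizes were chosen to make the combinatorial oracles
exact and fast; the package itself scales to ontologies of ~10⁴ terms.

## Known limitations

* RelativeBestPair is a query-to-disease score; unlike the seven pairwise
  measures it defines no similarity between two individual terms.
* Scores are not calibrated probabilities; no significance computation is
  attached to a rank.
* Only `is_a` semantics are used; part-of and other relations are ignored.
* The simulator models phenotype presence independently per term — no
  co-occurrence, severity or onset structure.
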