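---
title: "Methods: S-locus homeolog analysis in allotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-locus homeolog analysis in allotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysloc)
```

# Overview

`polysloc` implements the computational side of a survey of
self-incompatibility (SI) haplogroups at the two homeologous *S*-loci of an
allotetraploid plant: nucleotide-distance estimation, identity-based
haplogroup classification, parental-origin assignment, neighbor-joining
phylogeny, exact F2 segregation models, categorical association statistics
and molecular-clock dating — with a seeded synthetic-data generator standing
in for field-collected sequences and genotypes. This vignette records the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic data do and do not establish.

# Distance estimation

`p_distance()` computes the raw mismatch proportion `p` and its
transition/transversion split `(P, Q)` on compared sites. Gap and `N`
handling is **pairwise deletion** by default (sites where either sequence is
gapped are dropped); a complete-deletion mode that masks columns gapped
anywhere in the alignment is available. Pairwise deletion is the common
default in distance-based *SRK* work; the choice matters only for ragged
alignments and is surfaced as an argument rather than fixed.

Corrections assume among other things equal base frequencies and
independence across sites:

* Jukes–Cantor: `d = -(3/4) log(1 - 4p/3)`, analytic
  `SE = sqrt(p(1-p) / (L (1 - 4p/3)^2))`; rejected ("saturated") at
  `p >= 0.75` where the logarithm leaves its domain.
* Kimura two-parameter: `d = -(1/2) log(1-2P-Q) - (1/4) log(1-2Q)`,
  rejected when either argument is non-positive.
* Nei–Gojobori (1986, unweighted): synonymous site fractions are counted per
  codon as one-step synonymous neighbors / 3; multi-difference codons are
  averaged over all minimal substitution pathways with equal weights,
  excluding pathways through stop codons (if every pathway is blocked, the
  average falls back to all pathways — a degenerate case that cannot arise
  between stop-free coding sequences at one or two differences). `Ks` and
  `Ka` are Jukes–Cantor corrections of `Sd/S` and `Nd/N`. Only the standard
  genetic code is supported; the code table is a package constant verified
  in the tests against an independent source.

Group divergence (`group_mean_divergence()`) averages all between-group
pairwise distances. For a singleton pair the analytic SE applies; for larger
groups the SE is a nonparametric bootstrap over alignment columns (default
1000 replicates), since pairwise distances sharing sequences are not
independent and no simple analytic form exists. Whether published error bars
of this kind are analytic or bootstrap is generally unstated, so both are
provided and agree within sampling error on matched cases.

Distances are reported to 6 decimals. Percent identity is reported rounded
to the nearest integer, the convention in the *SRK* literature, but
**classification** (next section) uses the unrounded value: the classified
quantity should not depend on a reporting convention.

# Haplogroup classification and parental origin

`classify_haplogroup()` assigns a query to the reference with maximal
percent identity `(1 - p) * 100` and calls `same_haplogroup` only when
identity is **strictly greater** than the threshold (default 98). The strict
inequality follows the field's "more than 98% identity" phrasing; identity
of exactly 98.0 is therefore a novel haplogroup. Ties between references are
broken by input order and flagged. Region selection (which part of the
*S*-domain to compare) is the caller's responsibility; published identity
percentages also depend on unstated gap conventions, so ours (pairwise
deletion) is documented rather than claimed identical.

`assign_origin()` calls the parent whose ortholog is closer in corrected
distance. Distances within an absolute tolerance of 1e-9 are `ambiguous`:
only exact ties are biologically uninterpretable, so the tolerance is
numerical, not statistical — a deliberate choice, since a statistical test
on overlapping SEs would conflate "close call" with "no call". When only one
parent's ortholog exists (as happens for newly discovered haplogroups), the
call is made from the single comparison and flagged `single_parent`.

# Neighbor joining

`neighbor_joining()` implements Saitou–Nei agglomeration with two pinned-down
conventions the generic implementations leave open:

* **Tie-breaking**: the Q-matrix minimum is taken at the lowest (row,
  column) index pair, making output deterministic across platforms.
* **Negative branch lengths**: clamped to zero with the deficit transferred
  to the sister branch, preserving the joined pair's distance (the common
  Kuhner–Felsenstein practice).

On additive matrices NJ is consistent; the tests verify exact recovery
(≤ 1e-9 in the path metric) on random trees, and agreement with an
independent implementation on perturbed matrices. `write_newick()` emits
branch lengths at 6 decimals and rejects labels containing Newick
metacharacters rather than attempting quoting. Bootstrap support values and
rooting are out of scope.

# Exact F2 segregation models

This is the package's bespoke core. A `locus_spec()` is disomic (F1 carries
2 copies; a gamete receives 1, each with probability 1/2) or tetrasomic (4
copies; a gamete receives a random unordered pair, probability 1/6 each —
random **chromosome** segregation; double reduction is excluded, as only
this model yields the classical 34/36 and 1225/1296 class fractions). The
four preset models are the unique simple F1 genotypes reproducing the
textbook fractions for two presence/absence markers:

```{r presets}
sapply(segregation_models(), function(m) {
  d <- f2_class_distribution(m)
  paste(d$num, attr(d, "den"), sep = "/")
})
```

All probabilities are exact integer fractions; distributions sum to exactly
one as integers, not within tolerance, and the tests check them against a
brute-force oracle that enumerates individually indexed chromosomes.

`chisq_gof()` derives expected counts from the exact fractions
(`95 × 1/4 = 23.75`, not a rounded 23.5 — only the exact value reproduces
the reference χ² of 2.62 on the 53/25/17/0 family). Classes with zero
expectation contribute nothing and are excluded from
`df = (#classes with E > 0) - 1`; this df convention reproduces the
reference p-values (0.27 at df 2, 0.031 at df 3). Observing a
zero-expectation class rejects the model outright (`χ² = ∞`). No continuity
correction is applied.

**A known discrepancy**: published χ² values of 92.73 and 102.84 for the two
tetrasomic models on the 53/25/17/0 family are not Pearson statistics — the
exact Pearson values are ≈ 282.7 and ≈ 292.5, as this package reports. Both
lead to the same conclusion (p below machine precision), but the printed
tetrasomic χ² values cannot be reproduced by any goodness-of-fit statistic
consistent with the printed expected counts, so `polysloc` reports the
Pearson values.

`fit_segregation()` ranks models by descending p-value and flags the top
model; this reproduces the disomic-allelic conclusion on the study family.

## Identifiability of the tetrasomic pair

The two tetrasomic models differ *only* through the `neither` class
(probability 0 vs 1/1296). In an F2 family of 95, that class is empty with
probability `(1295/1296)^95 ≈ 93%`. When it is empty, the two models'
Pearson statistics differ by ≈ 0.073 while their degrees of freedom differ
by one, and the χ² survival function at df 3 exceeds that at df 2 at
comparable statistics — so p-value ranking prefers the nonallelic variant in
every such family. Even the likelihood-ratio (Bayes-optimal) classifier
cannot tell the pair apart at this family size. Consequently, in the
parameter-recovery experiment (1000 seeded families per model at n = 95) the
disomic models and the tetrasomic-nonallelic model are recovered with large
majorities, while tetrasomic-allelic families are systematically called
tetrasomic-nonallelic. This is a property of the experimental design, not of
the implementation: distinguishing the two tetrasomic models at 95 plants
would require observing the 1-in-1296 class. The recovery test reports the
full confusion matrix so the asymmetry is visible rather than hidden.

# Association statistics

`build_contingency()` applies the survey's exclusion rules: accessions
carrying two or more of the queried markers (heterozygotes) or none of them
are excluded and counted. Note the rules are relative to the queried set —
querying a single marker retains dual-carriers that hold only one of the
queried symbols.

`cramers_v()` uses the Pearson χ² of independence,
`V = sqrt(χ² / (n (min(r,c) - 1)))`, with significance from Fisher's exact
test, as is conventional for sparse marker-by-cluster tables. Zero-margin
rows/columns are dropped with a warning. `fisher_exact()` implements the
probability-mass two-tailed convention (sum of table probabilities no
greater than the observed probability, relative tolerance 1e-7) — the
dominant convention, which reproduces the reference two-tailed p of 0.0476
on the 4/0 vs 1/5 table; the one-tailed p (0.0238) is the hypergeometric
tail in the direction of the observed deviation and is defined for 2×2
tables only. Larger tables are enumerated exactly when a cheap
composition-count bound says at most 1e7 tables share the margins, otherwise
by seeded Monte Carlo over `r2dtable` draws (with the +1/+1 estimator so the
p-value is never exactly 0).

`marker_frequencies()` counts over `2N` subgenome slots: a tetraploid
accession has two copies of each homeologous locus, so a single-marker
accession is scored homozygous (2 slots) and a dual-marker accession
contributes 1 slot per marker. This is the convention under which 23
homozygotes among 49 accessions give 46/98 = 46.9%.

`delta_k()` is Evanno's second-order summary, `ΔK = |L''(K)| / sd(L(K))`,
with the **sample** (n−1) standard deviation across runs; the original
formulation is ambiguous on this point, and the choice is documented rather
than asserted. ΔK is defined only for interior K with at least two runs per
K; zero spread yields a flagged `NA` rather than an infinite ΔK.

`score_cross()` encodes the pollination criteria: fewer than 20 penetrating
pollen tubes (or fewer than 10 under the stricter sensitivity flag) is
incompatible, as is a silique shorter than 5 mm. Exactly 20 tubes is scored
compatible: the source criteria ("<20" incompatible, ">20" compatible)
leave 20 undefined, and the boundary is resolved toward compatibility and
documented here.

# Divergence dating

`divergence_time()` computes `T = K / 2r` under a strict molecular clock.
Two rate presets are provided: a fossil-calibrated synonymous rate of
1.5e-8 ± 0.5e-8 per site per year (consumes `Ks`) and a
mutation-accumulation rate of 7.1e-9 ± 0.7e-9 per site per generation
(consumes total `K`; divided by a generation time, default 2 years,
configurable since annual accessions exist). Supplying the wrong divergence
type for a model is a validation error — the two calibrations are not
interchangeable. The published "±" terms are not defined as SE or 95%
half-widths; this package reads `rate ± term` directly as the 95% bounds,
the simplest faithful reading, and flags it here rather than asserting it as
the original authors' intent. CI propagation pairs the upper divergence
bound with the lower rate bound and vice versa; all lower bounds are
truncated at 0. Reproducing specific published year estimates requires the
original per-locus divergence tables, which are not bundled; the dating
machinery is validated on closed-form cases and algebraic properties
instead.

# Synthetic data

The generators emulate the statistical structure the analyses assume — they
are study-condition definitions, not tuning knobs:

* **Sequences** (`simulate_haplogroup_sequences()`): a star genealogy with
  haplogroup founders at branch `between/2` from a common ancestor and
  members at `within/2` from their founder, evolved by a per-site
  Jukes–Cantor process. Defaults: 5 haplogroups (the number surveyed), 1000
  sites (S-domain scale), between-divergence 0.10 substitutions/site
  (≈ 91% identity, the observed between-haplogroup ceiling) and
  within-divergence 0.01 (≈ 99% identity, above the 98% threshold). The JC
  process is chosen so the JC estimator is the matched estimator and
  parameter-recovery tests are exact in expectation. Requests whose expected
  p-distance reaches the 0.75 saturation asymptote (within 1e-6) are
  rejected. No recombination, indels, rate heterogeneity or coalescent
  genealogy — so passing tests demonstrate estimator correctness under the
  matched model, not robustness to model violation on real data.
* **Panels** (`simulate_panel()`): 49 accessions (the survey size) assigned
  round-robin to two clusters; one marker per subgenome drawn from
  cluster-specific frequencies; heterozygotes arise only on subgenome 1
  (mirroring the single observed dual-carrier) at rate 0.02 ≈ 1/49,
  configurable.
* **F2 families** (`simulate_f2()`): two independent gametes drawn from the
  exact per-locus gamete distribution, defaulting to 95 individuals under
  the disomic-allelic model.

All generators are deterministic given the seed (one seeded global PRNG per
invocation), and the tests verify byte-identical reruns plus binomial
convergence of every simulated frequency to its exact target.

# Pipeline

`run_pipeline()` chains the stages on a seeded bundle and writes aligned
FASTA, distance TSV, Newick, call tables, a segregation report, association
and dating JSON, and a provenance record (seed, parameters, package
version). TSV outputs are tab-separated UTF-8 with a header row. Reports are
byte-identical under identical config and seed. The dating stage dates the
divergence of panel members from their haplogroup founders, the only split
present in the synthetic bundle.

# Problem sizes

The shipped tests use alignments of 300–10,000 sites, panels up to 10,000
accessions, F2 families up to 1e6 individuals for rare-class convergence, 20
random 8-leaf trees for NJ consistency, 50 random locus configurations plus
the four presets for the enumeration oracle, and 1000 seeded families per
model for the recovery confusion matrix — sizes at which binomial 3-SE bounds
are tight enough to detect implementation errors while each file runs in
seconds.

# Known limitations

* Distances assume the JC/K2P model classes; no ML or gamma-rate distances.
* NJ only; no ML/Bayesian trees, no bootstrap supports.
* Tetrasomic models exclude double reduction (no chromatid segregation).
* Bayesian clustering itself is out of scope; cluster assignments are
  consumed as input and only the ΔK summary is computed.
* The strict-clock dating inherits every caveat of a constant substitution
  rate.
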