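---
title: "Methods: MLSA population structure with mlsapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLSA population structure with mlsapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsapop)
```

## The data model

An MLSA dataset is a set of haploid isolates typed at *l* loci.  Each locus
has an allele catalog: distinct aligned sequences receive dense 1-based
indices in order of first appearance, and an isolate's *allelic profile* is
its vector of *l* allele indices.  Identical profiles define a *sequence
type* (ST).  Exact string identity defines an allele: missing characters
(`N`, `-`) are never imputed, so two sequences differing only at a missing
position are distinct alleles.  This is the strictest reading of
"each different allele gets a number" and avoids any inference step;
datasets with substantial missing data should resolve ambiguities upstream.

All downstream statistics use pairwise deletion of `N`/`-`: a site is
compared for a pair of sequences only if both have a proper base there.
Nucleotide diversity is the raw p-distance averaged over unordered pairs
(denominator `choose(n, 2)`), with no multiple-hit correction — at the
within-species divergences this package targets (well under 1%), corrected
and uncorrected distances are practically identical, and the uncorrected
form matches what MLSA studies conventionally report.  Whether to exclude
gapped columns entirely (complete deletion) or per pair was a genuinely
open choice; pairwise deletion was chosen because it uses all comparable
data and is the package-wide missing-data rule.

Translation-level variability uses the bacterial genetic code (NCBI table
11) at frame offset 0 by default; both are configurable per locus because
amplicon reading frames are scheme-specific.  Codons containing any
missing or ambiguous character translate to missing and are ignored in the
variable-residue count.

## Gene diversity

Per-locus diversity is Nei's unbiased estimator
\(H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)\), the probability that two
isolates drawn *without replacement* carry different alleles.  The test
suite checks this identity by exhaustive enumeration.  Frequencies are
computed over isolates by default (so clonally expanded STs weigh by their
abundance); `st_mode = TRUE` recomputes over deduplicated STs for the
contrast used in epidemic-structure analysis.  The unbiased \(n/(n-1)\)
correction is not optional: it is pinned by a worked 7-isolate example in
the tests (a spring subpopulation whose published per-locus H values are
reproducible by hand), where the biased estimator gives visibly different
numbers.

## The standardized index of association

For every unordered pair of isolates, let K be the number of loci at which
their profiles differ.  Under free recombination the loci are independent,
so the variance of K is \(V_E = \sum_j h_j (1 - h_j)\), with \(h_j\) the
unbiased diversity of locus *j*.  The observed variance \(V_D\) exceeds
\(V_E\) when allelic states are associated across loci.  The package
reports

\[ I_A = V_D / V_E - 1, \qquad
   I_A^S = \frac{I_A}{l - 1}, \]

the standardized form being comparable across schemes with different locus
counts.  Two variance conventions had to be fixed:

* \(V_D\) is the *sample* variance of K (denominator
  \(\binom{n}{2} - 1\));
* \(h_j\) uses the unbiased \(n/(n-1)\) correction.

These are locked by a regression test on a 7-isolate subpopulation whose
mismatch distribution can be enumerated by hand (6 pairs at K = 0, 3 at
K = 1, 12 at K = 7): the locked conventions give \(I_A^S = 0.841\), while
the three biased alternatives give 0.805, 0.794 and 0.760.  Any future
change to either convention trips the test.

Significance is Monte-Carlo, not parametric: each locus column is permuted
independently across isolates, which preserves allele frequencies while
destroying between-locus association, and
\(P = (\#\{I^S_{A,\mathrm{perm}} \ge I^S_{A,\mathrm{obs}}\} + 1)/(B + 1)\)
(add-one corrected, so P is never 0).  The default is 1000 resamples;
the permutation null is itself tested for centering at zero.

Subsets with fewer than `min_n = 3` profiles return NA.  Published
analyses disagree on the minimum sample size for this statistic (some
report NA for 3-profile sets); the threshold is therefore a visible,
configurable argument rather than a hidden rule.

Degenerate inputs: if every locus is monomorphic, \(V_E = 0\) and the
index is undefined — the result carries NA and a warning, and the
significance test propagates NA rather than fabricating a P value.

## Single-locus variants

Two STs differing at exactly one locus form an SLV pair; enumeration is an
exhaustive \(O(n^2 l)\) scan, checked against an independent brute-force
reimplementation.  Each pair is classified by the Feil-style rule: the
variant is attributed to **recombination** if the two alleles differ by
more than one nucleotide, or differ by one nucleotide while *both* alleles
recur in two or more STs; it is attributed to **mutation** when the
alleles differ by one nucleotide and at least one of them is confined to a
single ST (the putative novel variant).  Two interpretive choices deserve
mention, because the verbal rule in the literature does not fully
determine them:

* *Polarity.*  The rule speaks of "the variant allele" but SLV pairs are
  unordered.  The confinement criterion above (M iff some allele is
  ST-unique) is the symmetric reading, and it reproduces all eleven
  published calls of the packaged dataset exactly, which is the strongest
  validation available without ancestral information.
* *"Observed multiple times".*  Evaluated at ST level, not isolate level:
  an allele carried by one 5-isolate ST counts once.  Isolate-level
  counting would let clonal expansion masquerade as recombination; both
  readings agree on the packaged dataset.

When neither sequences nor a distance entry resolve an allele pair the
call is UNKNOWN, a value rather than an error, so partially annotated
datasets still produce a report.

## Differentiation and isolation by distance

Pairwise F_ST uses Excoffier-style haplotypic AMOVA on the matrix of
pairwise nucleotide differences between concatenated loci, treating
difference counts as squared distances.  For populations of sizes
\(n_a, n_b\) (N total): \(\mathrm{SSD}_{\mathrm{within}}\) sums each
group's pairwise differences divided by its size,
\(\sigma^2_b = \mathrm{SSD}_{\mathrm{within}}/(N-2)\),
\(\sigma^2_a = (\mathrm{SSD}_{\mathrm{among}} - \sigma^2_b)/n'\) with
\(n' = N - (n_a^2 + n_b^2)/N\), and
\(F_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_b)\).  Negative estimates are
reported as computed, never clamped.  Two consequences worth knowing:

* For *balanced* designs the estimator reduces exactly to the classical
  \((\pi_b - \pi_w)/\pi_b\); the tests verify this identity to 1e-9.
* Two subpopulations that are literally duplicated heterogeneous multisets
  give \(F_{ST} = -1/(n-1)\), the well-known small-sample expectation of
  unbiased estimators under identity — not 0.  Exactly 0 arises when all
  sequences are identical (the 0/0 case, defined as 0).

Significance permutes individuals between the two subpopulations (sizes
preserved), add-one corrected.  Some papers describe this step as
"bootstrap resampling"; the procedure implemented (and the one standard
AMOVA software actually performs) is a permutation test.

The isolation-by-distance test is a Mantel-type matrix correlation:
Spearman's rho between the condensed upper triangles of a genetic and a
geographic distance matrix, with significance from random label
permutations of one matrix, reported as a percentage (the convention of
RELATE-style implementations).  A constant matrix has no rank variance, so
rho is NA with a warning.  The test suite cross-checks the statistic
against `vegan::mantel(method = "spearman")`.

## The packaged dataset

The fixture encodes a published hot-spring survey: 106 *Thermoanaerobacter
uzonensis* isolates from seven geothermal springs (two sampled in both
2005 and 2006), typed at eight protein-coding loci (gyrB, lepA, leuS,
pyrG, recA, recG, rplB, rpoB; 8003 nt concatenated), collapsing to 49 STs,
plus the nucleotide distances between the variant alleles of its 11 SLV
pairs.  Allele *sequences* are not packaged (they live in GenBank PopSet),
so per-locus S, π, variable-residue counts and the original pairwise F_ST
matrix are not reproducible from the package alone — those operations are
instead validated on synthetic data with brute-force oracles.  One source
ambiguity is preserved honestly: two multi-isolate Thermophilny STs span
the 2005 and 2006 samplings without a published per-year split, so those
18 isolates carry `year = NA` and per-year Thermophilny subsets are not
reconstructable (whole-spring subsets are).  The source tables also
disagree internally on one marginal count (18 vs 19 Thermophilny-2006
isolates); the fixture follows the tabulated value (19).

## The simulator

`simulate_mlsa()` is a forward-time haploid island model built to emulate
the study design the analyses assume: several demes (hot springs) of
constant size, `n_loci` loci, and per-generation events applied in a fixed
order — Wright–Fisher resampling within demes, then migration
(whole-individual replacement from another deme), then recombination
(per-locus allele replacement from a same-deme donor, a gene-conversion
caricature of homologous recombination), then infinite-alleles mutation.
Mutation is realized on sequences: each event applies
\(k \sim 1 + \mathrm{Geometric}(1/2)\) random substitutions to the parent
allele and rejects collisions with existing alleles, so allele calling,
nucleotide distances and π are all exercised end to end.  Event order
matters quantitatively and is fixed; determinism under a seed is tested
byte-for-byte on the written files.  Clonal expansion is applied at
sampling time (the modal sampled ST's count is multiplied by
`clone_boost`), which is precisely the mechanism that inflates
isolate-level but not ST-level \(I_A^S\).

Four canned regimes (`make_regimes()`) span the qualitative structures the
statistics distinguish.  Their parameters are chosen to mimic a realistic
single-study sampling effort — 25 isolates per deme, 8 loci, deme size 60,
120 generations, per-locus θ = 2Nμ ≈ 1.2 so each locus segregates a
handful of alleles, as in typical within-species MLSA data:

| regime | key settings | designed expectation |
|---|---|---|
| `clonal` | r = 0 | \(I_A^S\) > 0, significant |
| `panmictic_recombining` | r = 0.5, one deme | \(I_A^S \approx 0\) |
| `epidemic` | r = 0.5, clone_boost = 6 | isolate-level > ST-level \(I_A^S\) |
| `island_low_migration` | 4 demes, m = 0.01 | high F_ST, decreasing in m |

What the simulator does *not* emulate: selection, spatially explicit
dispersal, varying deme sizes, coalescent-scale locus lengths, sequencing
error, and real mutational spectra.  Passing calibration tests therefore
demonstrates that the statistics respond correctly to known mutation /
recombination / migration / expansion signals — not that any particular
real dataset satisfies the model's assumptions.

## Problem sizes and runtime choices

The test suite runs the calibration checks at sizes chosen to give stable
qualitative outcomes in a couple of minutes on one core: 20 simulator
seeds per regime for the linkage signatures (with 199-resample permutation
tests), 20 seeds × 3 migration rates for the F_ST monotonicity rank check,
500 replicate Mantel runs at 199 permutations for null calibration, and
brute-force oracle comparisons on 20 × 100 nt alignments.  Larger sizes
sharpen the same conclusions but do not change them.

## Known limitations

* The SLV R/M rule is an interpretation of a two-sentence verbal rule;
  it is validated against one published call set, not proven unique.
* AMOVA F_ST assumes haplotypic (sequence-difference) input; the
  frequency-only variant some software offers is not implemented.
* \(I_A^S\) has no analytic small-sample distribution here — significance
  is always Monte-Carlo, so P values have resolution 1/(B+1).
* The Mantel test inherits the usual caveats on autocorrelated distance
  matrices; it tests association, not any parametric IBD model.
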