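# mlsapop

Population-structure analysis for haploid (bacterial/archaeal) multilocus
sequence data in R.

Microbial population studies routinely type tens to hundreds of isolates at
a handful of housekeeping loci (MLSA/MLST) and then ask three questions:
how much allelic diversity is there, are alleles at different loci
associated (i.e. is the population clonal, freely recombining, or an
"epidemic" mixture of the two), and are subpopulations from different sites
genetically differentiated?  `mlsapop` implements that analysis chain for
population geneticists and microbial ecologists:

- **Allele calling and sequence typing** — distinct aligned sequences per
  locus become dense 1-based allele indices; identical eight-locus profiles
  become sequence types (STs).
- **Diversity** — segregating sites *S*, nucleotide diversity *π*
  (pairwise deletion p-distance), variable amino-acid residues, and Nei's
  unbiased gene diversity *H* = (n/(n−1))(1 − Σ pᵢ²).
- **Linkage** — the standardized index of association
  *Iˢₐ* = (V_D/V_E − 1)/(l − 1), where V_D is the sample variance of the
  pairwise locus-mismatch counts and V_E = Σⱼ hⱼ(1 − hⱼ) its expectation
  under free recombination, with Monte-Carlo significance from per-locus
  allele permutation.  *Iˢₐ* ≈ 0 in a freely recombining population and
  > 0 under linkage disequilibrium; comparing the isolate-level and
  ST-level values diagnoses epidemic structure.
- **Single-locus variants (SLVs)** — ST pairs differing at exactly one
  locus, classified Feil-style as recombination (R: multiple nucleotide
  differences, or a 1-nt difference where both alleles recur in several
  STs) or point mutation (M: a 1-nt difference where an allele is confined
  to a single ST).
- **Differentiation** — pairwise F_ST between subpopulations via
  Excoffier-style haplotypic AMOVA on pairwise sequence differences, with
  permutation significance, and a Spearman Mantel test for isolation by
  distance.
- **Simulation** — a forward-time Wright–Fisher, multi-deme, haploid
  simulator (infinite-alleles mutation realized on sequences, allele-swap
  recombination, migration, sampling-time clonal expansion) so every stage
  can be tested end to end with known truth.

The package ships the published *Thermoanaerobacter uzonensis* hot-spring
survey (106 isolates, 49 STs, 8 protein-coding loci, Uzon Caldera,
Kamchatka) as a built-in fixture; `uzon_repro()` recomputes that study's
entire summary surface and compares it to the published numbers.

## Worked example

```r
library(mlsapop)

fx <- load_uzon_fixture()       # 106 isolates, 49 STs, 8 loci
print(epidemic_contrast(fx$isolates))
#> Index of association (all isolates): n = 106 profiles, 8 loci
#>   V_D = 2.4430  V_E = 1.5283  I_A = 0.5986  I_SA = 0.086
#> Index of association (unique STs): n = 49 profiles, 8 loci
#>   V_D = 1.7557  V_E = 1.4648  I_A = 0.1987  I_SA = 0.028
#> Drop (isolate-level minus ST-level): 0.057
```

The isolate-level index (0.086) is well above zero — alleles are
non-randomly associated — but most of the signal vanishes when each ST is
counted once (0.028): the classic signature of an epidemic population
structure, where a recombining background coexists with recently expanded
clones.

```r
print(slv_report(fx$sequence_types, fx$catalogs))
#> Single-locus variants: 11 pairs (10 same-spring)
#>    st_a st_b variant_locus allele_a allele_b same_spring nt_diff call
#> 1    14   18          pyrG       13       14        TRUE      10    R
#> ...
#> Calls: R = 7, M = 4, unknown = 0
```

Seven of the eleven SLV pairs are attributed to homologous recombination
and four to point mutation; ten of the eleven involve STs from the same
hot spring.

`Rscript inst/scripts/uzon-repro.R` prints the full computed-vs-published
comparison table and exits non-zero on any mismatch.

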