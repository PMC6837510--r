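---
title: "Methods: comparative mitogenomics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoclade)
```

mitoclade implements the analysis stages of a comparative mitogenomics study
of a recently diverged species cluster — consensus assembly merging, genome
characterization, divergence profiling, per-gene selection estimates, and
strict-clock dating — together with a simulator that generates the kind of
data those stages consume. This vignette is the package's account of the
underlying models, the defaults, and the choices made where the design was
genuinely open.

## The study system the simulator emulates

Animal mitochondrial genomes are small (~14.9 kb here), circular, AT-rich,
non-recombining, and carry a conserved complement of 37 genes: 13
protein-coding genes (PCGs) of the oxidative-phosphorylation machinery, 22
tRNAs and 2 rRNAs, distributed 23 on the heavy (+) and 14 on the light (−)
strand, plus an AT-rich control region. In closely related *Drosophila*-like
clusters the PCGs evolve under strong purifying selection: per-gene dN/dS
(ω) is of order 0.003–0.060, with *ATP8* and *ND2* the least constrained and
*COI* the most.

The simulator's defaults are fixed to these conditions:

* **Architecture** (`default_gene_architecture()`): 37 genes +
  1 control-region feature in the *Drosophila* gene order and orientation,
  realistic per-gene lengths, total 14,892 bp (within the 14,885–14,904 bp
  range typical of short-read mitogenome assemblies that truncate the
  control region; the 150 bp control feature reflects that truncation).
* **Composition**: ancestral A+T fraction 0.765, drawn i.i.d. with A/T and
  G/C equiprobable within their class. Stop-codon rejection inside PCGs
  shifts realized AT down by well under one percentage point.
* **Clock**: neutral rate μ = 6.2×10⁻⁷ substitutions/site/year, the
  empirical *Drosophila* mitochondrial pedigree rate commonly used as a
  strict-clock prior.
* **Chronogram** (`default_chronogram()`): six ingroup tips in two clades —
  (`Dbuz`, (`DkoeA`, `DkoeB`)) and (`Dant`, (`Dbor`, `Dser`)) — with crown
  age 2.11 Myr, splits at 1.5, 0.9, 0.31 and 0.05 Myr, and an outgroup
  `Dmoj` at 10.63 Myr. The 0.9 Myr age of the `Dant` split is a modeling
  choice (the clade is younger than its sister clade and radiated within the
  last 1 Myr); all ages are overridable, and `age_scale` rescales the whole
  tree.
* **Selection**: per-gene ω defaults spanning 0.003–0.060
  (`default_omega()`).

### The substitution mechanism and its closed form

Along each branch, every site receives at most one substitution proposal
with the Jukes–Cantor net-change probability

$$p = \tfrac{3}{4}\left(1 - e^{-\tfrac{4}{3} d}\right),$$

where *d* = μ × branch years × the site's codon-position multiplier
(default multipliers are 1,1,1: position-specific rate variation is left to
the ω mechanism). Proposals are uniform over the three alternative bases.
Inside PCGs, a proposal that changes the encoded amino acid is accepted with
probability ω(gene); silent proposals are always accepted; proposals that
create an internal stop codon (or turn the terminal stop into sense) are
rejected. This "ω-thinning" is not a full codon model, but it reproduces the
dN/dS signal with an analyzable mechanism: at four-fold degenerate third
positions every proposal is silent, so the realized divergence at those
sites follows the JC closed form *exactly*, which is what the simulator
calibration test checks (observed four-fold p-distance within 3 binomial
standard errors of the formula across ages 0.05–2.11 Myr).

Two caveats follow from the single-proposal design. First, branches are not
Markov-subdivisible: two consecutive branches of length *t* are not
statistically identical to one branch of length 2*t* for non-neutral sites
(for neutral sites they are, by the JC identity). Second, rejected
non-synonymous proposals do not accumulate, so the realized non-synonymous
net-change probability on a branch is ω·p(d) rather than p(ω·d); the two
agree to first order, and the discrepancy (≈3% at d = 0.05) is why the ω
recovery check is run at modest divergence (see below).

What the simulator does **not** model: indels (all genomes stay aligned by
construction — real assemblies need an aligner first), AT-biased mutation
(AT richness enters only through the ancestral composition; exchange rates
are equal so the JC oracle stays exact), rate heterogeneity across sites
beyond codon position, tRNA/rRNA structural constraint, and read-level
sequencing error (assembly corruption is applied at the consensus-sequence
level). Passing tests therefore demonstrate correctness of the *analysis
code* under these idealized conditions, not robustness to alignment error or
composition bias in real data.

## Consensus of per-coverage assemblies

`build_consensus()` merges multiple assemblies of the same genome, aligned
column by column, at a representation threshold τ (default 0.60):

* fractions are computed over **all** rows, so `N` and `-` count in the
  denominator but can never win — a heavily masked column honestly falls
  below threshold and emits `N`;
* the nucleotide with fraction ≥ τ wins; τ is restricted to (0.5, 1], which
  makes the winner unique and removes any need for tie-breaking;
* "not allowing gaps" is interpreted as: gaps can neither win nor appear in
  the output, and all-gap/N columns are dropped, so the consensus is always
  a gap-free sequence;
* when no nucleotide reaches τ the column is emitted as `N` — the method
  needs *some* defined symbol there, and `N` is the conservative choice.

Raising τ can only convert resolved columns into `N`, never the reverse
(threshold monotonicity), and with ≥5 replicates at ≤1% per-site error the
60% consensus recovers the true genome at ≥99.9% of unmasked positions.

## Characterization

`composition_summary()` reports length, GC%, N% and per-class coverage
percentages (a position covered by two classes counts once in each;
intergenic = covered by no gene and not control region — the control region
is deliberately *not* folded into "intergenic", so class percentages need
not total 100). `codon_usage()` reports per-gene and pooled codon counts
(terminal stops excluded, codons containing `N`/`-` skipped and tallied),
RSCU (observed count / family-uniform expectation), and a usage-bias index

$$B = \sum_{\text{families}} \frac{n_f}{n} \cdot
      \frac{\sum_{c \in f} |f_c - 1/k_f|}{2(1 - 1/k_f)} \in [0, 1],$$

which is 0 iff usage is uniform within every used family and 1 when each
family uses a single codon. Several different bias statistics circulate in
the literature; B is defined explicitly here, and RSCU is reported alongside
so any downstream comparison is transparent.

## Divergence

`p_distance()` divides nucleotide differences by nucleotides compared under
**pairwise deletion** (only the positions missing in that pair are
excluded), matching the per-pair denominator of the p-distance definition;
`group_mean_p()` further divides by the number of pairwise comparisons.
`window_profile()` reads "window 500 bp with an overlap of 100 bp"
literally: consecutive windows share 100 bp, so the step is 400 bp. The
caption-style parameters are ambiguous (overlap could mean step); both
readings are reachable since `window` and `overlap` are free parameters. A
final truncated window is kept iff it is at least half a window long, so
ragged tails do not produce high-variance endpoints.

`classify_sites()` classifies gap/N-free columns as conserved,
parsimony-informative (≥2 states each in ≥2 rows), singleton (exactly one
deviating row), or other-variable; any column containing `-` or `N` is
"unclassified" rather than silently dropped, which is also why published
class counts for real alignments may not total the alignment length.

## Codon evolution: four-fold sites and NG86

`extract_fourfold()` takes a codon-aligned PCG alignment and extracts a
third-position column iff *every* taxon has a degeneracy-4 codon there, the
first two codon positions are identical across all taxa, and no taxon has a
gap/N in the codon. The cross-taxon conservation requirement is stricter
than some implementations but guarantees that every extracted site is
genuinely silent in all taxa; since degeneracy at position 3 depends only on
positions 1–2, the extracted sites evolve neutrally under the simulator.

`ng86_pair()` implements Nei–Gojobori (1986) counting: potential synonymous
sites per codon are the per-position fractions of synonymous
single-nucleotide changes (changes to stops count as non-synonymous;
S + N = 3L), averaged between the two sequences; observed differences are
averaged over all minimal mutational pathways between differing codons with
equal weights, excluding pathways through stop codons (if every pathway is
blocked — impossible under code table 5 for valid codon pairs — all are
used). Proportions are Jukes–Cantor corrected; p ≥ 3/4 flags saturation and
the distance is undefined rather than clamped. `gene_dnds()` summarizes a
gene alignment as the mean pairwise dN and mean pairwise dS over
non-saturated pairs (with the exclusion count reported) and ω as their
ratio; a ratio of means is preferred to a mean of ratios because pairwise ω
is unstable when pairwise dS is small.

NG86 with JC correction is a counting stand-in for likelihood codon models:
at the deep divergences of an outgroup comparison it underestimates dS (and
hence inflates ω ordering noise), so published ML per-gene values are
comparators for orientation, not exact targets. Within the simulator's
ingroup depths the estimator brackets the generator's ω: the recovery check
runs 20 replicates of a 1,500-codon gene at pairwise neutral divergence
d = 0.05 — chosen so the ω·p(d)/p(ω d) thinning bias (~3%) is well inside
per-replicate sampling noise (~18–37%) — and applies a two-sided sign test
(count of estimates above ω_true within [3, 17], the ~0.3% binomial
acceptance region). For ω_true = 0 a sign test is degenerate (the estimator
is non-negative and essentially exact at zero), so the check is that the
mean estimate stays below 0.01.

## Dating

`jc_correct()` maps p-distances to substitutions/site. `nj_topology()` is
standard neighbor joining (via ape) rooted at the midpoint of the declared
outgroup's branch — only a single outgroup is used, mirroring the practice
of minimizing among-taxa rate variation at deep divergences.
`strict_clock_fit()` replaces Bayesian MCMC dating with a deterministic
least-squares fit: each internal node's unconstrained age is the mean of its
tip pairs' distances over 2μ; ages are then projected onto the
child ≤ parent order by pool-adjacent-violators on the tree (a violating
node is merged into its parent's block at the pair-count-weighted mean), so
the output is always ultrametric and never inverts a clade's age above its
ancestor's. With a root calibration the relative ages are kept, the root is
pinned, and the rate is re-estimated as a by-product — so calibrated and
uncalibrated fits agree exactly when the free root age happens to equal the
calibration. Saturated (p ≥ 3/4) distances abort dating with the offending
pairs listed rather than being clamped: at the default depths the outgroup
sits essentially at the saturation bound, which is why the package's own
end-to-end dating example runs at half depth (`age_scale = 0.5`) and uses
the outgroup only for rooting, not for the clock fit.

Two-taxon dating reduces to the analytic d/(2μ): a four-fold divergence of
0.062 at μ = 6.2×10⁻⁷/yr gives exactly 50,000 years.

## Problem sizes and numerical checks

The test-suite problem sizes are the package's own choices, selected so each
statistical check has adequate power at desk scale:

* Counting primitives (p-distance, site classes, degeneracy, NG86 Sd/Nd/S/N)
  are compared **exactly** against independent brute-force oracles on over
  1,000 randomized small instances.
* Consensus recovery and threshold monotonicity run on the full-size default
  genome with 5 replicates, 1% error, disjoint masks.
* Simulator calibration uses two-tip clades across ages 0.05–2.11 Myr (the
  deepest age gives p ≈ 0.73, inside but near the saturation bound — by the
  JC identity the check remains exact there).
* Clock-age recovery uses a 6-tip half-depth chronogram and 20,000
  simulated neutral sites per replicate (simulated with an independent JC
  site simulator, phangorn's `simSeq`, rather than the package's own
  generator). The site count matters: the youngest node (25 kyr at half
  depth) is estimated from a single tip pair, and at ~1,000 sites its
  binomial noise alone is ~19% relative — no estimator could place it within
  10% reliably — whereas at 20,000 sites all five node ages are recoverable
  within 10% in ≥18 of 20 replicates.
* Topology recovery runs 100 full-generator replicates at full depth; the
  ingroup bipartition is checked on the outgroup-rooted NJ tree of raw
  four-fold p-distances (raw, not corrected: NJ needs no correction and the
  outgroup's corrected distance would be undefined at these depths).

## Known limitations

* No indel or rearrangement evolution; all simulated genomes are trivially
  aligned, and alignment error — a real driver of divergence artifacts — is
  outside scope.
* The JC proposal process has no transition/transversion or AT bias;
  composition bias enters only via the ancestor.
* NG86 group estimates are means of pairwise estimates on a star-like
  weighting; no tree-aware counting or ML codon model is attempted.
* The strict-clock fit provides point ages only — no credible intervals,
  rate priors, or relaxed clocks.
* Single-pair nodes inherit the full binomial noise of their pair's
  distance; their fitted ages should be read with that in mind.
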