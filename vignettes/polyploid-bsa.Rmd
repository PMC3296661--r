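---
title: "Methods: polyploid SNP discovery and bulk frequency ratios"
author: "polyBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid SNP discovery and bulk frequency ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyBSA)
```

## The model

polyBSA analyses RNA-seq alignments of an allopolyploid against a
*collapsed* unigene reference: reads from both homoeologous genomes map
to the same consensus transcript. Three layers of polymorphism meet in
one pileup column:

1. **Inter-homoeologue polymorphisms (IHPs)** — fixed differences between
   the ancestral genomes, present in every variety. Under co-expression
   of both homoeologues they appear as a stable two-base mixture.
2. **Hemi-SNPs** — a varietal mutation on one homoeologue of one parent.
   The carrier parent shows a two-base mixture, the other parent a single
   base that is a member of that mixture. The allele private to the
   carrier is the *informative base*.
3. **Simple SNPs** — positions where each parent contributes one,
   different base (single-copy genes, or only one genome expressed).

The package assumes inbred, homozygous parental material: within each
genome a parent carries one allele, so a two-base call reflects
homoeologue mixing, not heterozygosity. A true diploid heterozygote
would be indistinguishable from a hemi-SNP; the method is designed for
material where that case does not arise.

### Consensus genotype calls

`call_genotypes()` uses an explicit count-based rule instead of a
probabilistic consensus: at a position with depth $d \ge$ `min_depth`,
base $b$ is an allele when

$$ n_b \ge \texttt{min\_allele\_reads} \quad\text{and}\quad
   n_b / d \ge \texttt{min\_allele\_fraction}, $$

with inclusive ties. One or two qualifying bases give a call (encoded as
an IUPAC character); zero or three or more give a no-call — three-base
mixtures usually mean collapsed paralogues and are never allowed into
SNP classification. Defaults: `min_depth = 8`, `min_allele_reads = 2`,
`min_allele_fraction = 0.2`. The depth threshold is the main operating
point: 8-fold gives the most candidates, 12- and 16-fold trade recall
for precision because both homoeologues must actually be sampled
(`prob_both_alleles_sampled()` quantifies this: 96.4% at 8-fold, 99.9%
at 16-fold for one read per allele).

The fraction rule matters statistically: at balanced mixing the minor
allele is Binomial$(d, 1/2)$ and the probability of dipping under 20% of
depth is $\sim 10^{-4}$ per site at $d \approx 50$ — small, but not zero
(see *Noise-free mode* below).

### Classification

`varietal_snp_scan()` intersects the two parental call sets and keeps
positions where the genotypes differ (the symmetric difference of the
SNP sets, restricted to positions callable in both parents):

| parent A | parent B | class   | informative base |
|----------|----------|---------|------------------|
| Y (C/T)  | Y (C/T)  | IHP     | —                |
| S (C/G)  | C        | hemi    | G, origin A      |
| T        | G        | simple  | see below        |
| S (C/G)  | T        | complex | —                |

Positions called in only one parent are excluded: with no cross-parent
evidence, a "difference" cannot be asserted. This is a deliberate,
conservative choice. "Complex" patterns (pair vs non-member singleton,
two different pairs) are side-reported but never emitted as markers.
Agreement with the *reference* base plays no role anywhere: the
reference is itself a consensus of co-assembled genomes, and a varietal
SNP is defined by the parents differing from each other.

For simple SNPs each parent's base is informative for its own bulk; the
stored record uses parent A's base with origin A, and the BFR
orientation rule makes the statistic symmetric, so nothing is lost by
the convention.

### Paralogue (SNP-density) filter

Collapsed paralogues masquerade as unigenes with implausibly many
varietal SNPs. `snp_density_filter()` computes per-unigene density as
$\text{SNPs} \times 1000 / \text{length\_bp}$ and removes the whole
unigene when density strictly exceeds `max_density` (default 5 SNPs/kb;
equality is retained). Unigenes are filtered independently of each
other.

### The bulk frequency ratio

Let $f_H, f_L$ be the informative-base frequencies in the high- and
low-phenotype bulks (counts over the full column depth by default; an
ACGT-only denominator is available via `denominator = "acgt"`). Then

$$ \mathrm{BFR} =
   \begin{cases} f_L / f_H & \text{origin = low-phenotype parent} \\
                 f_H / f_L & \text{origin = high-phenotype parent}
   \end{cases} $$

so enrichment of the correct parental allele in the matching bulk gives
BFR $> 1$ regardless of origin. A zero denominator is *excluded* — a
flagged record, not an error and not silently dropped — because at a
tightly linked marker the denominator frequency genuinely tends to zero
and the ratio diverges; excluded records are arguably the strongest
candidates but cannot be ranked. Screens: `passes_depth` requires
`min_depth` in both bulks; `passes_threshold` additionally requires a
non-excluded BFR $\ge$ `bfr_threshold` (default 3, inclusive).
`threshold_summary()` tabulates counts and percentages over the
depth-passing, non-excluded pool at cutoffs 2–10.

In a tetraploid the ceiling of the enriched-bulk frequency is 0.5 for a
hemi-SNP under balanced homoeologue expression (the non-informative
homoeologue always contributes the shared base) and 1.0 for a simple
SNP; expression skew moves the hemi ceiling accordingly
(`homoeologue_ratio` in the simulator).

With `one_per_unigene = TRUE` a single SNP per unigene is evaluated,
chosen as the one with the largest $\min(d_H, d_L)$, ties broken by
smallest position — a determinate rule that favours the best-measured
site.

## Coverage and design calculators

* `prob_read_sampled(d)` $= 1 - e^{-d}$: Poisson chance a position is
  sampled at mean fold-coverage $d$ (99.97% at 8-fold).
* `prob_both_alleles_sampled(d, r)` $= P(\mathrm{Pois}(d/2) \ge r)^2$:
  the total depth splits independently between the two alleles. At
  $r = 1$ this reproduces 99.93% (16-fold) and 96.37% (8-fold) exactly.
  At $r = 2$ the model gives 99.40% / 82.52%; figures sometimes quoted
  for this scenario (99.39% / 82.53%) differ in the final digit, so
  other approximations of the two-allele problem are evidently in
  circulation — the package asserts its own closed form.
* `expected_resolution(interval, lines)` and
  `marker_density(interval, markers)` are the interval quotients
  (12.2 cM / 27 lines = 0.45 cM; 12.2 cM / 39 markers = 0.31 cM).

## The simulator

`simulate_bsa_experiment()` generates the full experiment with ground
truth. What it emulates, with defaults chosen once as a realistic
desk-scale analogue:

* homoeologue pairs at 97% identity (`homoeologue_identity`), IHPs
  placed independently per site;
* 20% single-copy unigenes (`p_single_copy`), so hemi-SNPs dominate the
  varietal set (roughly 80–90%, as observed in tetraploid wheat
  transcriptomes);
* varietal SNPs at 2 SNPs/kb (`varietal_snp_rate`) in all polymorphic
  unigenes — linked and unlinked alike, since the BFR null behaviour is
  defined by unlinked markers;
* a 12.2 cM interval, target locus at its midpoint, 30% of unigenes
  linked with uniform map positions; bulks of 14 (high) and 15 (low)
  homozygous lines, each with exactly one crossover uniform on the
  interval (these panels are selected for single recombination events,
  which is why `simulate_cross()` uses a single-breakpoint model);
  per-line RNA weights allow unequal pooling (e.g. doubling specific
  lines). Loci outside the interval segregate freely
  (Bernoulli(1/2) per line);
* expression dispersion log-normal with `expression_sdlog = 0.5`
  (moderate; deliberately *not* the extreme skew of real non-normalised
  libraries, where the top few hundred transcripts can absorb half the
  reads — see limitations);
* reads: per-position depth Poisson(`mean_depth` × expression weight),
  base counts multinomial from the sample's allele mixture, uniform
  error `error_rate = 0.005` to the other three bases.

All randomness flows from one seed; the same configuration reproduces
byte-identical outputs, and `write_sim()` emits everything as plain text
(FASTA via Biostrings, mpileup text that round-trips through
`read_pileup()` with exact count agreement).

### Noise-free mode

`read_sampling = "expected"` replaces the multinomial read layer with a
deterministic largest-remainder apportionment of each column's depth
across the mixture (depth itself stays Poisson). This defines the
noise-free limit in which consensus calls recover the planted genotypes
*exactly* at every covered position — the right regime for validating
the classification pipeline, where any discrepancy is a bug rather than
sampling noise. Under the default binomial layer, exact recovery is
not a theorem: a Binomial$(41, 1/2)$ draw of 8 sits at 19.5% and drops
an IHP allele past the 20% fraction rule, producing about one false
hemi-SNP per couple of 50-unigene runs at 50-fold depth. That is a
property of any count-threshold caller on stochastic reads, and the
package treats it as such: correctness is asserted in the noise-free
mode, precision under noise is characterised, not promised.

## Numerical and interface choices

* mpileup parsing: 1-based positions; `.`/`,` resolve to the reference
  base; `^` consumes exactly one mapping-quality character; `+n`/`-n`
  indel blocks are consumed without counting (insertions do not occupy
  column depth); `*`, `N`, `<`, `>` consume depth into `n_other`. The
  parsed counts are validated against the depth field and mismatches
  are errors naming the line. Base qualities are not interpreted —
  quality control is the upstream aligner's job.
* Frequencies use the full column depth (including `n_other`) by
  default, matching a "count over total reads" reading; the ACGT-only
  alternative is a flag.
* Degenerate inputs: zero-depth columns have undefined frequencies
  (`NA`), which propagate to excluded/unevaluable records rather than
  errors; empty pileups run through the whole pipeline and produce
  empty outputs with a zero-count summary.
* Tabular outputs are header-addressed TSVs; reading validates column
  names (unknown headers are errors) so files survive column
  reordering but not schema drift.
* Parent A is *declared* the low-phenotype parent by configuration
  (`low_parent`), not hard-coded; BFR orientation follows the
  declaration.

## Test problem sizes

The validation suite runs simulations sized for exactness and
statistical power rather than realism: 50 unigenes × 2 kb at 50-fold
depth for exact-recovery checks (noise-free mode; recall measured over
truth sites covered ≥ 8-fold in both parents); 20 seeds of 60 unigenes
× 1 kb at 100-fold depth for the enrichment property (every planted SNP
within 0.5 cM of the target enriched ≥ 3-fold or excluded by a zero
denominator; unlinked median BFR inside [0.8, 1.25] — with ~36 unlinked
unigenes the per-seed median has enough precision for that band); 400-
fold depth for the 0.5 frequency ceiling. Monte-Carlo cross-checks
(Poisson-split sampling for the coverage model, brute-force BFR
recounts from raw pileup columns) accompany every closed form.

## Limitations

* The simulator models one cross; real bulks drawn from related crosses
  with shared ancestry, residual heterozygosity, or genotyping errors
  in bulk assembly are not represented.
* Expression dispersion is moderate log-normal; the extreme transcript
  skew of real non-normalised RNA-seq (and its effect on per-unigene
  coverage) is out of scope, so passing tests say nothing about
  recovering rare transcripts in real libraries.
* No statistical significance is attached to a BFR — the threshold is
  an operating point, and unlinked markers can exceed it by bulk
  composition drift at these bulk sizes (the worked example in the
  README shows two). Downstream marker validation is assumed.
* Varietal SNPs are not assigned to a homoeologous genome; that needs
  diploid-progenitor references.
* Alignment itself (and mapping-quality handling around clustered
  polymorphisms, which strongly affects false IHP calls) is upstream of
  this package: it consumes pileups as given.
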