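---
title: "Methods: cluster-based genotype calling and F2 mapping for an allotetraploid SNP array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based genotype calling and F2 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymap)
```

`polymap` implements the computational chain behind a high-density SNP
genotyping array for an allotetraploid crop (cotton is the motivating
system): selecting array content from candidate SNPs, calling genotypes
from two-channel intensity clusters, classifying markers by cluster
pattern, building F2 linkage maps, and comparing those maps to a
reference genome. This vignette describes the models, the tunable
parameters and their defaults, the design decisions taken where the
procedure was genuinely open, and the known limits of what the
synthetic-data tests demonstrate.

## Intensity model and cluster engine

Two-channel signals $(X, Y)$ are reduced to polar coordinates
$\theta = \tfrac{2}{\pi}\arctan(Y/X) \in [0,1]$ (allelic ratio) and
$R = X + Y$ (total signal). Genotype structure lives almost entirely on
the $\theta$ axis, so the cluster engine fits a one-dimensional
Gaussian mixture on $\theta$ per marker, for $k = 1, 2, 3$ components;
$R$ is used only to exclude assay failures below a floor
(`r_floor = 0.3` in the simulated signal units, where successful
samples sit near $R = 1$). Markers with fewer than 10 callable samples
are failed outright.

Model choice is by BIC with deterministic initialization from
$\theta$ quantiles, so a refit of the same data returns the same model
— a property worth more than marginal likelihood gains in a pipeline
whose reference implementation involved manual curation. Component
standard deviations are clamped below at $10^{-3}$ to keep degenerate
single-valued clusters finite. Components are ordered by mean and
labelled `AA < AB < BB` (for $k = 3$; for smaller $k$, by position on
the axis, homozygotes near 0 and 1, heterozygotes near 0.5).

Calls are maximum-posterior assignments, with no-calls (`NC`) when the
posterior falls below 0.85 or the signal is under the floor. The
posterior threshold trades call rate against error rate; 0.85 calls
essentially everything for well-separated clusters while refusing the
ambiguous overlap region of compressed ones. Call frequency (fraction
of samples called) is binned into the four canonical classes: below
0.5 `failed`, $[0.5, 0.99)$ `deviant` — the signature of a segregating
null allele, which the simulator reproduces as low-$R$ signal failure —
$[0.99, 1)$ `near_complete`, and 1 `complete`. The gap $(0, 0.5)$ is
assigned to `failed` by convention; the 0.99 boundary is
inclusive-left.

### Separation score

Proprietary cluster-quality scores (of the GenTrain kind) are not
reproducible, so the package defines an open surrogate. For adjacent
components the Ashman separation is
$D = |\mu_2 - \mu_1| / \sqrt{2(\sigma_1^2 + \sigma_2^2)}$, mapped to
$[0, 1]$ by $S = \min_{\text{pairs}} D/(D + D_0)$. The calibration
constant $D_0 = 1.875$ is fixed so that the canonical diploid-like
marker (means 0.05/0.50/0.95, sd 0.03) scores exactly 0.80. $S$ is
calibrated to occupy the same working range as the proprietary score,
not claimed equal to it.

### Pattern classification

Markers classify in rule order: (i) call-frequency class `failed`
gives status `failed`; (ii) a marker whose called inbred samples are
≥ 95% heterozygous is `intergenomic` (pattern 2) — a homeo-SNP reading
a fixed difference between the two subgenomes, heterozygous in every
line. This check runs before the cluster-count rule because a
homeo-SNP is a *single* cluster at $\theta \approx 0.5$; testing
$k = 1$ first would classify every homeo-SNP as monomorphic. (iii) A
remaining single cluster is `monomorphic` (pattern 1). (iv) Otherwise
the marker is `polymorphic`, with pattern from $S$: ≥ 0.60 pattern 3
(genome-specific, diploid-like); $[0.30, 0.60)$ — or any homozygote
component within 0.1 of $\theta = 0.5$, the signature of one
monomorphic plus one polymorphic locus — pattern 4; $[0.20, 0.30)$
pattern 5; below 0.20 pattern 6. The 5/6 boundary is placed at 0.20
(the published bin edges overlap between 0.20 and 0.21; the lower edge
was chosen so the two bins partition $[0, 0.30)$). Pattern-6 markers
can optionally be demoted to `failed`, mirroring curation practice.

### What pattern recovery can and cannot show

A structural consequence of the $S$ definition is worth stating
plainly. True $S < 0.30$ forces $D < 0.80$, i.e. an inter-cluster gap
below $1.6\sigma$ — a near-unimodal mixture. At 200 samples, BIC
(correctly) prefers $k = 1$ for such data, so markers *generated* in
the pattern-5/6 bins are mostly classified monomorphic or intergenomic:
their compressed geometry is statistically unidentifiable, which is
precisely why such markers needed manual adjustment or were failed in
practice. End-to-end recovery on a panel spanning all six patterns is
therefore bounded by the pattern-5/6 share (about 14% under the default
composition, giving ≈ 84% recovery with patterns 1–4 essentially
perfect). The acceptance suite records this honestly rather than
redefining recovery.

## Synthetic data: what it emulates

The generator produces (a) per-marker intensity clusters for the six
patterns (truncated-normal $\theta$, normal $R$, genotype frequencies
0.4/0.2/0.4 for three-cluster patterns), with null alleles as low-$R$
failures; (b) inbred panels whose per-marker minor allele frequency
follows $0.5 \cdot \mathrm{Beta}(0.427, 0.784)$, calibrated once so
the simulated spectrum matches the exceedance profile reported for a
diverse inbred panel (≈ 67% of markers above MAF 0.05, 56% above 0.10,
40% above 0.20, mean ≈ 0.17); and (c) F2 populations as Markov walks
along a linkage map with per-interval recombination probability equal
to the inverse-Kosambi of the interval — no crossover interference
beyond what the Kosambi scale itself implies, which is the simplest
process consistent with map distances (a chi-square interference model
is out of scope). Segregation distortion is induced by post-hoc
viability weighting of individuals, reproducing parental-allele skews
without modelling gametic selection. Technical-replicate similarity is
emulated with a per-call error of $3.5 \times 10^{-4}$, chosen to
reproduce the ≈ 99.93% similarity observed between genotyping runs.

Defaults for the six pattern specs: pattern 1 a single cluster at 0.05;
pattern 2 a single cluster at 0.50; pattern 3 the canonical
0.05/0.50/0.95 with sd 0.03; pattern 4 shifted clusters
0.05/0.275/0.50 (homozygote at 0.5); patterns 5 and 6 compressed
clusters 0.45/0.50/0.55 with sd 0.033 and 0.06, placing their true $S$
mid-bin (0.288) and below 0.20 (0.182) respectively. The default panel
composition weights patterns 1–6 at 19/11/42/14/8.4/5.6% — monomorphic
and homeo-SNP shares follow the reported classification counts, and the
polymorphic split makes the well-behaved diploid-like class dominant
with progressively rarer compressed classes. The generator has no
quantitative noise model to inherit for $R$; its defaults
(mean 1, sd 0.1, failures near 0.08) are calibration choices exposed in
the spec objects.

What passing these tests does *not* show: real arrays have correlated
noise across markers of a sample, batch effects between plates, and
curated cluster positions; the simulator's markers are independent and
its clusters honest. Recovery rates here are upper bounds on real-data
behaviour.

## Linkage mapping

ABH recoding keeps only markers whose parents are called, opposite
homozygotes; progeny are coded relative to the female parent (A).
Two-point recombination fractions come from the F2 codominant
likelihood, maximized by EM over the latent recombinant-gamete count of
the double-heterozygote class; LOD is $\log_{10} L(\hat r)/L(0.5)$ and
linkage significance is the likelihood-ratio test of $r = 0.5$. Pairs
with fewer than 20 joint calls are undefined.

Grouping is single-linkage transitive closure over pairs with
$p \le 0.05$ (Bonferroni-adjusted over the number of tested pairs) and
LOD ≥ 3. The multiplicity adjustment is deliberate: with 520 markers
there are ≈ 135,000 pairs, and a raw LOD ≥ 3 threshold
($p \approx 2\times10^{-4}$) admits a couple of dozen chance linkages —
enough for single-linkage closure to fuse chromosomes (observed: 22
groups instead of 26). Classic mapping software's "P = 0.05" search
criterion is likewise multiplicity-adjusted. `p_adjust = "none"`
restores the raw rule for small marker sets.

Ordering collapses identical columns into bins, then minimizes the sum
of adjacent recombination fractions (SARF): exhaustive search up to 6
bins (which doubles as the test oracle), otherwise greedy seriation
from the most-linked pair refined by 2-opt segment reversals and
single-bin relocations to a local optimum. Positions are cumulative
Kosambi distances, $d = 25\ln\frac{1+2r}{1-2r}$; groups are oriented
so the lexically smaller terminal marker comes first (the study
oriented by consensus-map anchors, which are out of scope).

Cleaning iteratively removes markers whose apparent singleton
double-recombinant count exceeds a threshold *and* whose removal
shortens the group, stopping at a fixed point. The default threshold
(2) presumes dense maps (sub-cM spacing) where double crossovers
between neighbours are vanishingly rare; at the 7 cM spacing of the
desk-scale simulations a genuine rate of ≈ 1 per marker per 118
individuals makes 5 the appropriate setting, and the analysis scripts
say so where they use it. Framework reordering fixes the shared
markers in a trusted map's relative order and inserts the rest at
SARF-minimizing positions — the remedy for inversions across weakly
linked gaps, where de novo ordering is ambiguous.

Crossovers are counted as genotype transitions along an individual
(A↔H or H↔B one, A↔B two, missing skipped); with 20 markers per group
an appreciable fraction of true crossovers falls between markers or
within double-crossover intervals, so observed counts run a few percent
under truth and approach it as marker density rises — the dense-map
averages (≈ 2.6–2.9 per group per individual) match the reported
values. Recombination bins merge adjacent markers with
wildcard-compatible columns. Distortion is the $\chi^2$ test against
1:2:1 with 2 degrees of freedom (the codominant F2 has three genotype
classes); the summary reports the distorted fraction, the
heterozygote-deficit share among distorted markers, and the
female:male favored-allele ratio.

## Synteny

The dot-plot table is an inner join of map and alignment positions. A
group's expected reference chromosome is the modal chromosome of its
markers (ties by supported bp span, then lexically) — an override
table is accepted where anchor-based assignment exists. Translocations
are maximal runs of at least `min_run = 5` consecutive markers on the
same discordant chromosome; 5 suppresses single-marker alignment noise
while keeping arm-scale events detectable. Intervals are reported as
[min bp, max bp] of the run (Mb, 1 decimal) and the flanking-marker cM
range; both are this package's own definitions — published breakpoint
statements mix map and physical coordinates loosely. Map scale is
kb/cM per subgenome from assumed physical sizes (1600/800 Mb for the
A/D subgenomes of cotton).

## Numerical choices and degenerate inputs

Truncated-normal $\theta$ is sampled by inverse-CDF between the
truncation bounds; EM stops at $10^{-8}$ log-likelihood change or 500
iterations; recombination fractions are clamped to
$[10^{-9}, 0.5 - 10^{-9}]$ and the Kosambi transform caps at 1000 cM;
round-trips of all writers/readers are exact to 6 decimals (cluster
files) or 1 decimal (map positions, matching common map tables).
Empty inputs return empty results rather than errors wherever a
downstream join can cope; malformed cells (non-numeric bp, illegal ABH
codes, duplicate ids) are rejected with the offending location named.

## Problem sizes

The simulations behind the tests and the acceptance script use
500 markers × 200 samples for cluster recovery, 26 groups × 20 markers
× 118 individuals for map reconstruction, 100 replicates × 1000
individuals for recombination-fraction recovery, and 10,000 markers ×
93 individuals for the distortion null calibration — sizes chosen to
hold Monte-Carlo error well inside each check's tolerance while keeping
a full run in minutes on one core.

## Known limitations

Two-point ordering cannot resolve marker order within a bin (no
information exists at a given population size); the caller does not
model allele-specific intensity asymmetry or plate effects; the
homeo-SNP rule needs inbred annotations to fire; translocation calls
assume a run of markers keeps a consistent discordant chromosome; and
the pattern-5/6 identifiability bound discussed above is inherent to
any caller working from a fitted mixture on $\theta$ alone.
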