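---
title: "Methods behind mitocomp: models, conventions and design choices"
author: "mitocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements the comparative toolkit used when a clade of unusual
mitochondrial genomes — the motivating case is the scale insects
(Hemiptera: Coccoidea), whose mitogenomes reach ~86% A+T, show very strong
codon usage bias, carry truncated tRNAs and are heavily rearranged — is
analysed against a background set of related species. This vignette is the
package's own account of the statistics it computes, the conventions it
fixes where deposited records and the literature are ambiguous, and the
choices made where the design was genuinely open.

## Records, coordinates and partitions

A `mitogenome_record` holds the majority-strand sequence of a circular
molecule and a table of typed gene features (13 protein-coding genes, 22
tRNAs, 2 rRNAs, control region). Coordinates are 1-based inclusive, the
GenBank convention; a feature crossing the replication origin is stored
with `wraps = TRUE` and `start > end` rather than as a split location, so
downstream code can treat every feature as one interval on a circle.
Sequences are restricted to A/C/G/T/N: the rare IUPAC ambiguity codes are
rejected at parse time with a clear error rather than silently miscounted,
while N is accepted and excluded from every numerator *and* denominator.

Gene names in deposited records are wildly inconsistent (COI/COX1/cox1,
ND4L/nad4L, 16S/rrnL, ...), so all names are normalized to canonical
tokens. The leucine and serine isoacceptor tRNAs are disambiguated in this
order: an explicit codon-family tag in the name or product (CUN/UUR,
AGN/UCN, or a 1/2 suffix), then the anticodon qualifier (the reverse
complement of the anticodon identifies the decoded codon family), and
otherwise the gene is flagged `"?"` rather than guessed — records differ
too much for a silent default to be safe. Records are taken as deposited;
no attempt is made to re-annotate genes the submitter missed.

Two strand conventions coexist deliberately. Composition and skew
statistics use the **majority strand** — partition sequences are
concatenated exactly as stored, minus-strand features *not*
reverse-complemented — because strand skews are properties of the
replication strand, and this is the convention under which published
mitogenome composition tables are computed. Codon-level statistics (RSCU,
ENC, GC3, Ka/Ks) use **coding strands**, since codons only exist in the
reading frame. `extract_partition()` exposes both via `coding_strand`.

The control region: when no D-loop feature is annotated the package does
not invent one. (A single longest-unannotated-span heuristic was
considered and rejected: with truncated tRNAs and variable spacers it too
often picks a spacer. Composition of the CR partition is simply empty,
and flagged, for such records.)

## Composition and skews

AT skew = (A−T)/(A+T) and GC skew = (G−C)/(G+C), the standard
strand-asymmetry definitions; they are not recomputable from published
figures in any other convention, and the package states them explicitly
because many papers print "AT skew" without a formula. Skews on a
partition with no counted bases of the relevant pair are `NA` with a
warning, never 0 — a zero would be indistinguishable from perfect balance.

Two-group comparisons default to the two-sided Mann–Whitney U test: focal
clades in this kind of study have n ≈ 5, where normality is untestable and
a rank test costs little power. A Welch t test is available behind
`method = "t"`. Significance tiers follow the plot-annotation convention
`***` (p < 0.01), `**` (p < 0.05), `ns`. With a singleton group the p
value is returned but flagged unreliable.

## Codon usage under translation table 5

All codon statistics default to the invertebrate mitochondrial code:
TGA = Trp, AGA/AGG = Ser, ATA = Met, stops TAA/TAG, hence **62 sense
codons** and a degeneracy structure of twelve 2-fold families, six 4-fold,
one 6-fold (Leu) and one 8-fold (Ser). The code is a parameter throughout,
so the standard code remains available.

Counting conventions: sequences are read in frame from position 1; a
trailing 1–2 nt remainder (the truncated stop codons T/TA completed by
polyadenylation in vivo) is dropped; codons containing N are skipped; stop
codons are excluded from every downstream statistic, and a stop *before*
the final codon triggers a warning naming the sequence and position, since
it usually indicates an annotation error.

RSCU is observed count over the family-uniform expectation. A codon of a
family with zero total is `NA` (nothing to normalize), distinct from an
unused codon of a present family, which is 0 and classified "unused".
Classification thresholds are strict inequalities at 1.6 and 0.6. A
display-level split of Leu into Leu1 (CUN)/Leu2 (UUR) and Ser into Ser1
(AGN)/Ser2 (UCN) is available for RSCU only; ENC and default RSCU use the
full code families.

GC1/GC2/GC3 are computed over all sense codons including Met and Trp
(under table 5 every amino acid has at least a 2-fold family, so the
synonymous-only variant, exposed as `synonymous_only = TRUE`, coincides
with the default there); GC12 is the exact mean of GC1 and GC2.

### Wright's ENC and its expectation curve

Per synonymous family with n ≥ 2 counted codons the codon homozygosity is
estimated as F̂ = (nΣp²−1)/(n−1); families are grouped by the **active
code's** degeneracy classes and ENC = Σ K<sub>c</sub>/F̄<sub>c</sub>. The
familiar "ENC ranges 20–61" applies to the standard code; under table 5
the no-bias limit is the 62 sense codons, and the floor of 20 (one codon
per amino acid, every F̂ = 1) is preserved because the code has no
single-codon amino acids. The result is clipped to [20, 62].

Missing-class fallback: a class with no eligible family (all n < 2 or
F̂ ≤ 0) borrows the mean of the nearest lower-degeneracy class that has
one — 6-/8-fold from the 4-fold mean, and the 4-fold class itself from the
2-fold mean. The second step matters in practice: at ~86% A+T every 4-fold
family requires a G or C at codon position 1 or 2, and extremely biased
genomes can leave all six unestimable at once. Each substitution is
logged. ENC is `NA` only when even the 2-fold class is empty.

Two numerical facts the test suite pins down because they are easy to get
wrong: the finite-sample bias of F̂ is downward (F̂ rises toward Σp² as n
grows), so ENC computed on k-fold scaled counts *decreases* monotonically
toward its large-sample value; and the mutation-only expectation curve
ENC\*(s) = 2 + s + 29/(s²+(1−s)²) — the bracketed denominator is sometimes
misprinted as s²+(1−s²), which collapses the whole curve to the useless
constant-plus-s form 31+s — has its maximum slightly *above* s = 0.5 (at
s ≈ 0.5022), because of the linear +s term.

## Neutrality analysis

Each species contributes one point: codon positions are pooled over the
concatenated 13 PCGs (per-gene averaging was the alternative; pooling
matches how per-mitogenome GC3/GC12 values are conventionally reported and
weights genes by length). The GC12-on-GC3 regression is ordinary least
squares; significance is reported via the slope's F statistic
(F = r²(n−2)/(1−r²) on 1 and n−2 df), the reporting style of the
neutrality-plot literature. The slope b maps to mutation pressure 100·b %
and selection 100·(1−b) %; the two always sum to exactly 100, and slopes
outside [0, 1] are reported as-is with a warning because the partition
interpretation breaks down there.

Note that the regression needs compositional spread *between* species: a
set of genomes generated (or sequenced) at a single mutational pressure
gives a slope dominated by sampling noise, and the per-species codon-usage
noise attenuates the slope toward 0 exactly like errors-in-variables in
any regression. The worked example in the README spans A+T 70–88% for
this reason.

## Ka/Ks by Nei–Gojobori

Codon alignment first: sequences are translated (terminal stops removed;
internal stops warned about and excluded later), globally aligned at the
protein level with Needleman–Wunsch under BLOSUM62 with affine gap
penalties (opening 10, extension 1 — a gap of length k costs 10+k), and
back-translated, so gaps always respect codon boundaries. The alignment
step is standard machinery and delegates to Biostrings; the rate
estimation is implemented in the package.

Sites: at each codon position the synonymous fraction is the share of the
one-step changes *not creating a stop* that preserve the amino acid; per
codon the three fractions sum with their complements to exactly 3, so
N+S = 3 × (codon pairs) always. Differences: a pair differing at k
positions is decomposed into its k! single-step orderings; orderings
passing through a stop codon are discarded and the synonymous/
nonsynonymous step counts averaged over the rest with equal weights. If
*every* complete ordering is blocked (possible only for some 2–3 step
pairs), the pair contributes the average over the maximal stop-free
prefixes instead — an undercount, logged whenever it happens, preferred
over dropping the pair entirely. Proportions are corrected with
Jukes–Cantor, d = −(3/4)ln(1−4p/3), undefined at p ≥ 3/4.

Regime calls: purifying/neutral/positive by comparison of Ka/Ks to 1 with
tolerance 1e-9; identical sequences give ratio `NA` and regime
"undefined"; Ks = 0 with Ka > 0 gives ratio `Inf` and "positive". Per-gene
group summaries average the *defined pairwise ratios* (the ratio of mean
rates is available via `ratio_method = "ratio_of_means"`; the mean of
ratios was chosen as the default because it is what per-gene bar charts of
"average Ka/Ks" usually show, and the count of undefined pairs is always
reported alongside). Exact numerical agreement with other Ka/Ks software
is not guaranteed — implementations differ in pathway weighting and stop
handling — but the method family is the same.

All 64×64 pathway tables are precomputed per genetic code and cached, so
genome-scale Ka/Ks runs are lookup-bound.

## Gene order

Orders are signed circular sequences of canonical tokens, extracted by
ascending start coordinate, rotation-normalized to start at cox1 (rotation
never changes any statistic). An adjacency is a directed signed pair; the
same physical junction read on the other strand is (−y, −x), and both
encodings collapse to one canonical string, because circular DNA has no
intrinsic reading direction. Shared adjacencies are computed after
restricting both orders to their common gene set (removing a gene joins
its neighbours, as on the molecule); breakpoint distance is the number of
non-shared junctions, which on equal gene sets equals n minus the shared
count and is symmetric. It is a pseudometric: distance 0 means identical
up to rotation or whole-molecule reflection. The control region is
excluded from orders by default (length-variable, often unannotated);
rearrangement *scenario* inference (common intervals, TDRLs, inversion
distance) is deliberately out of scope — conservation frequencies per
junction are reported and interpretation left to the user. The ancestral
*Drosophila yakuba* arrangement ships as a plain-text fixture.

## The synthetic generator: what it emulates, and what it does not

`make_mitogenome()` draws a per-species codon distribution from a
Dirichlet centred on an iid-nucleotide model at the A+T target
(concentration = α × 62 × centre, default α = 0.15), builds PCGs
codon-wise with ATN starts, TAA/TAG stops and no internal stops by
construction, samples tRNAs (50–66 nt, emulating the truncated tRNAs of
scale insects), rRNAs, a 100–1400 bp control region and 0–30 bp spacers
from iid bases at the same target, applies the requested number of random
tRNA-block transpositions/inversions to the ancestral order (rearrangement
confined to tRNA blocks, the empirically dominant mode), and redraws until
the realized whole-genome A+T is within ±2% of target. Everything is
deterministic under (seed, index). Defaults — A+T 0.86, α 0.15, two
rearrangements — are fixed once to the focal-clade regime and are not
tuned per analysis.

`simulate_divergence()` evolves a derived copy of an ancestral CDS under a
Poisson process of candidate point mutations accepted in the ratio
1 : ω for synonymous : nonsynonymous changes, with the larger acceptance
probability equal to 1 so that ω > 1 (positive selection) is
representable, and stop-creating changes always rejected; the intensity is
calibrated so the expected accepted synonymous divergence per ancestral
synonymous site equals `target_dS`. Accepted substitution counts are
returned as ground truth.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: gene overlaps; secondary-structure-aware
tRNA/rRNA sequences; phylogenetic correlation among species (every genome
is an independent draw); position-specific selection on codon usage (the
Dirichlet noise is symmetric across positions); indels within coding
sequences; and the annotation noise of real deposited records. Parameter
recovery on simulated data shows the estimators are consistent under their
own model, not that the model captures every force shaping real
mitogenomes.

## Problem sizes and numerical conventions used by the test suite

The suite generates all fixtures in code: typical sizes are 300–4000
codons for codon-usage and Ka/Ks oracles, 3000-codon pairs × 30 replicates
for selection-regime recovery, 100 random signed circular permutations of
≤ 10 genes for breakpoint checks, and 20–30 whole synthetic genomes for
generator fidelity; these sizes were chosen as the smallest at which the
stochastic properties under test are stable. Oracles are independent
implementations (explicit loops, exhaustive enumeration, matrix-solve
normal equations, a separately coded Gotoh DP) frozen into the tests.
Floating-point equality is asserted at 1e-12 where arithmetic is exact,
1e-9/1e-10 where accumulation is involved, and with stated stochastic
bands (e.g. ±15% for neutral-ω recovery) elsewhere.

## Known limitations

The GenBank parser covers the flat-file subset produced by mitogenome
annotation pipelines, not the full standard (no multi-interval joins other
than origin wrapping, no feature operators beyond `complement`/`join`/
`order`). Ka/Ks values are pairwise, not phylogenetically corrected, and
short genes (atp8, nad4L) give volatile ratios — the per-gene summaries
report the number of undefined pairs for this reason. The neutrality
partition inherits every caveat of interpreting an OLS slope causally.
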