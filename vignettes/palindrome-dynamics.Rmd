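---
title: "Inferring palindrome mutation and gene-conversion dynamics on the Y chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring palindrome mutation and gene-conversion dynamics on the Y chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ypal)
```

## The model

The male-specific region of the Y chromosome is transmitted clonally, so
a cohort of Y chromosomes is related by a single rooted tree. A
palindrome's two arms are so similar that reads from both map to one
arm; a position where the arms differ therefore appears as a
heterozygous call in an otherwise haploid chromosome. Treating each arm
position as a pseudo-diploid locus with states `HOM_REF`, `HET`,
`HOM_ALT`, the evolution of a site along the tree is a three-state
process with two elementary moves:

* a **mutation** changes one arm's base, taking a homozygous state to
  `HET`;
* an **arm-to-arm gene conversion** overwrites one arm with the other,
  taking `HET` to a homozygous state. The surviving allele need not be
  the older one, which is what makes conversion *directional*: it can
  favour G:C over A:T pairing (GC-biased gene conversion) and the
  ancestral over the derived allele.

Given observed leaf genotypes and the tree, ancestral states are
reconstructed by Fitch parsimony: a bottom-up pass assigns every
internal node the intersection of its children's state sets when that
intersection is non-empty, else their union; a top-down pass then picks
one state per node, preferring the parent's state whenever it is
admissible. Every branch-site pair whose resolved parent and child
states differ is one event, typed by the state pair (the homozygous-to-
opposite-homozygous case is labelled `complex`; it requires two moves
on one branch and is excluded from rate tallies). This resolution
achieves the parsimony minimum on binary trees; the test suite verifies
the count against brute-force enumeration of all ancestral labellings
on every rooted topology with up to five leaves and a sampled subset of
six-leaf topologies, under every possible leaf-state combination.

Polarisation uses outgroup genotypes supplied per site: the root takes
the outgroup consensus when it is admissible, and the site's ancestral
allele is the allele of a homozygous resolved root (or the outgroup's
homozygous allele when the root stays heterozygous). A conversion whose
site has no known ancestral allele is reported with `ambiguous`
polarity, not guessed. Events on the root's own two branches are only
called where the outgroup fixed the root; otherwise the direction of
change on those branches is unidentifiable and they are counted as
"unpolarizable" instead.

Rates divide event counts by the generations spanned by *all* branches
of the tree and by the analysed sequence length — for an arm pair,
twice the arm length, since a mutation on either arm creates the same
pseudo-heterozygote. The generation span itself comes from haploid
X-degenerate SNVs: `generations = n_SNVs / (mu * callable_bp)` with mu
the per-generation haploid SNV rate. Bias contrasts (conversion
polarity, conversion GC direction, mutation GC direction overall and
restricted to private events) are 1-df chi-square goodness-of-fit tests
against 1:1 without continuity correction; percentages are reported to
the nearest integer. The GC-neutral conversion polarity subtable is
reported descriptively, without a significance claim, because its
counts are small by construction.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `mu_xdeg` | SNVs per position per generation | 3.14e-8 | haploid Y SNV rate used for calibration |
| `mu_pal` | events PPPG (arm pair counted as 2 x arm length) | 1.76e-8 | palindrome mutation rate |
| `gamma` | events PPPG | 1.21e-8 | arm-to-arm conversion rate |
| `b_at` | probability | 0.56 | new mutations create A/T alleles at 56:44 |
| `b_gc` | probability | 259/417 | conversion resolves GC-vs-AT sites to G/C at ~62:38 |
| `b_anc` | probability | 171/271 | conversion favours the ancestral allele at ~63:37 |
| `total_generations` | generations (total branch length) | 12265 | span of the cohort tree |
| `arm_length_bp` | bp | 1.4e6 | one palindrome arm |
| `xdeg_length_bp` | bp | 8.1e6 | callable X-degenerate sequence |
| `depth_per_copy` | reads | 30 | a two-copy arm pair reads ~60X |
| `het0_density` | het sites per arm position | 1e-4 | standing arm divergence at the root |
| `min_depth`, `max_depth` | reads | 50, 250 | inclusive depth window for genotype calls |

`het0_density` deserves a note. Real palindrome arms are >99.9% — but
not 100% — identical, so the root of any cohort tree already carries a
pool of arm differences. The simulator seeds that pool explicitly; it
also keeps early gene conversions honest, since a conversion must act
on a currently heterozygous site and a root with no standing
differences would silently suppress conversions near the root (a drawn
conversion with no heterozygous target is discarded and counted, and at
the default densities the discard count is essentially zero).

The conversion survivor at a heterozygous site with ancestral allele
`a` and derived allele `d` is drawn with probability proportional to
`w_gc(x) * w_anc(x)`, where `w_gc` applies `b_gc` only when the two
alleles differ in GC class and `w_anc` applies `b_anc` to the ancestral
allele. This factorised form reproduces both marginal biases — exactly
for `b_anc` on GC-neutral sites, and to well within binomial error for
`b_gc` — which the acceptance tests check by running the bias summary
on the simulator's truth log.

## What the generator does and does not emulate

The simulator reproduces the statistical structure the inference
assumes: a rooted binary tree whose father-son pairs are cherries with
one-generation terminal branches and whose total branch length is the
requested generation span; Poisson event counts per branch; time-ordered
events within a branch, so conversions only target sites heterozygous
at that moment; infinite-sites haploid SNVs; finite-sites palindrome
positions kept biallelic over their whole history (a mutation re-hitting
any previously touched site is redrawn, so a site never carries three
alleles); and per-position depth as Poisson(copy number x depth per
copy).

It does not simulate reads or sequence context, indels or STRs,
conversion tracts longer than one site (called tracts can be merged
afterwards with `merge_conversion_tracts()`, 1 kb default gap), or
cross-talk between different palindromes; multi-copy arms are outside
the model, matching the analysis that excludes them. Depth is
independent Poisson per position, with none of the GC-tracking or
mapping artefacts of real coverage. Passing tests therefore show that
the inference machinery is correct under the stated model, not that
real-data artefacts (mapping bias, reference errors, recurrent
mutation) are handled.

## Numerical and design choices

* **Depth bounds inclusive.** The window keeps genotypes with depth in
  [50, 250]; depth 49 or 251 becomes `MISSING`.
* **Missing leaves** contribute the full state universe in the
  bottom-up pass (standard Fitch treatment) and never generate events
  on their own terminal branches.
* **Tie-breaks are fixed**: where several states are admissible the
  order `HOM_REF > HET > HOM_ALT` decides, making every run
  deterministic; the per-site flag `root_by_outgroup` records whether
  the root came from the outgroup or from this preference, so
  sensitivity can be audited.
* **Rounding of copy numbers is half-up** (2.5 becomes 3), applied both
  to normalised coverage and to the group baseline of the conservative
  high-copy rule, under which leaf values within one copy of their
  haplogroup's rounded mean collapse onto it before changes are
  counted.
* **Degenerate inputs**: a pair of samples with no jointly-called SNV
  site is an error unless explicitly permitted as `NA`; a coverage
  track shorter than one window yields a single whole-track segment; a
  bias table with fewer than two events reports percentages but skips
  its test; an empty event list gives an empty report with a warning.
* **Concordance masking** measures the 50 bp gap flank in alignment
  columns and computes windows in alignment coordinates; gap and masked
  columns count toward neither numerator nor denominator.
* **Generation calibration** returns the unrounded quotient
  (`calibrate_generations(3126, 3.14e-8, 8.1e6)` is 12290.6); reports
  that print generations round to whole numbers, and downstream
  arithmetic keeps full precision. The callable length is an explicit
  argument precisely because small changes in it move the result by
  tens of generations. Likewise the analysed palindrome length is an
  explicit argument of `estimate_rate()` (the arm-pair convention is
  2 x 1.4 Mb = 2.8 Mb).
* **Recurrent-site exclusion** for calibration is an iterative clade
  filter: build the NJ tree, drop sites whose carriers are not a clade,
  rebuild once.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive parsimony enumeration (all rooted topologies with up to five
leaves, all 3^n leaf-state combinations; forty random six-leaf
topologies), a replay oracle that re-derives every leaf genotype from
the logged truth along its root-to-leaf path, Poisson and binomial
moment checks over replicates at 3-standard-error tolerance, additive
distance matrices for neighbor joining, and brute-force enumeration for
copy-number parsimony.

Simulation-based checks run at a reduced scale chosen so that each
check's statistic is well-powered: 100 kb arms, 20 samples with five
father-son pairs, and the full 12265-generation span for event-recovery
and rate-recovery (100 replicates); the full 1.4 Mb arm and 62-sample
cohort for the bias-parameter recovery, where conversion counts near
400 are needed. The event-recovery check raises the standing root
heterozygosity to 8e-3 so that expected events per segregating site
stay below ~0.1: recovery is deliberately assessed in a sparse regime,
because nested same-site events (a conversion reverting a mutation on
an adjacent branch, or on the same branch) are intrinsically ambiguous
for any parsimony method — the corresponding blind spot applies to real
data too and is why the recovery criterion excludes that regime. The
recovery check also skips depth masking to isolate reconstruction
accuracy from missingness, whose effect is covered separately by the
monotonicity property (tightening the depth window never increases the
number of calls).

## Known limitations

* Parsimony undercounts events at densely hit sites; rates are
  therefore slight underestimates when many events share a site.
* Conversions at sites already heterozygous at the root cannot be
  polarised without an outgroup that is homozygous there; they dilute
  the polarity tables as `ambiguous` entries rather than biasing them.
* The copy-number estimator resolves single-copy differences poorly for
  high-copy arrays (hence the group-baseline collapse) and cannot
  distinguish functional genes from pseudogenes.
* The chi-square bias tests use the continuous chi-square tail; at
  small totals the discrete binomial null deviates from it, which the
  suite accounts for by comparing against a Monte-Carlo mid-p.
* Neighbor joining is distance-based; no likelihood tree is attempted.
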