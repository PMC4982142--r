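---
title: "Detecting chromosome-specific regions from DOP-PCR sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosome-specific regions from DOP-PCR sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopseg)
```

## The problem

Flow sorting (or microdissection) isolates one chromosome — here typically a
supernumerary B chromosome — whose few picograms of DNA are amplified by
degenerate-oligonucleotide-primed PCR (DOP-PCR) before Illumina sequencing.
Two properties of such libraries shape the whole analysis:

* The DOP primer anchors at a fixed 3' hexamer (`ATGTGG`), so amplification
  starts at reproducible genomic sites. After alignment to a reference
  genome, overlapping reads collapse into discrete intervals
  (**DOP-positions**), each standing for one amplicon locus, rather than
  into continuous coverage.
* Sorting is imperfect and amplification is promiscuous, so a substantial
  fraction of positions is whole-genome background. The sequence actually
  present on the sorted chromosome reveals itself not by depth but by
  **density of positions**: inside such a region there is roughly one
  amplicon per 1.7–2.2 kbp, against one per tens of kbp elsewhere.

`dopseg` turns this into an explicit signal: for each chromosome the
**pairwise distance** (PD) from every DOP-position to the one on its left
(for the first position, to the 0-coordinate) is computed, and chromosomes
are partitioned into segments of homogeneous mean PD. Segments with the
lowest mean PD are candidate **target regions** — intervals present on the
sampled chromosome.

## Contamination filtering

Human DNA is a characteristic contaminant of whole-genome-amplified
libraries. Reads are aligned to both the target genome and the human
genome, and mapping quality is compared per read (per mate):

* a read whose contaminant-genome MAPQ **strictly exceeds** its
  target-genome MAPQ is removed as contamination (equal MAPQs keep the
  read — only strictly better evidence counts against it);
* survivors must clear a MAPQ floor on the target genome
  (`mapq_floor = 20`, exclusive), removing non-unique alignments;
* reads unmapped in the target genome are dropped before any accounting,
  since they contribute no coordinates.

The order of the two steps does not change which reads survive — a read is
kept iff `target_mapq > 20` and `target_mapq >= contam_mapq` — it only
changes how removals split between the "contaminant" and "low-quality"
columns of the statistics. `dopseg` applies the contaminant comparison
first, on raw MAPQ pairs, and the floor to its survivors. Filtering is per
mate: a pair with one human-looking mate keeps the clean mate, because
nothing about the chemistry makes contamination pair-coherent.

## DOP-positions and the PD series

Kept reads are merged into positions with book-ended intervals joined
(distance 0), matching the defaults of the standard BED toolchain used for
this operation. Two numerical conventions matter downstream:

* all interval tables are 0-based half-open (BED); VCF positions are
  1-based only at the file boundary;
* PD is the inter-position **gap** (`start[i] − end[i−1]`), not the
  start-to-start distance. This choice makes the conservation identity
  `sum(pd) + sum(position widths) = end of last position` hold exactly,
  and makes "distance to the 0-coordinate" the natural value for the first
  position.

The position length histogram (default 10 bp bins) is a library QC:
Nextera-style fragmentation gives a characteristic bimodal length profile
with modes near 100 bp (fragmented amplicons) and 180–200 bp (intact
ones). Modes are local maxima over a ±2-bin window at ≥ 25 % of the tallest
bin; a plateau of tied bins reports one mode at its leftmost bin, so an
amplicon-length peak falling on a bin edge is still a single mode.

## Outlier trimming

Raw PD series carry two artifact tails that would dominate a mean-based
segmentation:

* **small PDs** (`pd_low = 300` bp, about the upper amplicon length):
  non-overlapping read pairs from the two ends of one longer amplicon
  produce two positions a few tens of bp apart — one amplicon, not two
  independent loci;
* **large PDs** (above the genome-wide `pd_high_quantile = 0.995`
  quantile): stretches with no mappable positions at all — assembly gaps,
  repeat deserts, sequence without the primer hexamer.

Values outside `[pd_low, Q(0.995)]` are removed before segmentation; the
index map back to the original positions is kept, so genomic coordinates
are never lost. The thresholds are this package's own calibration — the
principle of trimming both tails is inherent to the method, the numbers
are configurable via `trim_config()`.

## Circular binary segmentation

Changes of mean PD along a chromosome are located by circular binary
segmentation (CBS), implemented from scratch (in C++ via Rcpp for the
quadratic scan) rather than wrapped from an existing copy-number package,
since the segmentation is the analytical core of the tool:

1. The current stretch of values is treated as a circle. For every
   boundary pair $(i, j)$ the two-sample contrast
   $T(i,j) = |\bar{x}_{in} - \bar{x}_{out}| / \sqrt{1/k + 1/(n-k)}$
   between the arc and its complement is computed from cumulative sums;
   the maximizing pair is the candidate split (ties break to the leftmost
   pair, making results deterministic). Both arc and complement must hold
   at least `min_width = 4` values.
2. The split is accepted when its permutation p-value
   $(\#\{\text{perm max} \ge \text{obs max}\} + 1) / (n_{perm} + 1)$
   over `n_perm = 1000` value shuffles is below `alpha = 0.01`.
   Permutations stop early once the exceedance count already forces
   rejection (a sequential early-stop; it can only terminate permutations
   whose outcome is decided).
3. Accepted splits recurse on the resulting linear pieces. A pruning pass
   then re-merges adjacent segments whose means do not differ at `alpha`
   (Welch t-test, or a permutation mean test for tiny or flat segments),
   and any fragment shorter than `min_width` is absorbed into the
   neighbour with the closer mean.

Segmentation operates on `log2(PD + 1)` by default: PD is heavy-tailed
(approximately exponential within a compartment), and the log transform
brings the within-segment distribution close enough to symmetric for a
mean-contrast statistic. `transform = "identity"` switches this off, and
then segment boundaries are invariant under adding a constant. All
permutation seeds derive deterministically from the user seed and the
window coordinates, so a run is reproducible end to end.

The per-test seeds are folded modulo $2^{31}-1$; `alpha`, `n_perm` and
`min_width` echo common copy-number-segmentation defaults and are package
choices, exposed in `cbs_config()`.

## Target-region calling

Segment means separate into a low-PD (target) and a high-PD (background)
population. `classify_segments()` runs an exact 1-D 2-means on
`log2(mean_pd)` (computed by scanning all split points of the sorted
values — deterministic, no random restarts):

* if the two cluster means are closer than `min_contrast = 3`-fold, the
  genome shows no target/background contrast and everything is background,
  with a warning — a single-segment genome degenerates the same way;
* segments within `margin_factor = 2`-fold of the boundary between the
  clusters are labelled `ambiguous` for visual review of the PD plots
  rather than silently assigned — the classifier is a provisional screen,
  not a final arbiter;
* sparse target segments (fewer than `min_region_positions = 10`
  positions) sitting first or last on their chromosome are demoted to
  `ambiguous`: spurious mapping of telomeric reads produces exactly this
  signature of a few kbp of dense positions at a chromosome end.

Adjacent target segments on one chromosome merge into one region. Margins
need one subtlety: each PD value describes the gap *left* of its position,
so a run of small PDs at indices $a..b$ means positions $a-1..b$ are
densely spaced — the position left of the first small gap belongs to the
region. `call_regions()` therefore extends the left margin by one position,
then refines both margins by splitting the candidate run at gaps above the
classification boundary and stripping terminal blocks of fewer than four
positions: a pair of background positions that happens to fall near a
region boundary would otherwise be absorbed by the mean-based segment and
stretch the margin by tens of kbp. With target spacing around 2 kbp, the
resulting margin resolution is on the order of the inter-amplicon gap
(a few kbp).

Regions too small for CBS to resolve (fewer than `2 * min_width`
positions) are still visible as short runs of consecutive small PDs;
`candidate_regions()` reports such runs outside the called regions as
`candidate (visual)`, mirroring the manual rescue of small regions from
the PD plots.

## Putative deletions and genes

Within a called region, maximal stretches with no covered position and
length ≥ `min_gap = 100` kbp are reported as **putative deletions**:
sequence plausibly absent from the sorted chromosome. The default sits
below the smallest deletion printed for the roe-deer dataset (140 kbp) and
near the mean implied by the brocket dataset (1.03 Mbp over 10 deletions).
Overlap with an assembly gap is annotated as an alternative explanation —
a gap is unmappable, so absence of positions there is not evidence of
absence; the method cannot distinguish true deletions from amplification
or mapping dropouts, and does not claim to.

Genes overlapping a region are classified `complete` (fully inside, clear
of deletions), `partial_margin` "(f)" (crossing a region margin), or
`partial_deletion` "(f?)" (inside but overlapping a putative deletion).
A gene that both crosses a margin and touches a deletion is margin-first,
"(f)" — the published tables never double-flag.

## Variant accounting

Variant calling itself is out of scope; `dopseg` consumes VCF callsets and
accounts for them on the read-covered fraction of the target regions:

* `subtract_callsets()` removes variants also present in a second callset
  (e.g. a sister species' divergence set), matching exactly on
  (chrom, pos, ref, alt) — no allele normalization beyond what the caller
  produced, a documented dialect decision;
* `covered_feature_sizes()` intersects covered intervals with gene
  features under the precedence coding > UTR > intron > intergenic, so the
  per-category lengths partition the covered total;
* `variant_density()` reports bp-per-variant (integer-rounded), overall
  and heterozygous-only; a category with no variants is undefined ("-"),
  not zero. `density_table_from_counts()` applies the same arithmetic to
  externally tabulated counts, whose categories may overlap and therefore
  not sum to the total;
* `novelty_stats()` applies the depth filter first, then counts absence
  from a known-variant set; `het_hom_ratio()` is a plain count ratio that
  refuses to divide by zero;
* `classify_effect()` is a lightweight single-category classifier: coding
  SNVs are translated with and without the alternate allele under the
  standard genetic code; indels in coding sequence are non-synonymous
  regardless of phase (frameshift and in-frame disruptions are pooled).
  It assumes one transcript per gene and does not model NMD or splice
  sites — for publication-grade annotation a dedicated annotator should
  replace it; the category scheme is compatible.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates a full synthetic experiment with known
truth. Amplicon start sites follow a Poisson process: `target_rate = 0.5`
per kbp inside truth regions minus planted deletions (one amplicon per
2 kbp, the observed B-chromosome spacing), `background_rate = 0.025` per
kbp elsewhere (one per 40 kbp), nothing inside assembly gaps. Lengths come
from an equal-weight normal mixture 100 ± 10 / 190 ± 10 bp, matching the
observed bimodal profile; each amplicon emits one read pair;
`contamination_fraction = 0.02` of reads get a contaminant MAPQ above
their target MAPQ, inside the observed 1.1–4.3 % range. Variants are
planted only within amplicon footprints at per-compartment rates with
per-compartment heterozygote fractions, so density and zygosity accounting
is exactly recoverable from the truth. Everything is reproducible from one
seed.

Deliberate simplifications: contamination is modelled at the
alignment-record level (MAPQ pairs), not by generating human sequence —
the filter's contract needs nothing more; no read-level sequencing errors;
Poisson placement rather than motif placement by default, so tests need no
reference FASTA. `simulate_motif_amplicons()` provides the motif-driven
alternative — deterministic amplicons between inward-facing occurrences of
the primer hexamer — for sequence-driven studies. Consequently, passing
tests demonstrate correct recovery of the generative geometry (region
margins, deletions, rates, zygosity); they do not demonstrate robustness
to mappability structure, repeat-driven multi-mapping, or PCR bias
correlated along the genome, none of which the generator produces.

## Scaled study layouts

`synthetic_truth_layout()` reproduces the two published region-size
spectra — 2 regions (1.94 Mbp + 41 kbp) for the roe-like layout, 26
regions of 23 kbp–1.83 Mbp for the brocket-like layout — each region on
its own synthetic chromosome with 2–3 Mbp background flanks. This keeps
the target/background geometry and the 20-fold density contrast of the
real experiments while the simulated genomes stay at 15–170 Mbp, small
enough that the end-to-end suite runs tens of replicates in minutes.
Recovery statements in the tests (≥ 95 % of planted region bp for regions
≥ 100 kbp, zero false-positive regions ≥ 100 kbp, margin error within
twice the mean inter-amplicon gap, all planted deletions ≥ 140 kbp found)
are therefore statements about these desk-scale conditions, not about the
original sequencing runs: read counts, position counts and the specific
genomic coordinates of the published tables require the real libraries and
reference genomes and are not reproduced here. What the package does
recompute from the published tables is their arithmetic — region totals,
gene completeness counts, variant densities, ratios and novelty
percentages — which the bundled data files and `scripts/acceptance.R`
exercise end to end.

Two bundled files are synthetic stand-ins, labelled as such in their
filenames: the brocket deletion table (only the count and total length
were published; 10 deletions of 103 kbp are placed inside the larger
regions) and the gene spans (only completeness flags were published;
intervals are placed to realize each flag).

## Known limitations

* Mean-PD segmentation detects regions down to roughly `2 * min_width`
  retained positions (≈ 20–90 kbp at target spacing); smaller regions
  surface only as visual candidates.
* The permutation test's quadratic scan makes runtime grow with the square
  of positions per chromosome; at one position per 2 kbp this is
  comfortable up to a few thousand positions per chromosome but would need
  windowing for dense whole-genome libraries.
* Het/hom ratios from pooled technical replicates inherit whatever
  genotype merging produced the input VCF; the package counts, it does not
  re-genotype.
* The effect classifier handles one transcript per gene; overlapping
  transcripts resolve by feature precedence, not by worst consequence.
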